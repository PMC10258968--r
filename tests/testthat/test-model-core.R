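test_that("read_boolnet parses minimal and multi-node files", {
  f <- write_model_file(c("targets, factors", "A, ! A"))
  m <- read_boolnet(f)
  expect_s3_class(m, "boolean_model")
  expect_identical(m$nodes, "A")
  expect_identical(boolvvv:::render_rule(m$rules$A), "! A")

  f2 <- write_model_file(c("targets, factors", "# a comment", "",
                           "A, B | C", "B, 1", "C, A & ! B"))
  m2 <- read_boolnet(f2)
  expect_identical(m2$nodes, c("A", "B", "C"))
})

test_that("malformed files produce errors naming the offending line or node", {
  f <- write_model_file(c("targets, factors", "A, ! A", "no comma here"))
  expect_error(read_boolnet(f), "line 3")
  f2 <- write_model_file(c("nodes, rules", "A, 1"))
  expect_error(read_boolnet(f2), "targets, factors", fixed = TRUE)
  f3 <- write_model_file(c("targets, factors", "A, 1", "A, 0"))
  expect_error(read_boolnet(f3), "duplicate node 'A'")
  f4 <- write_model_file(c("targets, factors", "C, A & D", "A, 1"))
  expect_error(read_boolnet(f4), "undeclared node\\(s\\): D")
  f5 <- write_model_file(c("targets, factors", "A, B & | C", "B, 1", "C, 1"))
  expect_error(read_boolnet(f5), "malformed Boolean expression")
})

test_that("write/read round trip preserves nodes and rule semantics exactly", {
  models <- list(
    make_cascade(TRUE)$model,
    make_cascade(FALSE, n_extra_layers = 1L)$model,
    make_random_model(8, 3, seed = 11),
    boolean_model(c("A", "B"), list(A = "1", B = "0"))
  )
  for (m in models) {
    f <- tempfile(fileext = ".boolnet")
    write_boolnet(m, f)
    m2 <- read_boolnet(f)
    expect_identical(m2$nodes, m$nodes)
    n <- length(m$nodes)
    if (n <= 10) {
      for (i in seq_len(2^n)) {
        s <- state_from_index(m, i)
        expect_identical(state_transition(m2, s), state_transition(m, s))
      }
    }
  }
  # constant-TRUE rule is written with the "1" constant dialect
  f <- tempfile()
  write_boolnet(boolean_model("A", list(A = "1")), f)
  expect_identical(readLines(f)[2], "A, 1")
})

test_that("parse_node_name classifies by the rxncon convention", {
  bond <- parse_node_name("L_[lig]--R_[ext]")
  expect_identical(bond$node_class, "state")
  expect_setequal(bond$components, c("L", "R"))
  expect_identical(unname(bond$bound_partner["L"]), "R_[ext]--0")
  expect_identical(unname(bond$bound_partner["R"]), "L_[lig]--0")
  expect_false(bond$is_neutral)

  expect_true(parse_node_name("L_[lig]--0")$is_neutral)
  neutral_mod <- parse_node_name("S_[site]-{0}")
  expect_identical(neutral_mod$node_class, "state")
  expect_true(neutral_mod$is_neutral)
  expect_identical(neutral_mod$components, "S")
  expect_false(parse_node_name("S_[site]-{p}")$is_neutral)

  rxn <- parse_node_name("K_p+_S_[site]")
  expect_identical(rxn$node_class, "reaction")
  expect_setequal(rxn$components, c("K", "S"))
  expect_identical(parse_node_name("L_ppi+_R_[ext]")$node_class, "reaction")
  expect_identical(parse_node_name("[EGF]")$node_class, "input")
  expect_identical(parse_node_name("<AND1>")$node_class, "gate")
  expect_identical(parse_node_name("whatever")$node_class, "unknown")
})

test_that("parse_node_name is total, deterministic, and bond-symmetric", {
  names <- c(make_cascade(TRUE, 2)$model$nodes, "x", "A--B--C", "_p+_",
             "A_[a]--B_[b]", "Q_ub-_Z")
  for (nm in names) {
    m1 <- parse_node_name(nm)
    m2 <- parse_node_name(nm)
    expect_identical(m1, m2)
    expect_true(m1$node_class %in%
                  c("reaction", "state", "input", "gate", "unknown"))
    if (length(m1$bound_partner) > 0) {
      expect_identical(sort(names(m1$bound_partner)), sort(m1$components))
    }
  }
})

test_that("neutral_state turns on exactly the neutral nodes", {
  cas <- make_cascade(TRUE)
  ns <- neutral_state(cas$model)
  expect_setequal(names(ns)[ns],
                  c("L_[lig]--0", "R_[ext]--0", "S_[site]-{0}"))
  # no neutral nodes -> all off; unknown-class nodes are off
  expect_identical(unname(neutral_state(neg_model())), FALSE)
  expect_true(all(!neutral_state(rotor3_model())))
})

test_that("read_annotations trims tags, handles empties, rejects bad quality", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,modules,quality",
               "S6K_stuff,\"S6K, PI3K-Akt\",3",
               "empty_one,,",
               "half, tagA ,"), f)
  ann <- read_annotations(f)
  expect_identical(ann$modules[[1]], c("S6K", "PI3K-Akt"))
  expect_identical(ann$quality[[1]], 3)
  expect_length(ann$modules[[2]], 0)
  expect_true(is.na(ann$quality[[2]]))
  expect_identical(ann$modules[[3]], "tagA")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,modules,quality", "x,tag,notanumber"), f2)
  expect_error(read_annotations(f2), "row 1.*non-numeric")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("id,quality", "x,1"), f3)
  expect_error(read_annotations(f3), "missing column")
})

test_that("annotation ids absent from the model are reported", {
  cas <- make_cascade(TRUE)
  ann <- tibble::tibble(id = c("L_[lig]--0", "ghost_node"),
                        modules = list("binding", "x"),
                        quality = c(3, 1))
  expect_warning(annotate_model(cas$model, ann), "ghost_node")
})

test_that("extract_module keeps tagged plus boundary nodes and stays closed", {
  cas <- make_cascade(TRUE, n_extra_layers = 1L)
  m <- cas$model
  ann <- cas$annotations
  # extracting every tag is the identity
  all_tags <- unique(unlist(ann$modules))
  full <- extract_module(m, ann, all_tags)
  expect_identical(full$nodes, m$nodes)
  for (nd in m$nodes) {
    expect_identical(boolvvv:::render_rule(full$rules[[nd]]),
                     boolvvv:::render_rule(m$rules[[nd]]))
  }
  # a single module survives with only its own and boundary nodes
  bind_only <- extract_module(m, ann, "binding")
  expect_true(all(grepl("^(L|R)", bind_only$nodes)))
  for (nd in bind_only$nodes) {
    expect_true(all(boolvvv:::rule_vars(bind_only$rules[[nd]]) %in%
                      bind_only$nodes))
  }
  # removed neutral nodes substitute as ON: the kinase reaction keeps firing
  # once the bond forms even though the substrate's neutral node is gone
  layer1 <- extract_module(m, ann, c("binding", "layer1"))
  expect_false("S2_[site]-{0}" %in% layer1$nodes)
  expect_warning(extract_module(m, ann, c("binding", "nosuchtag")),
                 "nosuchtag")
})

test_that("quality filtering removes low-scoring nodes and can empty a model", {
  cas <- make_cascade(TRUE)
  m <- cas$model
  ann <- cas$annotations
  # phosphatase reactions carry the lowest score in the fixture annotations
  no_pase <- extract_module(m, ann, unique(unlist(ann$modules)),
                            quality_threshold = 2)
  expect_false("P_p-_S_[site]" %in% no_pase$nodes)
  expect_true("K_p+_S_[site]" %in% no_pase$nodes)
  expect_error(
    extract_module(m, ann, unique(unlist(ann$modules)),
                   quality_threshold = 99),
    "empty model"
  )
})
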