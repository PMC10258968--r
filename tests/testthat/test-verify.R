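test_that("remove_ligand dissolves ligand complexes and preserves partners", {
  cas <- make_cascade(TRUE)
  m <- cas$model
  lig <- ligand_spec(m, cas$ligand)
  s <- neutral_state(m)
  s["L_[lig]--0"] <- FALSE
  s["R_[ext]--0"] <- FALSE
  s["L_[lig]--R_[ext]"] <- TRUE
  out <- remove_ligand(s, lig, m)
  expect_false(out[["L_[lig]--R_[ext]"]])
  expect_true(out[["R_[ext]--0"]])
  expect_false(out[["L_[lig]--0"]])

  # ligand already absent -> identity
  s2 <- neutral_state(m)
  s2["L_[lig]--0"] <- FALSE
  expect_identical(remove_ligand(s2, lig, m), s2)

  # unbound ligand present: only the presence node is cleared
  s3 <- neutral_state(m)
  out3 <- remove_ligand(s3, lig, m)
  expect_false(out3[["L_[lig]--0"]])
  expect_identical(out3[setdiff(names(out3), "L_[lig]--0")],
                   s3[setdiff(names(s3), "L_[lig]--0")])
})

test_that("add_ligand turns on the presence nodes only, idempotently", {
  cas <- make_cascade(TRUE)
  m <- cas$model
  lig <- ligand_spec(m, cas$ligand)
  s <- cascade_init(cas)
  out <- add_ligand(s, lig)
  expect_true(out[["L_[lig]--0"]])
  expect_identical(out[setdiff(names(out), "L_[lig]--0")],
                   s[setdiff(names(s), "L_[lig]--0")])
  expect_identical(add_ligand(out, lig), out)
  # bond untouched when the ligand is already bound
  s2 <- s
  s2[["L_[lig]--R_[ext]"]] <- TRUE
  out2 <- add_ligand(s2, lig)
  expect_true(out2[["L_[lig]--R_[ext]"]])
  expect_true(out2[["L_[lig]--0"]])
})

test_that("a reversible cascade verifies as a consistent two-attractor cycle", {
  cas <- make_cascade(TRUE)
  v <- verify_model(cas$model, ligand_spec(cas$model, cas$ligand))
  expect_true(v$consistent)
  expect_false(v$branching)
  expect_false(v$trap)
  expect_identical(nrow(v$attractors), 2L)
  expect_setequal(v$attractors$label, c("no-ligand", "with-ligand"))
  expect_length(v$meta_attractor, 2L)
  # the substrate is phosphorylated with ligand, unphosphorylated without
  atts <- split(v$attractors$attractor, v$attractors$label)
  expect_identical(
    unname(quantify_attractor(atts[["with-ligand"]][[1]], "S_[site]-{p}")), 1)
  expect_identical(
    unname(quantify_attractor(atts[["no-ligand"]][[1]], "S_[site]-{p}")), 0)
})

test_that("a cascade without dephosphorylation is flagged as a trap", {
  cas <- make_cascade(FALSE)
  v <- verify_model(cas$model, ligand_spec(cas$model, cas$ligand))
  expect_false(v$consistent)
  expect_true(v$trap)
  expect_false(v$branching)
  no_lig <- v$attractors$attractor[v$attractors$label == "no-ligand"]
  expect_identical(length(no_lig), 2L)
  expect_false(attractors_equal(no_lig[[1]], no_lig[[2]]))
  # the two no-ligand attractors differ only in the substrate's
  # phosphorylation state
  diff_nodes <- rownames(no_lig[[1]]$cycle)[
    no_lig[[1]]$cycle[, 1] != no_lig[[2]]$cycle[, 1]]
  expect_setequal(diff_nodes, c("S_[site]-{0}", "S_[site]-{p}"))
})

test_that("branching is detected when removal outcome depends on cycle phase", {
  m <- branching_model()
  v <- verify_model(m, ligand_spec(m, "L"))
  expect_false(v$consistent)
  expect_true(v$branching)
  # one with-ligand attractor node has two removal edges to distinct targets
  rm_edges <- v$edges[v$edges$transition == "remove", ]
  by_src <- split(rm_edges$to, rm_edges$from)
  expect_true(any(vapply(by_src, function(x) length(unique(x)) > 1, logical(1))))
})

test_that("a fixed-point with-ligand attractor cannot produce spurious branching", {
  cas <- make_cascade(FALSE)
  v <- verify_model(cas$model, ligand_spec(cas$model, cas$ligand))
  # every attractor here is a fixed point: the per-state fan-out is vacuous
  expect_true(all(v$attractors$cycle_length == 1L))
  expect_false(v$branching)
})

test_that("a ligand with no downstream edges yields an immediate meta-attractor", {
  m <- boolean_model(c("L", "X"), list(L = "L", X = "X"))
  v <- verify_model(m, ligand_spec(m, "L"), init = c(L = FALSE, X = FALSE))
  expect_true(v$consistent)
  expect_identical(nrow(v$attractors), 2L)
  a <- v$attractors$attractor[[1]]$cycle
  b <- v$attractors$attractor[[2]]$cycle
  expect_identical(rownames(a)[a[, 1] != b[, 1]], "L")
})

test_that("verification is reproducible and respects standing clamps", {
  cas <- make_cascade(TRUE)
  lig <- ligand_spec(cas$model, cas$ligand)
  v1 <- verify_model(cas$model, lig)
  v2 <- verify_model(cas$model, lig)
  expect_identical(v1$edges, v2$edges)
  expect_identical(v1$attractors$id, v2$attractors$id)

  # clamping the kinase reaction off survives the ligand transforms
  cl <- clamps(off = "K_p+_S_[site]")
  v3 <- verify_model(cas$model, lig, clamp = cl)
  for (tr in v3$trajectories) {
    expect_false(any(tr$trajectory$states["K_p+_S_[site]", ]))
  }
  expect_true(v3$consistent)
})

test_that("exported state and attractor graphs re-parse with matching counts", {
  cas <- make_cascade(FALSE)
  v <- verify_model(cas$model, ligand_spec(cas$model, cas$ligand))
  prefix <- file.path(tempdir(), "verify_graph")
  files <- export_state_graph(v, prefix, format = "xgmml")
  expect_true(all(file.exists(files)))
  att_xml <- xml2::read_xml(files[[2]])
  att_nodes <- xml2::xml_find_all(att_xml, ".//*[local-name()='node']")
  expect_identical(length(att_nodes), nrow(v$attractors))
  att_edges <- xml2::xml_find_all(att_xml, ".//*[local-name()='edge']")
  expect_identical(length(att_edges),
                   nrow(dplyr::distinct(v$edges[, c("from", "to", "transition")])))

  files_g <- export_state_graph(v, prefix, format = "graphml")
  g <- igraph::read_graph(files_g[[2]], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(v$attractors),
               ignore_attr = TRUE, tolerance = 0)

  # the reversible fixture's attractor-space graph is a 2-node cycle
  cas2 <- make_cascade(TRUE)
  v2 <- verify_model(cas2$model, ligand_spec(cas2$model, cas2$ligand))
  ids <- v2$attractors$id
  e <- dplyr::distinct(v2$edges[, c("from", "to")])
  expect_identical(nrow(e), 2L)
  expect_setequal(e$from, ids)
  expect_setequal(e$to, ids)
})
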