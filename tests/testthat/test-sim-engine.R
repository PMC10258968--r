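test_that("state_transition follows the rules and clamps dominate", {
  m <- neg_model()
  expect_identical(unname(state_transition(m, c(A = TRUE))), FALSE)
  expect_identical(unname(state_transition(m, c(A = FALSE))), TRUE)
  expect_identical(unname(state_transition(m, c(A = FALSE), clamps(on = "A"))),
                   TRUE)
  expect_identical(unname(state_transition(m, c(A = TRUE), clamps(on = "A"))),
                   TRUE)

  m2 <- copy2_model()
  expect_identical(state_transition(m2, c(A = TRUE, B = FALSE)),
                   c(A = FALSE, B = TRUE))
  expect_error(state_transition(m2, c(A = TRUE, B = FALSE),
                                clamps(off = "Z")), "unknown node")
  expect_error(clamps(on = "A", off = "A"), "both ON and OFF")
})

test_that("simulate_path detects fixed points and cycles at the right index", {
  tr <- simulate_path(neg_model(), c(A = FALSE))
  expect_identical(ncol(tr$states), 2L)
  expect_identical(tr$attractor_start, 1L)
  expect_identical(unname(tr$states["A", ]), c(FALSE, TRUE))

  m_id <- boolean_model("A", list(A = "A"))
  tr2 <- simulate_path(m_id, c(A = TRUE))
  expect_identical(ncol(tr2$states), 1L)
  expect_identical(tr2$attractor_start, 1L)

  # three-state rotor: (1,0,0) -> (0,1,0) -> (0,0,1) -> back
  tr3 <- simulate_path(rotor3_model(), c(A = TRUE, B = FALSE, C = FALSE))
  expect_identical(ncol(tr3$states), 3L)
  expect_identical(tr3$attractor_start, 1L)
  expect_identical(unname(tr3$states[, 2]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(tr3$states[, 3]), c(FALSE, FALSE, TRUE))

  expect_error(simulate_path(rotor3_model(), max_steps = 0), "max_steps")
})

test_that("simulation is deterministic and clamps hold at every tick", {
  for (seed in 1:5) {
    m <- make_random_model(7, 2, seed = seed)
    init <- state_from_index(m, (seed * 17L) %% 2L^7L + 1L)
    cl <- clamps(on = m$nodes[1], off = m$nodes[3])
    tr1 <- simulate_path(m, init, cl)
    tr2 <- simulate_path(m, init, cl)
    expect_identical(tr1$states, tr2$states)
    expect_identical(tr1$attractor_start, tr2$attractor_start)
    expect_true(all(tr1$states[m$nodes[1], ]))
    expect_false(any(tr1$states[m$nodes[3], ]))
  }
})

test_that("quantify_attractor returns exact on-fractions and conserves mass", {
  m_id <- boolean_model("A", list(A = "A"))
  att_on <- attractor(simulate_path(m_id, c(A = TRUE)))
  expect_identical(unname(quantify_attractor(att_on, "A")), 1)
  att_off <- attractor(simulate_path(m_id, c(A = FALSE)))
  expect_identical(unname(quantify_attractor(att_off, "A")), 0)

  att_half <- attractor(simulate_path(neg_model(), c(A = FALSE)))
  expect_identical(unname(quantify_attractor(att_half, "A")), 0.5)
  expect_error(quantify_attractor(att_half, "Z"), "unknown output")

  for (seed in 1:5) {
    m <- make_random_model(6, 2, seed = seed + 100L)
    att <- attractor(simulate_path(m, state_from_index(m, seed)))
    on_frac <- quantify_attractor(att, m$nodes)
    off_frac <- 1 - rowMeans(att$cycle)
    expect_equal(unname(on_frac + off_frac), rep(1, length(m$nodes)))
  }
})

test_that("attractor_distance is rotation-invariant, symmetric, and exact", {
  mk_att <- function(cycle) {
    attractor(boolvvv:::new_boolean_attractor(cycle))
  }
  nodes <- sprintf("x%02d", 1:10)
  s1 <- matrix(FALSE, 10, 1, dimnames = list(nodes, NULL))
  s2 <- s1
  s2[1, 1] <- TRUE
  expect_identical(attractor_distance(mk_att(s1), mk_att(s1)), 0)
  # fixed points differing in 1 of 10 nodes
  expect_identical(attractor_distance(mk_att(s1), mk_att(s2)), 0.1)

  # rotated copies of a cycle are at distance 0 and equal
  tr <- simulate_path(rotor3_model(), c(A = TRUE, B = FALSE, C = FALSE))
  cyc <- tr$states
  rot <- cyc[, c(2, 3, 1)]
  a <- mk_att(cyc)
  b <- mk_att(rot)
  expect_identical(attractor_distance(a, b), 0)
  expect_true(attractors_equal(a, b))

  # unequal-length cycles: fixed point vs the rotor 3-cycle; each rotor state
  # has exactly one node on, so the best phase still mismatches 1/3 of cells
  fp <- matrix(FALSE, 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(attractor_distance(mk_att(fp), a), 1 / 3)
  expect_false(attractors_equal(mk_att(fp), a))

  for (seed in 1:10) {
    m <- make_random_model(6, 2, seed = seed + 50L)
    a1 <- attractor(simulate_path(m, state_from_index(m, 2L * seed)))
    a2 <- attractor(simulate_path(m, state_from_index(m, 2L * seed + 31L)))
    expect_identical(attractor_distance(a1, a2), attractor_distance(a2, a1))
    expect_identical(attractor_distance(a1, a2) == 0,
                     identical(a1$cycle, a2$cycle))
  }
})

test_that("simulate-from-all-states matches exhaustive enumeration on small models", {
  for (seed in c(1, 2, 3)) {
    m <- make_random_model(6, 2, seed = seed)
    expect_identical(simulated_attractor_keys(m), oracle_attractor_keys(m))
  }
  # with clamps
  m <- make_random_model(6, 2, seed = 4)
  cl <- clamps(on = m$nodes[2])
  expect_identical(simulated_attractor_keys(m, cl), oracle_attractor_keys(m, cl))
})

test_that("trajectory CSV round-trips states, ticks, and attractor flags", {
  cas <- make_cascade(TRUE)
  lig <- ligand_spec(cas$model, cas$ligand)
  tr <- simulate_path(cas$model, add_ligand(cascade_init(cas), lig))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f)
  expect_identical(unname(tr2$states), unname(tr$states))
  expect_identical(rownames(tr2$states), rownames(tr$states))
  expect_identical(tr2$attractor_start, tr$attractor_start)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_trajectory_csv(bad), "malformed trajectory CSV")
})
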