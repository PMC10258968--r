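midas_fixture <- function(noise_sd = 0, seed = 7L, outputs = NULL) {
  cas <- make_cascade(TRUE)
  if (is.null(outputs)) outputs <- c("S_[site]-{p}", "L_[lig]--R_[ext]")
  treatments <- list(
    treatment_def("LIG", "stimulation", "L_[lig]--0"),
    treatment_def("KIN-i", "inhibition", "K_p+_S_[site]")
  )
  dir <- tempfile("midas")
  db <- make_synthetic_midas(cas$model, treatments, outputs, dir,
                             noise_sd = noise_sd, seed = seed)
  list(model = cas$model, db = db, dir = dir)
}

test_that("read_midas parses CSV-directory databases and validates them", {
  fx <- midas_fixture()
  expect_s3_class(fx$db, "experiment_db")
  expect_length(fx$db$experiments, 4L)  # 2 treatments -> 4 combinations
  expect_setequal(names(fx$db$treatments), c("LIG", "KIN-i"))
  expect_identical(fx$db$treatments[["KIN-i"]]$effect, "inhibition")

  # missing TreatmentDefs sheet
  d2 <- tempfile()
  dir.create(d2)
  file.copy(file.path(fx$dir, "Experiment01.csv"), d2)
  expect_error(read_midas(d2), "TreatmentDefs")

  # out-of-range DV value, unknown prefix, undefined treatment
  d3 <- tempfile(); dir.create(d3)
  file.copy(file.path(fx$dir, "TreatmentDefs.csv"), d3)
  utils::write.csv(
    data.frame(`TR:LIG` = 1, `DA:ALL` = 0, `DV:x` = 1.3, check.names = FALSE),
    file.path(d3, "Exp.csv"), row.names = FALSE)
  expect_error(read_midas(d3), "outside \\[0, 1\\]")
  utils::write.csv(
    data.frame(`TR:LIG` = 1, `ZZ:t` = 0, `DV:x` = 1, check.names = FALSE),
    file.path(d3, "Exp.csv"), row.names = FALSE)
  expect_error(read_midas(d3), "unknown column prefix")
  utils::write.csv(
    data.frame(`TR:GHOST` = 1, `DA:ALL` = 0, `DV:x` = 1, check.names = FALSE),
    file.path(d3, "Exp.csv"), row.names = FALSE)
  expect_error(read_midas(d3), "GHOST")
})

test_that("timepoint collapsing averages pre and post measurements", {
  d <- tempfile(); dir.create(d)
  utils::write.csv(
    data.frame(`TR:X` = c(1, 1, 1, 1),
               `DA:ALL` = c(0, 0, 10, 30),
               `DV:out` = c(0.1, 0.3, 0.6, 0.8), check.names = FALSE),
    file.path(d, "Exp1.csv"), row.names = FALSE)
  utils::write.csv(data.frame(name = "X", effect = "stimulation", nodes = "n"),
                   file.path(d, "TreatmentDefs.csv"), row.names = FALSE)
  db <- read_midas(d)

  col <- collapse_timepoints(db)
  expect_equal(col$exp_pre, 0.2)   # duplicate t=0 rows averaged
  expect_equal(col$exp_post, 0.7)  # mean of 0.6 and 0.8

  col_bin <- collapse_timepoints(db, time_bins = c(20, 40))
  expect_equal(col_bin$exp_post, 0.8)

  expect_warning(col_none <- collapse_timepoints(db, time_bins = c(100, 200)),
                 "exclude all post-stimulation data")
  expect_true(is.na(col_none$exp_post))
})

test_that("mse_cell implements the two-timepoint mean squared error", {
  expect_identical(mse_cell(1, 1, 1, 1), 0)
  expect_identical(mse_cell(1, 1, 0, 0), 1)
  expect_equal(mse_cell(0.2, 0.7, 0, 1), 0.065)
  # missing timepoints score on the available half; fully missing is NA
  expect_identical(mse_cell(NA, 1, 0, 0), 1)
  expect_identical(mse_cell(0.5, NA, 0.5, 1), 0)
  expect_true(is.na(mse_cell(NA, NA, 0, 1)))
})

test_that("predict_responses clamps treatments per the pre/post protocol", {
  fx <- midas_fixture()
  preds <- predict_responses(fx$model, fx$db)
  get <- function(combo, output, col) {
    preds[[col]][preds$combo == combo & preds$output == output]
  }
  # ligand stimulation: substrate off pre, on post
  expect_identical(get("LIG", "S_[site]-{p}", "sim_pre"), 0)
  expect_identical(get("LIG", "S_[site]-{p}", "sim_post"), 1)
  # kinase inhibitor blocks the response
  expect_identical(get("KIN-i + LIG", "S_[site]-{p}", "sim_post"), 0)
  # no treatment: nothing is toggled between pre and post
  expect_identical(get("(none)", "S_[site]-{p}", "sim_pre"),
                   get("(none)", "S_[site]-{p}", "sim_post"))

  bad_db <- fx$db
  bad_db$treatments[["LIG"]]$nodes <- "no_such_node"
  expect_error(predict_responses(fx$model, bad_db), "no_such_node")
})

test_that("scoring a model against its own noiseless predictions gives 0, inverted gives 1", {
  fx <- midas_fixture()
  rep <- score_model(fx$model, fx$db)
  expect_identical(rep$mse_tot, 0)
  expect_true(all(rep$cells$mse == 0))

  inv <- fx$db
  for (s in names(inv$experiments)) {
    dv <- grep("^DV:", names(inv$experiments[[s]]))
    inv$experiments[[s]][dv] <- lapply(inv$experiments[[s]][dv], function(v) 1 - v)
  }
  rep_inv <- score_model(fx$model, inv)
  expect_identical(rep_inv$mse_tot, 1)
})

test_that("the total score is invariant to sheet and row order", {
  fx <- midas_fixture(noise_sd = 0.15, seed = 42L)
  rep1 <- score_model(fx$model, fx$db)
  shuffled <- fx$db
  shuffled$experiments <- rev(shuffled$experiments)
  shuffled$experiments <- lapply(shuffled$experiments, function(df) {
    df[rev(seq_len(nrow(df))), , drop = FALSE]
  })
  rep2 <- score_model(fx$model, shuffled)
  expect_identical(rep2$mse_tot, rep1$mse_tot)
})

test_that("cells without experimental data are flagged and excluded from the mean", {
  fx <- midas_fixture()
  partial <- fx$db
  partial$experiments[["Experiment02"]] <- NULL
  rep_full <- score_model(fx$model, fx$db)
  rep_part <- score_model(fx$model, partial)
  expect_lt(nrow(rep_part$cells[!rep_part$cells$missing, ]),
            nrow(rep_full$cells[!rep_full$cells$missing, ]))
  expect_identical(rep_part$mse_tot, 0)
})

test_that("score increases with generator noise, in expectation", {
  fx0 <- midas_fixture(noise_sd = 0.05, seed = 5L)
  fx1 <- midas_fixture(noise_sd = 0.35, seed = 5L)
  r0 <- score_model(fx0$model, fx0$db)
  r1 <- score_model(fx1$model, fx1$db)
  expect_lt(r0$mse_tot, r1$mse_tot)
})

test_that("render_score_report writes CSV and comparison grid", {
  fx <- midas_fixture(noise_sd = 0.1, seed = 3L)
  rep <- score_model(fx$model, fx$db)
  prefix <- file.path(tempdir(), "score_render")
  files <- render_score_report(rep, prefix)
  expect_true(all(file.exists(files)))
  expect_gt(file.size(files[[2]]), 0)
})
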