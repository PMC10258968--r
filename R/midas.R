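# MIDAS experimental database: parsing, collapsing, prediction, scoring ------

#' Define a treatment
#'
#' Maps a treatment name used in the experimental database to the model nodes
#' it affects and its effect type.
#'
#' @param name Treatment name (the `TR:` column suffix).
#' @param effect One of `"stimulation"`, `"inhibition"`, `"knockout"`.
#' @param nodes Character vector of target model node names (non-empty).
#' @return An object of class `treatment_def`.
#' @export
treatment_def <- function(name, effect, nodes) {
  effect <- match.arg(effect, c("stimulation", "inhibition", "knockout"))
  nodes <- as.character(nodes)
  if (length(nodes) == 0L || any(!nzchar(nodes))) {
    stop("treatment '", name, "' must target at least one node", call. = FALSE)
  }
  structure(list(name = name, effect = effect, nodes = nodes),
            class = "treatment_def")
}

#' Read a MIDAS-style experimental database
#'
#' Reads either a directory of CSV sheets (one per experiment, plus a
#' required `TreatmentDefs.csv` and an optional `OutputMap.csv`) or a
#' multi-sheet `.xlsx` workbook (requires the readxl package). Each
#' experiment sheet has treatment columns (prefix `TR:`, 0/1), acquisition
#' time columns (prefix `DA:`, either `DA:ALL` or one per readout) and
#' normalized data-value columns (prefix `DV:`, values in `[0, 1]`).
#' `TreatmentDefs` has columns `name`, `effect`, `nodes` (targets separated
#' by `;`); `OutputMap` has columns `readout`, `node` and defaults to the
#' identity (readout names are model node names).
#'
#' @param path Directory of CSV sheets, or an `.xlsx` workbook.
#' @return An object of class `experiment_db`: list with `experiments`
#'   (named list of tibbles), `treatments` (named list of [treatment_def()])
#'   and `output_map` (named character vector: readout -> model node).
#' @export
read_midas <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    names(files) <- sub("\\.csv$", "", basename(files))
    sheets <- lapply(files, function(f) {
      tibble::as_tibble(utils::read.csv(f, check.names = FALSE,
                                        stringsAsFactors = FALSE))
    })
  } else if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx workbooks requires the readxl package", call. = FALSE)
    }
    sheet_names <- readxl::excel_sheets(path)
    sheets <- lapply(sheet_names, function(s) readxl::read_excel(path, sheet = s))
    names(sheets) <- sheet_names
  } else {
    stop("no such database: ", path,
         " (expected a directory of CSV sheets or an .xlsx workbook)",
         call. = FALSE)
  }

  td_name <- grep("^treatmentdefs$", names(sheets), ignore.case = TRUE, value = TRUE)
  if (length(td_name) != 1L) {
    stop("database must contain exactly one TreatmentDefs sheet", call. = FALSE)
  }
  om_name <- grep("^outputmap$", names(sheets), ignore.case = TRUE, value = TRUE)

  td <- sheets[[td_name]]
  if (!all(c("name", "effect", "nodes") %in% names(td))) {
    stop("TreatmentDefs sheet must have columns name, effect, nodes",
         call. = FALSE)
  }
  treatments <- lapply(seq_len(nrow(td)), function(i) {
    targets <- trimws(strsplit(as.character(td$nodes[[i]]), ";", fixed = TRUE)[[1]])
    treatment_def(as.character(td$name[[i]]), as.character(td$effect[[i]]),
                  targets[nzchar(targets)])
  })
  names(treatments) <- vapply(treatments, `[[`, character(1), "name")

  experiments <- sheets[setdiff(names(sheets), c(td_name, om_name))]
  if (length(experiments) == 0L) {
    stop("database contains no experiment sheets", call. = FALSE)
  }
  readouts <- character(0)
  for (sheet in names(experiments)) {
    df <- experiments[[sheet]]
    prefixes <- sub(":.*$", "", names(df))
    bad <- !(prefixes %in% c("TR", "DA", "DV"))
    if (any(bad)) {
      stop(sprintf("sheet '%s': unknown column prefix in %s (expected TR:, DA:, DV:)",
                   sheet, paste(names(df)[bad], collapse = ", ")), call. = FALSE)
    }
    tr_names <- sub("^TR:", "", grep("^TR:", names(df), value = TRUE))
    missing_defs <- setdiff(tr_names, names(treatments))
    if (length(missing_defs) > 0L) {
      stop(sprintf("sheet '%s': treatment(s) with no TreatmentDefs entry: %s",
                   sheet, paste(missing_defs, collapse = ", ")), call. = FALSE)
    }
    dv_cols <- grep("^DV:", names(df), value = TRUE)
    for (cc in dv_cols) {
      vals <- as.numeric(df[[cc]])
      out_of_range <- which(!is.na(vals) & (vals < 0 | vals > 1))
      if (length(out_of_range) > 0L) {
        stop(sprintf(paste("sheet '%s', column '%s', row %d: value %g outside [0, 1];",
                           "normalization of the database is the user's responsibility"),
                     sheet, cc, out_of_range[[1]], vals[out_of_range[[1]]]),
             call. = FALSE)
      }
    }
    readouts <- union(readouts, sub("^DV:", "", dv_cols))
  }

  output_map <- stats::setNames(readouts, readouts)
  if (length(om_name) == 1L) {
    om <- sheets[[om_name]]
    if (!all(c("readout", "node") %in% names(om))) {
      stop("OutputMap sheet must have columns readout, node", call. = FALSE)
    }
    output_map[as.character(om$readout)] <- as.character(om$node)
  }

  structure(list(experiments = experiments, treatments = treatments,
                 output_map = output_map),
            class = "experiment_db")
}

#' @export
print.experiment_db <- function(x, ...) {
  cat(sprintf("MIDAS experiment database: %d experiment sheet(s), %d treatment(s), %d readout(s)\n",
              length(x$experiments), length(x$treatments), length(x$output_map)))
  invisible(x)
}

combo_id <- function(active) {
  if (length(active) == 0L) "(none)" else paste(sort(active), collapse = " + ")
}

# Long form of the merged database: one row per (sheet row, readout).
midas_long <- function(db) {
  pieces <- list()
  for (sheet in names(db$experiments)) {
    df <- db$experiments[[sheet]]
    tr_cols <- grep("^TR:", names(df), value = TRUE)
    dv_cols <- grep("^DV:", names(df), value = TRUE)
    for (i in seq_len(nrow(df))) {
      active <- sub("^TR:", "", tr_cols[vapply(tr_cols, function(cc) {
        isTRUE(as.numeric(df[[cc]][[i]]) == 1)
      }, logical(1))])
      for (cc in dv_cols) {
        readout <- sub("^DV:", "", cc)
        da_col <- if (paste0("DA:", readout) %in% names(df)) {
          paste0("DA:", readout)
        } else if ("DA:ALL" %in% names(df)) {
          "DA:ALL"
        } else {
          stop(sprintf("sheet '%s': no DA:ALL or DA:%s acquisition-time column",
                       sheet, readout), call. = FALSE)
        }
        val <- as.numeric(df[[cc]][[i]])
        if (is.na(val)) next
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          sheet = sheet, combo = combo_id(active),
          treatments = list(sort(active)), readout = readout,
          time = as.numeric(df[[da_col]][[i]]), value = val
        )
      }
    }
  }
  if (length(pieces) == 0L) {
    stop("database holds no data values", call. = FALSE)
  }
  dplyr::bind_rows(pieces)
}

#' Collapse timepoints to pre- and post-stimulation values
#'
#' Merges all experiment sheets and collapses each (perturbation combination,
#' readout) group to two values: `exp_pre`, the mean of all measurements at
#' `t = 0`, and `exp_post`, the mean of all measurements at `t > 0` —
#' optionally restricted to the given time bins.
#'
#' @param db An [read_midas()] database.
#' @param time_bins Optional: a numeric `c(lo, hi)` interval or a list of
#'   such intervals; post-stimulation measurements outside every bin are
#'   dropped (with a warning for groups left without post data).
#' @return A tibble with columns `combo`, `treatments` (list), `output`
#'   (readout name), `exp_pre`, `exp_post` (`NA` when no data).
#' @export
collapse_timepoints <- function(db, time_bins = NULL) {
  stopifnot(inherits(db, "experiment_db"))
  long <- midas_long(db)
  if (!is.null(time_bins) && !is.list(time_bins)) time_bins <- list(time_bins)
  in_bins <- function(t) {
    if (is.null(time_bins)) return(rep(TRUE, length(t)))
    Reduce(`|`, lapply(time_bins, function(b) t >= b[[1]] & t <= b[[2]]))
  }
  groups <- dplyr::group_by(long, .data$combo, .data$readout)
  out <- dplyr::summarise(
    groups,
    treatments = list(.data$treatments[[1]]),
    exp_pre = if (any(.data$time == 0)) mean(.data$value[.data$time == 0]) else NA_real_,
    exp_post = {
      post <- .data$time > 0 & in_bins(.data$time)
      if (any(post)) mean(.data$value[post]) else NA_real_
    },
    n_pre = sum(.data$time == 0),
    n_post = sum(.data$time > 0 & in_bins(.data$time)),
    .groups = "drop"
  )
  dropped <- out[is.na(out$exp_post) & !is.na(out$exp_pre), ]
  if (!is.null(time_bins) && nrow(dropped) > 0L) {
    warning("time bins exclude all post-stimulation data for: ",
            paste(paste0(dropped$combo, "/", dropped$readout), collapse = ", "),
            call. = FALSE)
  }
  out <- dplyr::rename(out, output = "readout")
  out[order(out$combo, out$output), ]
}

# Resolve the clamp sets of one perturbation combination.
combo_effects <- function(db, active) {
  defs <- db$treatments[active]
  targets <- function(effects) {
    unique(unlist(lapply(defs, function(d) {
      if (d$effect %in% effects) d$nodes else character(0)
    }), use.names = FALSE))
  }
  stim <- targets("stimulation")
  inhib <- targets("inhibition")
  ko <- targets("knockout")
  conflict <- intersect(stim, inhib)
  if (length(conflict) > 0L) {
    stop("combination '", combo_id(active),
         "' both stimulates and inhibits node(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  list(stim = stim, inhib = inhib, ko = ko)
}

# Pre-/post-stimulation prediction for one perturbation combination.
# Pre-stimulation: knocked-out and stimulated nodes forced OFF. Post: start
# from the canonical first state of the pre-stimulation attractor with
# inhibited and knocked-out nodes forced OFF and stimulated nodes forced ON.
predict_combo <- function(model, eff, output_nodes, init, max_steps = 100000L) {
  unknown <- setdiff(c(eff$stim, eff$inhib, eff$ko), model$nodes)
  if (length(unknown) > 0L) {
    stop("treatment target node(s) not in model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pre_cl <- clamps(off = union(eff$ko, eff$stim))
  pre_att <- attractor(simulate_path(model, init, pre_cl, max_steps))
  post_cl <- clamps(on = eff$stim, off = union(eff$inhib, eff$ko))
  post_att <- attractor(simulate_path(model, first_state(pre_att), post_cl,
                                      max_steps))
  list(pre_att = pre_att, post_att = post_att,
       sim_pre = quantify_attractor(pre_att, output_nodes),
       sim_post = quantify_attractor(post_att, output_nodes))
}

#' Model predictions for every perturbation combination in a database
#'
#' For each perturbation combination occurring in the database, simulates the
#' pre-stimulation condition (knockout and stimulation targets forced OFF)
#' from `init` to an attractor, then the post-stimulation condition
#' (inhibition and knockout targets OFF, stimulation targets ON) from the
#' pre-stimulation attractor's canonical first state, and quantifies each
#' mapped output over both attractors.
#'
#' @param model A [boolean_model()].
#' @param db An [read_midas()] database.
#' @param init Initial state; defaults to [neutral_state()].
#' @param max_steps Per-simulation tick bound.
#' @return A tibble with columns `combo`, `output`, `sim_pre`, `sim_post`.
#' @export
predict_responses <- function(model, db, init = NULL, max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"), inherits(db, "experiment_db"))
  if (is.null(init)) init <- neutral_state(model)
  long <- midas_long(db)
  combos <- dplyr::distinct(long[, c("combo", "treatments")])
  readouts <- sort(unique(long$readout))
  nodes <- db$output_map[readouts]
  unknown <- setdiff(nodes, model$nodes)
  if (length(unknown) > 0L) {
    stop("output map names node(s) not in model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    active <- combos$treatments[[i]]
    eff <- combo_effects(db, active)
    pred <- predict_combo(model, eff, unname(nodes), init, max_steps)
    tibble::tibble(combo = combos$combo[[i]], output = readouts,
                   sim_pre = unname(pred$sim_pre),
                   sim_post = unname(pred$sim_post))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$combo, out$output), ]
}

#' Per-cell mean squared error between experiment and simulation
#'
#' `((exp_pre - sim_pre)^2 + (exp_post - sim_post)^2) / 2`, ranging from 0
#' (perfect agreement) to 1 (perfect disagreement) when all inputs lie in
#' `[0, 1]`. A cell missing its pre or post experimental value is scored on
#' the available timepoint alone; a cell with neither is `NA`.
#'
#' @param exp_pre,exp_post,sim_pre,sim_post Numeric vectors in `[0, 1]`
#'   (experimental values may be `NA`).
#' @return Numeric vector of per-cell MSE values.
#' @export
mse_cell <- function(exp_pre, exp_post, sim_pre, sim_post) {
  d0 <- (exp_pre - sim_pre)^2
  d1 <- (exp_post - sim_post)^2
  n_avail <- (!is.na(d0)) + (!is.na(d1))
  total <- ifelse(is.na(d0), 0, d0) + ifelse(is.na(d1), 0, d1)
  ifelse(n_avail == 0L, NA_real_, total / n_avail)
}

#' Score a model against a MIDAS experimental database
#'
#' Composes [collapse_timepoints()], [predict_responses()] and [mse_cell()]:
#' each (perturbation combination, output) cell is scored by the mean squared
#' error between the collapsed experimental pre/post values and the simulated
#' pre/post predictions, and the total score is the mean over cells with
#' experimental data.
#'
#' @param model A [boolean_model()].
#' @param db An [read_midas()] database.
#' @param time_bins Optional post-stimulation time bins, see
#'   [collapse_timepoints()].
#' @param init Initial state; defaults to [neutral_state()].
#' @param max_steps Per-simulation tick bound.
#' @return A `score_report`: list with `cells` (tibble: combo, output,
#'   exp_pre, exp_post, sim_pre, sim_post, mse, missing flag) and `mse_tot`.
#' @export
score_model <- function(model, db, time_bins = NULL, init = NULL,
                        max_steps = 100000L) {
  collapsed <- collapse_timepoints(db, time_bins)
  preds <- predict_responses(model, db, init, max_steps)
  cells <- dplyr::full_join(collapsed[, c("combo", "output", "exp_pre", "exp_post")],
                            preds, by = c("combo", "output"))
  cells$mse <- mse_cell(cells$exp_pre, cells$exp_post,
                        cells$sim_pre, cells$sim_post)
  cells$missing <- is.na(cells$mse)
  mse_tot <- mean(cells$mse, na.rm = TRUE)
  structure(list(cells = cells, mse_tot = mse_tot,
                 n_combos = length(unique(cells$combo)),
                 n_outputs = length(unique(cells$output))),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Model-vs-database score: %d combination(s) x %d output(s), MSE_tot = %.4g\n",
              x$n_combos, x$n_outputs, x$mse_tot))
  invisible(x)
}

#' Render a score report as CSV and comparison grid
#'
#' Writes `<prefix>.csv` and `<prefix>.pdf`: a grid of perturbation
#' combinations (rows) by outputs (columns), cells shaded by MSE with the
#' experimental and simulated pre/post values printed; cells with no
#' experimental data are grey.
#'
#' @param report A `score_report` from [score_model()].
#' @param path_prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
render_score_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "score_report"))
  csv <- paste0(path_prefix, ".csv")
  utils::write.csv(as.data.frame(report$cells), csv, row.names = FALSE)
  pdf_path <- paste0(path_prefix, ".pdf")
  df <- report$cells
  df$label <- ifelse(df$missing, "no data",
                     sprintf("e: %.2f>%.2f\ns: %.2f>%.2f",
                             df$exp_pre, df$exp_post, df$sim_pre, df$sim_post))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$combo)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mse), color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.4) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey80",
                                 name = "MSE") +
    ggplot2::labs(x = "output", y = "perturbation combination",
                  title = sprintf("MSE_tot = %.4g", report$mse_tot)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(pdf_path, p,
                  width = 2.5 + 1.1 * report$n_outputs,
                  height = 1.5 + 0.6 * report$n_combos, limitsize = FALSE)
  invisible(c(csv, pdf_path))
}
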