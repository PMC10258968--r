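# Single-node inhibition / component knockout sensitivity --------------------

#' Ligand-induced response of output nodes
#'
#' The no-ligand attractor is obtained by simulating from `init` with the
#' ligand removed; the with-ligand attractor by adding the ligand to the
#' no-ligand attractor's first state and simulating again (the same round-1
#' procedure as [verify_model()]). The response delta of each output is the
#' difference of its attractor-averaged activity between the two conditions,
#' in `[-1, 1]`.
#'
#' @param model A [boolean_model()].
#' @param ligand A [ligand_spec()].
#' @param outputs Character vector of output node names.
#' @param init Initial state; defaults to [neutral_state()].
#' @param clamp A [clamps()] object (perturbations under study plus any
#'   standing on/off lists).
#' @param max_steps Per-simulation tick bound.
#' @return Named numeric vector of deltas, one per output.
#' @export
ligand_response <- function(model, ligand, outputs, init = NULL,
                            clamp = clamps(), max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"), inherits(ligand, "ligand_spec"))
  clamp <- check_clamps(model, clamp)
  if (is.null(init)) init <- neutral_state(model)
  no_lig <- attractor(simulate_path(
    model, remove_ligand(init, ligand, model), clamp, max_steps))
  with_lig <- attractor(simulate_path(
    model, add_ligand(first_state(no_lig), ligand), clamp, max_steps))
  quantify_attractor(with_lig, outputs) - quantify_attractor(no_lig, outputs)
}

component_knockout_clamps <- function(model, component) {
  off <- vapply(model$nodes, function(nd) {
    m <- model$meta[[nd]]
    component %in% m$components &&
      (m$node_class == "reaction" ||
         (m$node_class == "state" && !m$is_neutral))
  }, logical(1))
  clamps(off = model$nodes[off])
}

#' Sensitivity of the ligand response to single perturbations
#'
#' Quantifies how inhibiting each reaction node individually, and knocking
#' out each component individually (all of its reaction nodes and non-neutral
#' state nodes clamped OFF), changes the ligand-induced response of the
#' chosen outputs. The effect is the perturbed response delta minus the
#' unperturbed baseline delta, in `[-1, 1]`; the baseline row has effect 0 by
#' construction.
#'
#' @inheritParams ligand_response
#' @return A tibble of class `sensitivity_report` with columns `target`,
#'   `kind` (`"none"`, `"reaction"` or `"component"`), `output`,
#'   `baseline_delta`, `perturbed_delta` and `effect`.
#' @export
sensitivity_analysis <- function(model, ligand, outputs, init = NULL,
                                 clamp = clamps(), max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"))
  clamp <- check_clamps(model, clamp)
  baseline <- ligand_response(model, ligand, outputs, init, clamp, max_steps)

  reactions <- model$nodes[vapply(model$meta, function(m) {
    m$node_class == "reaction"
  }, logical(1))]
  components <- sort(unique(unlist(lapply(model$meta, `[[`, "components"),
                                   use.names = FALSE)))

  row_for <- function(target, kind, extra_off) {
    cl <- clamps(on = clamp$on, off = union(clamp$off, extra_off))
    delta <- ligand_response(model, ligand, outputs, init, cl, max_steps)
    tibble::tibble(target = target, kind = kind, output = outputs,
                   baseline_delta = unname(baseline),
                   perturbed_delta = unname(delta),
                   effect = unname(delta - baseline))
  }

  rows <- list(tibble::tibble(
    target = "(none)", kind = "none", output = outputs,
    baseline_delta = unname(baseline), perturbed_delta = unname(baseline),
    effect = 0
  ))
  for (r in reactions) {
    rows[[length(rows) + 1L]] <- row_for(r, "reaction", r)
  }
  for (comp in components) {
    ko <- component_knockout_clamps(model, comp)
    rows[[length(rows) + 1L]] <- row_for(comp, "component", ko$off)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Render a sensitivity report as CSV and heatmap
#'
#' Writes `<prefix>.csv` and `<prefix>.pdf` (targets x outputs, diverging
#' color scale on the effect).
#'
#' @param report A `sensitivity_report` from [sensitivity_analysis()].
#' @param path_prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
render_sensitivity <- function(report, path_prefix) {
  stopifnot(inherits(report, "sensitivity_report"))
  csv <- paste0(path_prefix, ".csv")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  pdf_path <- paste0(path_prefix, ".pdf")
  df <- as.data.frame(report)
  df$target <- factor(df$target, levels = rev(unique(df$target)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$target,
                                        fill = .data$effect)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1),
                                  name = "effect") +
    ggplot2::labs(x = "output", y = "inhibited / knocked out") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(pdf_path, p,
                  width = 2 + 0.7 * length(unique(df$output)),
                  height = 1.5 + 0.25 * nlevels(df$target), limitsize = FALSE)
  invisible(c(csv, pdf_path))
}
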