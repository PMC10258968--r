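# Exhaustive stimulus/inhibitor truth tables ---------------------------------

#' Simulate all stimulus/inhibitor combinations
#'
#' For each of the `2^n` subsets of the given `n` perturbations, active
#' stimuli are clamped ON and active inhibitors clamped OFF (inactive
#' perturbations are left unclamped), the model is simulated from `init`
#' until an attractor is reached, and each output's activity is averaged
#' across the attractor states, giving a score between 0 (always off) and 1
#' (always on).
#'
#' @param model A [boolean_model()].
#' @param stimuli,inhibitors Character vectors of perturbation node names.
#' @param outputs Character vector of output node names.
#' @param init Initial state; defaults to [neutral_state()].
#' @param max_n Cap on the number of perturbations (the table has `2^n`
#'   rows); exceeding it is an error — extract a module instead.
#' @param max_steps Per-simulation tick bound.
#' @return A `truth_table`: list with `perturbations` (tibble: name, kind),
#'   `assignments` (character matrix, rows x perturbations, values `"on"`,
#'   `"off"` or — after compression — `"any"`), `scores` (numeric matrix,
#'   rows x outputs) and `outputs`.
#' @export
truth_table <- function(model, stimuli = character(0),
                        inhibitors = character(0), outputs,
                        init = NULL, max_n = 12L, max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"))
  perts <- tibble::tibble(
    name = c(stimuli, inhibitors),
    kind = c(rep("stimulus", length(stimuli)),
             rep("inhibitor", length(inhibitors)))
  )
  if (anyDuplicated(perts$name)) {
    stop("duplicate perturbation node(s)", call. = FALSE)
  }
  unknown <- setdiff(c(perts$name, outputs), model$nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(perts)
  if (n > max_n) {
    stop(sprintf(paste("%d perturbations would require %s simulations;",
                       "raise max_n or extract a smaller module"),
                 n, format(2^n, big.mark = ",")), call. = FALSE)
  }
  if (is.null(init)) init <- neutral_state(model)

  grid <- if (n == 0L) {
    matrix(character(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(rep(list(c("off", "on")), n),
                          stringsAsFactors = FALSE))
  }
  colnames(grid) <- perts$name

  scores <- matrix(NA_real_, nrow = nrow(grid), ncol = length(outputs),
                   dimnames = list(NULL, outputs))
  for (i in seq_len(nrow(grid))) {
    active <- grid[i, ] == "on"
    cl <- clamps(on = perts$name[active & perts$kind == "stimulus"],
                 off = perts$name[active & perts$kind == "inhibitor"])
    att <- attractor(simulate_path(model, init, cl, max_steps))
    scores[i, ] <- quantify_attractor(att, outputs)
  }
  structure(list(perturbations = perts, assignments = grid,
                 scores = scores, outputs = outputs),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Truth table: %d perturbation(s), %d row(s), %d output(s)\n",
              nrow(x$perturbations), nrow(x$assignments), length(x$outputs)))
  print(utils::head(as.data.frame(truth_table_df(x)), 16L))
  invisible(x)
}

truth_table_df <- function(x, any_char = "any") {
  a <- x$assignments
  a[a == "any"] <- any_char
  tibble::as_tibble(cbind(
    tibble::as_tibble(a),
    tibble::as_tibble(x$scores)
  ))
}

#' Compress a truth table losslessly
#'
#' Greedy vertical compression: whenever one value of one perturbation makes
#' the model insensitive to all other perturbations (all rows carrying that
#' value have identical score vectors, and no already-merged row overlaps
#' them), those rows are merged into a single row with `"any"` in the other
#' perturbation columns. Repeats to a fixed point. The compression is
#' lossless: expanding the result reproduces the original `2^n` score map
#' exactly (see [expand_table()]).
#'
#' @param table A `truth_table`.
#' @return A `truth_table` with (possibly) fewer rows.
#' @export
compress_table <- function(table) {
  stopifnot(inherits(table, "truth_table"))
  a <- table$assignments
  s <- table$scores
  if (ncol(a) == 0L) return(table)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (p in colnames(a)) {
      for (v in c("on", "off")) {
        sel <- a[, p] == v
        if (sum(sel) < 2L) next
        # Rows outside the merge set must pin p to the opposite value,
        # otherwise the merged subcube would overlap them.
        if (any(a[!sel, p] == "any")) next
        score_rows <- unique(as.data.frame(s[sel, , drop = FALSE]))
        if (nrow(score_rows) != 1L) next
        merged_a <- matrix("any", nrow = 1L, ncol = ncol(a),
                           dimnames = list(NULL, colnames(a)))
        merged_a[1L, p] <- v
        a <- rbind(a[!sel, , drop = FALSE], merged_a)
        s <- rbind(s[!sel, , drop = FALSE],
                   s[which(sel)[[1L]], , drop = FALSE])
        changed <- TRUE
        break
      }
      if (changed) break
    }
  }
  structure(list(perturbations = table$perturbations, assignments = a,
                 scores = s, outputs = table$outputs),
            class = "truth_table")
}

#' Expand a (possibly compressed) truth table to concrete rows
#'
#' Replaces every `"any"` by both values, recovering one row per concrete
#' perturbation assignment. Rows are ordered deterministically by assignment.
#'
#' @param table A `truth_table`.
#' @return A `truth_table` whose rows are all concrete and cover each
#'   assignment exactly once.
#' @export
expand_table <- function(table) {
  stopifnot(inherits(table, "truth_table"))
  a <- table$assignments
  s <- table$scores
  out_a <- list()
  out_s <- list()
  for (i in seq_len(nrow(a))) {
    row <- a[i, , drop = TRUE]
    free <- names(row)[row == "any"]
    combos <- if (length(free) == 0L) {
      matrix(character(0), nrow = 1L, ncol = 0L)
    } else {
      as.matrix(expand.grid(rep(list(c("off", "on")), length(free)),
                            stringsAsFactors = FALSE))
    }
    for (j in seq_len(nrow(combos))) {
      full <- row
      if (length(free) > 0L) full[free] <- combos[j, ]
      out_a[[length(out_a) + 1L]] <- full
      out_s[[length(out_s) + 1L]] <- s[i, , drop = TRUE]
    }
  }
  a2 <- do.call(rbind, out_a)
  s2 <- do.call(rbind, out_s)
  if (ncol(a) == 0L) {
    a2 <- matrix(character(0), nrow = 1L, ncol = 0L)
    s2 <- s
  } else {
    key <- apply(a2, 1L, paste, collapse = "|")
    if (anyDuplicated(key)) {
      stop("expanded rows cover some assignments more than once", call. = FALSE)
    }
    ord <- order(key)
    a2 <- a2[ord, , drop = FALSE]
    s2 <- s2[ord, , drop = FALSE]
    colnames(a2) <- colnames(a)
  }
  colnames(s2) <- colnames(s)
  structure(list(perturbations = table$perturbations, assignments = a2,
                 scores = s2, outputs = table$outputs),
            class = "truth_table")
}

#' Render a truth table as CSV and a matrix-style figure
#'
#' Writes `<prefix>.csv` (one row per table row, perturbation columns then
#' output scores; `"any"` cells rendered as `"*"`) and `<prefix>.pdf`, a
#' matrix plot with perturbation assignments on the left and output scores
#' shaded 0-1 on the right.
#'
#' @param table A `truth_table`.
#' @param path_prefix Output path prefix.
#' @return Paths of the files written, invisibly.
#' @export
render_truth_table <- function(table, path_prefix) {
  stopifnot(inherits(table, "truth_table"))
  df <- truth_table_df(table, any_char = "*")
  csv <- paste0(path_prefix, ".csv")
  utils::write.csv(as.data.frame(df), csv, row.names = FALSE)

  pdf_path <- paste0(path_prefix, ".pdf")
  long <- truth_table_long(table)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), color = "grey40") +
    ggplot2::geom_text(data = long[long$label != "", ],
                       ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), na.value = "grey85",
                                 name = "score") +
    ggplot2::scale_y_reverse(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "combination") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(pdf_path, p, width = 2 + 0.6 * nlevels(long$column),
                  height = 1.5 + 0.3 * nrow(table$assignments), limitsize = FALSE)
  invisible(c(csv, pdf_path))
}

truth_table_long <- function(table) {
  a <- table$assignments
  s <- table$scores
  cols <- c(colnames(a), colnames(s))
  rows <- seq_len(nrow(s))
  pieces <- list()
  for (j in seq_len(ncol(a))) {
    v <- a[, j]
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      row = rows, column = colnames(a)[[j]],
      value = ifelse(v == "on", 1, ifelse(v == "off", 0, NA_real_)),
      label = ifelse(v == "any", "*", "")
    )
  }
  for (j in seq_len(ncol(s))) {
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      row = rows, column = colnames(s)[[j]], value = s[, j], label = ""
    )
  }
  out <- dplyr::bind_rows(pieces)
  out$column <- factor(out$column, levels = cols)
  out
}
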