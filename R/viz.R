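# Trajectory plots, trajectory alignment, regulatory graph export ------------

#' Plot a trajectory as a node-by-tick matrix
#'
#' Rows are nodes, columns are synchronous ticks; ON cells are blue, OFF
#' cells white. Attractor ticks are hatched by a darker border and marked by
#' a dashed line where the cycle begins.
#'
#' @param traj A `boolean_trajectory` from [simulate_path()], or the path of
#'   a trajectory CSV in the [write_trajectory_csv()] dialect.
#' @param out Optional output figure path (extension selects the device,
#'   e.g. `.pdf` or `.png`).
#' @return The ggplot object, invisibly.
#' @export
plot_trajectory <- function(traj, out = NULL) {
  if (is.character(traj)) traj <- read_trajectory_csv(traj)
  stopifnot(inherits(traj, "boolean_trajectory"))
  if (ncol(traj$states) == 0L || nrow(traj$states) == 0L) {
    stop("empty trajectory", call. = FALSE)
  }
  df <- tidyr::pivot_longer(
    tibble::as_tibble(traj$states * 1L, rownames = "node"),
    -"node", names_to = "tick", values_to = "on"
  )
  df$tick <- as.integer(df$tick)
  df$node <- factor(df$node, levels = rev(rownames(traj$states)))
  df$in_attractor <- df$tick >= traj$attractor_start - 1L
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tick, y = .data$node)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$on),
                                    color = .data$in_attractor),
                       linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "steelblue"),
                               name = NULL, labels = c(`0` = "off", `1` = "on")) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey80", `TRUE` = "grey30"),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = traj$attractor_start - 1.5,
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "tick", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 2 + 0.35 * ncol(traj$states),
                    height = 1 + 0.22 * nrow(traj$states), limitsize = FALSE)
  }
  invisible(p)
}

#' Align two trajectories for comparison
#'
#' Left-pads the shorter transient so both transients end at the same tick,
#' rotates the second trajectory's attractor cycle to the phase minimizing
#' the Hamming distance to the first (cycles are extended to the least
#' common multiple of their lengths), and takes the union of the node sets,
#' flagging nodes present in only one trajectory.
#'
#' @param a,b `boolean_trajectory` objects with overlapping node sets.
#' @return A `trajectory_alignment`: list with `nodes`, matrices `a` and `b`
#'   (NA where a trajectory lacks a node or a padded tick), `agreement`
#'   (logical matrix; `TRUE` iff both values present and equal),
#'   `attractor_start`, and the chosen phase `shift`.
#' @export
align_trajectories <- function(a, b) {
  stopifnot(inherits(a, "boolean_trajectory"), inherits(b, "boolean_trajectory"))
  common <- intersect(rownames(a$states), rownames(b$states))
  if (length(common) == 0L) {
    stop("trajectories share no nodes", call. = FALSE)
  }
  nodes <- union(rownames(a$states), rownames(b$states))

  split_traj <- function(tr) {
    list(trans = tr$states[, seq_len(tr$attractor_start - 1L), drop = FALSE],
         cycle = tr$states[, tr$attractor_start:ncol(tr$states), drop = FALSE])
  }
  sa <- split_traj(a)
  sb <- split_traj(b)

  # Phase alignment on the common nodes: minimize mean Hamming distance over
  # all rotations of b's cycle (both cycles extended to the LCM length).
  la <- ncol(sa$cycle)
  lb <- ncol(sb$cycle)
  L <- lcm_int(la, lb)
  ca <- sa$cycle[common, rep(seq_len(la), length.out = L), drop = FALSE]
  cb <- sb$cycle[common, rep(seq_len(lb), length.out = L), drop = FALSE]
  dists <- vapply(seq_len(L) - 1L, function(s) {
    idx <- ((seq_len(L) - 1L + s) %% L) + 1L
    mean(ca != cb[, idx, drop = FALSE])
  }, numeric(1))
  shift <- which.min(dists) - 1L
  idx <- ((seq_len(L) - 1L + shift) %% L) + 1L

  n_trans <- max(ncol(sa$trans), ncol(sb$trans))
  expand <- function(tr, trans, cycle, cycle_idx) {
    m <- matrix(NA, nrow = length(nodes), ncol = n_trans + L,
                dimnames = list(nodes, NULL))
    present <- rownames(tr$states)
    if (ncol(trans) > 0L) {
      m[present, (n_trans - ncol(trans) + 1L):n_trans] <- trans[present, ]
    }
    m[present, n_trans + seq_len(L)] <- cycle[present, cycle_idx, drop = FALSE]
    m
  }
  ma <- expand(a, sa$trans, sa$cycle[, rep(seq_len(la), length.out = L),
                                     drop = FALSE], seq_len(L))
  mb <- expand(b, sb$trans, sb$cycle[, rep(seq_len(lb), length.out = L),
                                     drop = FALSE], idx)
  colnames(ma) <- colnames(mb) <- as.character(seq_len(n_trans + L) - 1L)
  agreement <- !is.na(ma) & !is.na(mb) & (ma == mb)
  structure(list(nodes = nodes, a = ma, b = mb, agreement = agreement,
                 attractor_start = n_trans + 1L, shift = shift,
                 distance = min(dists)),
            class = "trajectory_alignment")
}

#' Plot an overlay of two aligned trajectories
#'
#' Cells where the two trajectories agree are shown in the usual on/off
#' colors; disagreements are red; ticks or nodes absent from one trajectory
#' are grey.
#'
#' @param alignment A `trajectory_alignment` from [align_trajectories()].
#' @param out Optional output figure path.
#' @return The ggplot object, invisibly.
#' @export
plot_alignment <- function(alignment, out = NULL) {
  stopifnot(inherits(alignment, "trajectory_alignment"))
  status <- matrix("missing", nrow = nrow(alignment$a), ncol = ncol(alignment$a),
                   dimnames = dimnames(alignment$a))
  both <- !is.na(alignment$a) & !is.na(alignment$b)
  status[both & alignment$a & alignment$b] <- "both on"
  status[both & !alignment$a & !alignment$b] <- "both off"
  status[both & (alignment$a != alignment$b)] <- "disagree"
  df <- tidyr::pivot_longer(
    tibble::as_tibble(status, rownames = "node"),
    -"node", names_to = "tick", values_to = "status"
  )
  df$tick <- as.integer(df$tick)
  df$node <- factor(df$node, levels = rev(rownames(alignment$a)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tick, y = .data$node,
                                        fill = .data$status)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = c(`both on` = "steelblue",
                                          `both off` = "white",
                                          disagree = "firebrick",
                                          missing = "grey85"), name = NULL) +
    ggplot2::geom_vline(xintercept = alignment$attractor_start - 1.5,
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "tick", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 2 + 0.35 * ncol(alignment$a),
                    height = 1 + 0.22 * nrow(alignment$a), limitsize = FALSE)
  }
  invisible(p)
}

# Regulatory-graph edges derived from rule structure. Reactions produce
# (positive) or consume (negative) the states whose rules they appear in;
# states regulate (positively or negatively) the reactions whose rules they
# appear in. Self-loops (a state rule holding its own value) are structural
# and omitted.
regulatory_edges <- function(model) {
  classes <- vapply(model$meta, `[[`, character(1), "node_class")
  rows <- list()
  for (target in model$nodes) {
    pol <- rule_polarity(model$rules[[target]])
    for (src in names(pol)) {
      if (src == target) next
      sc <- classes[[src]]
      tc <- classes[[target]]
      type <- if (sc == "reaction" && tc == "state") {
        if (pol[[src]] >= 0L) "produce" else "consume"
      } else if (sc %in% c("state", "input") && tc == "reaction") {
        if (pol[[src]] >= 0L) "activate" else "inhibit"
      } else {
        "influence"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = src, to = target, type = type, sign = pol[[src]]
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(from = character(0), to = character(0),
                          type = character(0), sign = integer(0)))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Export the regulatory graph of a model
#'
#' Writes the static bipartite reaction/state graph with node-class
#' attributes and edge types derived from the rule structure: reactions
#' produce or consume states; states activate or inhibit reactions. Layout
#' is left to the consumer; the file carries attributes only.
#'
#' @param model A [boolean_model()].
#' @param out Output file path.
#' @param format `"xgmml"` or `"graphml"`.
#' @return `out`, invisibly.
#' @export
export_regulatory_graph <- function(model, out, format = c("xgmml", "graphml")) {
  stopifnot(inherits(model, "boolean_model"))
  format <- match.arg(format)
  edges <- regulatory_edges(model)
  nodes <- tibble::tibble(
    id = model$nodes,
    node_class = vapply(model$meta, `[[`, character(1), "node_class"),
    modules = vapply(model$meta, function(m) {
      paste(m$modules, collapse = ",")
    }, character(1))
  )
  if (format == "xgmml") {
    write_xgmml(nodes, edges, out, label = "regulatory graph",
                node_atts = c("node_class", "modules"), edge_atts = "type")
  } else {
    write_graphml(nodes, edges, out)
  }
  invisible(out)
}

#' Export one regulatory graph per annotated module
#'
#' Extracts every module tag found in the annotation table with
#' [extract_module()] and writes its regulatory graph to
#' `<dir>/module_<tag>.<ext>`.
#'
#' @param model A [boolean_model()].
#' @param annotations Annotation table, see [read_annotations()].
#' @param dir Output directory (created if needed).
#' @param format `"xgmml"` or `"graphml"`.
#' @return Named character vector of the files written, invisibly.
#' @export
export_module_graphs <- function(model, annotations, dir,
                                 format = c("xgmml", "graphml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tags <- sort(unique(unlist(annotations$modules, use.names = FALSE)))
  out <- vapply(tags, function(tag) {
    sub_model <- extract_module(model, annotations, tag)
    f <- file.path(dir, sprintf("module_%s.%s", gsub("[^A-Za-z0-9_-]", "_", tag),
                                format))
    export_regulatory_graph(sub_model, f, format)
    f
  }, character(1))
  invisible(out)
}

#' Export per-tick animation frames of a trajectory
#'
#' Writes one numbered image of the regulatory graph per trajectory tick,
#' nodes colored by their ON/OFF value at that tick, plus one state-annotated
#' GraphML file per tick. A fixed seeded layout keeps node positions
#' identical across frames.
#'
#' @param model A [boolean_model()].
#' @param traj A `boolean_trajectory` over the model's nodes.
#' @param out_dir Output directory (created if needed).
#' @param image_format `"png"` or `"pdf"`.
#' @return Character vector of the image frames written, invisibly.
#' @export
export_animation_frames <- function(model, traj, out_dir,
                                    image_format = c("png", "pdf")) {
  stopifnot(inherits(model, "boolean_model"),
            inherits(traj, "boolean_trajectory"))
  image_format <- match.arg(image_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- regulatory_edges(model)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[, c("from", "to", "type")]),
    directed = TRUE,
    vertices = data.frame(name = model$nodes)
  )
  set.seed(1L)
  layout <- igraph::layout_with_fr(g)
  classes <- vapply(model$meta, `[[`, character(1), "node_class")
  shapes <- ifelse(classes == "reaction", "square", "circle")

  frames <- character(ncol(traj$states))
  for (t in seq_len(ncol(traj$states))) {
    state <- traj$states[, t]
    frame <- file.path(out_dir, sprintf("frame_%03d.%s", t, image_format))
    if (image_format == "png") {
      grDevices::png(frame, width = 900, height = 700)
    } else {
      grDevices::pdf(frame, width = 9, height = 7)
    }
    igraph::plot.igraph(
      g, layout = layout,
      vertex.color = ifelse(state[model$nodes], "steelblue", "white"),
      vertex.shape = shapes[model$nodes], vertex.label.cex = 0.7,
      edge.arrow.size = 0.4,
      main = sprintf("tick %d%s", t - 1L,
                     if (t >= traj$attractor_start) " (attractor)" else "")
    )
    grDevices::dev.off()
    frames[[t]] <- frame

    gg <- igraph::set_vertex_attr(g, "active",
                                  value = as.integer(state[model$nodes]))
    igraph::write_graph(gg, file.path(out_dir, sprintf("frame_%03d.graphml", t)),
                        format = "graphml")
  }
  invisible(frames)
}
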