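# Ligand cycling and meta-attractor verification -----------------------------

#' Designate a ligand by its unbound presence node(s)
#'
#' A ligand is identified by the state node(s) marking its unbound presence in
#' the system (e.g. `"L_[lig]--0"`). The ligand's component names are derived
#' from the node metadata; bound states involving those components are
#' discovered automatically when the ligand is removed.
#'
#' @param model A [boolean_model()].
#' @param nodes Character vector of ligand presence node names.
#' @return An object of class `ligand_spec` with elements `nodes` and
#'   `components`.
#' @export
ligand_spec <- function(model, nodes) {
  stopifnot(inherits(model, "boolean_model"))
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, model$nodes)
  if (length(unknown) > 0L) {
    stop("ligand node(s) not in model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  comps <- unique(unlist(lapply(model$meta[nodes], `[[`, "components"),
                         use.names = FALSE))
  structure(list(nodes = nodes, components = comps), class = "ligand_spec")
}

#' Remove the ligand from a state
#'
#' Turns all ligand presence nodes OFF. Any non-neutral state node involving a
#' ligand component that is ON is also turned OFF, and — for bond states — the
#' partner component's unbound (neutral) node is turned ON so that the partner
#' remains in the system. All other nodes are untouched.
#'
#' @param state Named logical state vector.
#' @param ligand A [ligand_spec()].
#' @param model The [boolean_model()] the state belongs to.
#' @return The modified state.
#' @export
remove_ligand <- function(state, ligand, model) {
  stopifnot(inherits(ligand, "ligand_spec"))
  state <- check_state(model, state)
  state[ligand$nodes] <- FALSE
  for (nd in model$nodes) {
    m <- model$meta[[nd]]
    if (m$node_class != "state" || m$is_neutral) next
    if (length(intersect(m$components, ligand$components)) == 0L) next
    if (!state[[nd]]) next
    state[[nd]] <- FALSE
    # bound_partner maps each component of a bond to the *other* component's
    # neutral node; looking it up for the ligand component(s) yields the
    # partner's own unbound state, which must come back ON so the partner
    # stays in the system.
    bp <- m$bound_partner
    lig_side <- intersect(names(bp), ligand$components)
    partner_side <- setdiff(names(bp), ligand$components)
    if (length(partner_side) > 0L) {
      for (neutral in unname(bp[lig_side])) {
        if (!(neutral %in% model$nodes)) {
          stop(sprintf("bond node '%s': partner neutral node '%s' absent from model",
                       nd, neutral), call. = FALSE)
        }
        state[[neutral]] <- TRUE
      }
    }
  }
  state
}

#' Add the ligand to a state
#'
#' Turns the ligand's unbound presence node(s) ON; nothing else changes.
#' Idempotent.
#'
#' @inheritParams remove_ligand
#' @return The modified state.
#' @export
add_ligand <- function(state, ligand) {
  stopifnot(inherits(ligand, "ligand_spec"))
  state[ligand$nodes] <- TRUE
  state
}

#' Verify model consistency under ligand cycling
#'
#' Maps the attractor space reachable by repeatedly adding and removing a
#' ligand, in three steps. (1) The network is simulated from `init` (default:
#' the rxncon neutral state) with the ligand removed, until it reaches the
#' initial no-ligand attractor; the ligand is then added to that attractor's
#' first state and the initial with-ligand attractor determined. (2) From
#' *every* state of the current attractor, the opposite ligand transform is
#' applied and the network simulated to an attractor; if the resulting
#' attractors are not all equal, the destination depends on the intra-cycle
#' state at which the ligand event occurred ("branching") and the rounds stop.
#' (3) Rounds alternate until the (no-ligand, with-ligand) attractor pair
#' repeats a previously seen pair, at which point a meta-attractor — a cycle
#' through attractor space driven by ligand addition/removal — has been found.
#'
#' The result is *consistent* when no branching occurred and the ligand
#' response is reversible, i.e. all no-ligand attractors are equal and all
#' with-ligand attractors are equal (a simple two-attractor meta-attractor).
#' A model that halts in a meta-attractor excluding its initial no-ligand
#' attractor is caught in a "trap" (e.g. a substrate that stays phosphorylated
#' after ligand removal because no dephosphorylation reaction exists) and is
#' reported as inconsistent with `trap = TRUE`.
#'
#' @param model A [boolean_model()].
#' @param ligand A [ligand_spec()].
#' @param init Initial state; defaults to [neutral_state()].
#' @param clamp A [clamps()] object; clamps are re-applied after every ligand
#'   transform so forced nodes cannot be flipped by it.
#' @param max_rounds Maximum number of attractor simulation rounds.
#' @param max_steps Per-simulation tick bound, see [simulate_path()].
#' @return A `meta_attractor_graph`: list with `attractors` (tibble: id,
#'   label, cycle length, attractor objects), `edges` (tibble: from, to,
#'   transition, source_state_index), `consistent`, `branching`, `trap`,
#'   `meta_attractor` (ordered attractor-id cycle, or `NULL`),
#'   `trajectories` (all simulation trajectories, labeled), and
#'   `state_edges` (ligand-transform transitions between packed states).
#' @export
verify_model <- function(model, ligand, init = NULL, clamp = clamps(),
                         max_rounds = 50L, max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"), inherits(ligand, "ligand_spec"))
  clamp <- check_clamps(model, clamp)
  if (is.null(init)) init <- neutral_state(model)
  init <- check_state(model, init)

  registry <- new.env(parent = emptyenv(), hash = TRUE)
  atts <- list()
  labels <- character(0)
  edges <- list()
  state_edges <- list()
  trajectories <- list()

  register <- function(att, label) {
    key <- paste(label, attractor_key(att), sep = "::")
    id <- registry[[key]]
    if (is.null(id)) {
      prefix <- if (label == "no-ligand") "N" else "W"
      id <- paste0(prefix, sum(labels == label) + 1L)
      registry[[key]] <- id
      atts[[id]] <<- att
      labels <<- c(labels, stats::setNames(label, id))
    }
    id
  }
  add_edge <- function(from, to, transition, src) {
    edges[[length(edges) + 1L]] <<- tibble::tibble(
      from = from, to = to, transition = transition,
      source_state_index = as.integer(src)
    )
  }
  run <- function(start, phase, round) {
    start <- apply_clamps(start, clamp)
    tr <- simulate_path(model, start, clamp, max_steps)
    trajectories[[length(trajectories) + 1L]] <<-
      list(trajectory = tr, phase = phase, round = round)
    attractor(tr)
  }
  # Simulate from every state of `att` after applying `transform`; returns the
  # per-state destination attractors plus the transform edges in state space.
  fan_out <- function(att, transform, phase, round) {
    lapply(seq_len(ncol(att$cycle)), function(j) {
      src <- stats::setNames(att$cycle[, j], rownames(att$cycle))
      dst_state <- apply_clamps(transform(src), clamp)
      state_edges[[length(state_edges) + 1L]] <<- tibble::tibble(
        from = pack_state(src), to = pack_state(dst_state),
        transition = if (phase == "no-ligand") "remove" else "add"
      )
      run(dst_state, phase, round)
    })
  }
  finish <- function(branching, meta_cycle) {
    no_ids <- names(labels)[labels == "no-ligand"]
    with_ids <- names(labels)[labels == "with-ligand"]
    trap <- !branching && (length(no_ids) > 1L || length(with_ids) > 1L)
    structure(list(
      attractors = tibble::tibble(
        id = names(labels),
        label = unname(labels),
        cycle_length = vapply(atts[names(labels)], function(a) ncol(a$cycle),
                              integer(1)),
        attractor = unname(atts[names(labels)])
      ),
      edges = if (length(edges)) dplyr::bind_rows(edges) else
        tibble::tibble(from = character(0), to = character(0),
                       transition = character(0),
                       source_state_index = integer(0)),
      consistent = !branching && !trap,
      branching = branching,
      trap = trap,
      meta_attractor = meta_cycle,
      trajectories = trajectories,
      state_edges = if (length(state_edges)) dplyr::bind_rows(state_edges) else
        tibble::tibble(from = character(0), to = character(0),
                       transition = character(0)),
      ligand = ligand, clamps = clamp
    ), class = "meta_attractor_graph")
  }

  # Step 1: initial no-ligand and with-ligand attractors.
  A <- run(remove_ligand(init, ligand, model), "no-ligand", 0L)
  aid <- register(A, "no-ligand")
  B <- run(add_ligand(first_state(A), ligand), "with-ligand", 0L)
  bid <- register(B, "with-ligand")
  state_edges[[length(state_edges) + 1L]] <- tibble::tibble(
    from = pack_state(first_state(A)),
    to = pack_state(apply_clamps(add_ligand(first_state(A), ligand), clamp)),
    transition = "add"
  )
  add_edge(aid, bid, "add", 1L)
  pair_seq <- list(c(aid, bid))
  seen_pairs <- paste(aid, bid, sep = "|")

  cur <- B
  cur_id <- bid
  for (round in seq_len(max_rounds)) {
    # Remove phase: ligand off from every with-ligand attractor state.
    res <- fan_out(cur, function(s) remove_ligand(s, ligand, model),
                   "no-ligand", round)
    ids <- vapply(res, register, character(1), label = "no-ligand")
    if (length(unique(ids)) > 1L) {
      for (j in seq_along(ids)) add_edge(cur_id, ids[[j]], "remove", j)
      return(finish(branching = TRUE, meta_cycle = NULL))
    }
    A <- res[[1L]]
    aid <- ids[[1L]]
    add_edge(cur_id, aid, "remove", 1L)

    # Add phase: ligand on from every no-ligand attractor state.
    res <- fan_out(A, function(s) add_ligand(s, ligand), "with-ligand", round)
    ids <- vapply(res, register, character(1), label = "with-ligand")
    if (length(unique(ids)) > 1L) {
      for (j in seq_along(ids)) add_edge(aid, ids[[j]], "add", j)
      return(finish(branching = TRUE, meta_cycle = NULL))
    }
    B <- res[[1L]]
    bid <- ids[[1L]]
    add_edge(aid, bid, "add", 1L)

    pair <- paste(aid, bid, sep = "|")
    if (pair %in% seen_pairs) {
      i0 <- which(seen_pairs == pair)[[1L]]
      cyc <- unlist(lapply(pair_seq[i0:length(pair_seq)], identity),
                    use.names = FALSE)
      return(finish(branching = FALSE, meta_cycle = cyc))
    }
    seen_pairs <- c(seen_pairs, pair)
    pair_seq <- c(pair_seq, list(c(aid, bid)))
    cur <- B
    cur_id <- bid
  }
  stop(sprintf("no meta-attractor found within max_rounds = %d rounds", max_rounds),
       call. = FALSE)
}

#' @export
print.meta_attractor_graph <- function(x, ...) {
  cat("Meta-attractor verification\n")
  cat(sprintf("  attractors found: %d (%d no-ligand, %d with-ligand)\n",
              nrow(x$attractors), sum(x$attractors$label == "no-ligand"),
              sum(x$attractors$label == "with-ligand")))
  if (x$consistent) {
    cat("  verdict: CONSISTENT - reversible meta-attractor:",
        paste(x$meta_attractor, collapse = " -> "), "\n")
  } else if (x$branching) {
    cat("  verdict: INCONSISTENT - branching: the destination attractor depends",
        "on the intra-attractor state at the ligand event\n")
  } else {
    cat("  verdict: INCONSISTENT - trap: the system does not return to its",
        "initial attractor after ligand removal\n")
  }
  invisible(x)
}

#' Export verification state-space and attractor-space graphs
#'
#' Writes two graphs: the Boolean state graph traversed during verification
#' (nodes are states, step edges plus attribute-tagged ligand-addition/removal
#' edges, attractor states flagged) and the attractor-space graph (nodes are
#' attractors, edges are ligand transitions). Both XGMML and GraphML dialects
#' are supported.
#'
#' @param result A `meta_attractor_graph` from [verify_model()].
#' @param path_prefix Output path prefix; files `<prefix>_states.<ext>` and
#'   `<prefix>_attractors.<ext>` are written.
#' @param format `"xgmml"` or `"graphml"`.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_state_graph <- function(result, path_prefix,
                               format = c("xgmml", "graphml")) {
  stopifnot(inherits(result, "meta_attractor_graph"))
  format <- match.arg(format)

  att_states <- unique(unlist(lapply(result$attractors$attractor, function(a) {
    apply(a$cycle, 2L, pack_state)
  }), use.names = FALSE))

  step_edges <- dplyr::bind_rows(lapply(result$trajectories, function(tr) {
    keys <- apply(tr$trajectory$states, 2L, pack_state)
    n <- length(keys)
    # Close the cycle: the last state maps back to the attractor start.
    tibble::tibble(
      from = keys[c(seq_len(n - 1L), n)],
      to = c(keys[-1L], keys[[tr$trajectory$attractor_start]]),
      transition = "step"
    )
  }))
  all_edges <- dplyr::distinct(dplyr::bind_rows(step_edges, result$state_edges))
  nodes <- tibble::tibble(id = unique(c(all_edges$from, all_edges$to)))
  nodes$is_attractor <- nodes$id %in% att_states

  att_nodes <- tibble::tibble(id = result$attractors$id,
                              label = result$attractors$label,
                              cycle_length = result$attractors$cycle_length)
  att_edges <- dplyr::distinct(result$edges[, c("from", "to", "transition")])

  ext <- format
  f_states <- paste0(path_prefix, "_states.", ext)
  f_atts <- paste0(path_prefix, "_attractors.", ext)
  if (format == "xgmml") {
    write_xgmml(nodes, all_edges, f_states, label = "state space",
                node_atts = "is_attractor", edge_atts = "transition")
    write_xgmml(att_nodes, att_edges, f_atts, label = "attractor space",
                node_atts = c("label", "cycle_length"), edge_atts = "transition")
  } else {
    write_graphml(nodes, all_edges, f_states)
    write_graphml(att_nodes, att_edges, f_atts)
  }
  invisible(c(f_states, f_atts))
}

# Minimal XGMML writer (directed graph, string/boolean/integer node and edge
# attributes).
write_xgmml <- function(nodes, edges, path, label = "graph",
                        node_atts = character(0), edge_atts = character(0)) {
  doc <- xml2::xml_new_root("graph", label = label, directed = "1",
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  att_type <- function(v) {
    if (is.logical(v)) "boolean" else if (is.numeric(v)) "integer" else "string"
  }
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(doc, "node", id = nodes$id[[i]],
                              label = nodes$id[[i]])
    for (a in node_atts) {
      xml2::xml_add_child(nd, "att", name = a, type = att_type(nodes[[a]]),
                          value = as.character(nodes[[a]][[i]]))
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(doc, "edge", source = edges$from[[i]],
                              target = edges$to[[i]])
    for (a in edge_atts) {
      xml2::xml_add_child(ed, "att", name = a, type = att_type(edges[[a]]),
                          value = as.character(edges[[a]][[i]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

write_graphml <- function(nodes, edges, path) {
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges), directed = TRUE,
    vertices = as.data.frame(nodes)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
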