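# Synchronous simulation, attractors, and attractor comparison ---------------

#' Clamped-node sets
#'
#' Clamps model stimuli, inhibitors and knockouts: `on` nodes are forced ON
#' and `off` nodes forced OFF at the initial state and after every synchronous
#' update tick, so clamped values are invariant along a trajectory.
#'
#' @param on,off Character vectors of node names (disjoint).
#' @return An object of class `clamp_set`.
#' @export
clamps <- function(on = character(0), off = character(0)) {
  on <- unique(as.character(on))
  off <- unique(as.character(off))
  both <- intersect(on, off)
  if (length(both) > 0L) {
    stop("node(s) clamped both ON and OFF: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  structure(list(on = on, off = off), class = "clamp_set")
}

check_clamps <- function(model, cl) {
  if (!inherits(cl, "clamp_set")) cl <- do.call(clamps, as.list(cl))
  unknown <- setdiff(c(cl$on, cl$off), model$nodes)
  if (length(unknown) > 0L) {
    stop("clamp names unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cl
}

apply_clamps <- function(state, cl) {
  state[cl$on] <- TRUE
  state[cl$off] <- FALSE
  state
}

pack_state <- function(state) paste(as.integer(state), collapse = "")

#' One synchronous update step
#'
#' Every node's next value is its Boolean rule evaluated on the current state;
#' clamped nodes are then overwritten. Deterministic.
#'
#' @param model A [boolean_model()].
#' @param state Named (or model-ordered) logical vector.
#' @param clamp A [clamps()] object.
#' @return The successor state (named logical vector).
#' @export
state_transition <- function(model, state, clamp = clamps()) {
  state <- check_state(model, state)
  clamp <- check_clamps(model, clamp)
  nxt <- model$step_fun(unname(state))
  names(nxt) <- model$nodes
  apply_clamps(nxt, clamp)
}

#' Simulate until an attractor is reached
#'
#' Iterates [state_transition()] from `init` (clamps applied to the initial
#' state first), recording visited states, and stops at the first revisited
#' state. Because synchronous dynamics are deterministic, the segment from the
#' first occurrence of the revisited state to the end of the recorded
#' trajectory is the attractor cycle.
#'
#' @param model A [boolean_model()].
#' @param init Initial state; defaults to [neutral_state()].
#' @param clamp A [clamps()] object.
#' @param max_steps Upper bound on simulation ticks before giving up
#'   (a revisit is guaranteed whenever `max_steps > 2^n`).
#' @return A `boolean_trajectory`: list with `states` (logical matrix, nodes
#'   as rows, ticks as columns), `attractor_start` (1-based column index of
#'   the first cycle state) and `clamps`.
#' @export
simulate_path <- function(model, init = NULL, clamp = clamps(),
                          max_steps = 100000L) {
  stopifnot(inherits(model, "boolean_model"))
  if (max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  clamp <- check_clamps(model, clamp)
  if (is.null(init)) init <- neutral_state(model)
  state <- apply_clamps(check_state(model, init), clamp)

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", 64L)
  t <- 0L
  attractor_start <- NA_integer_
  repeat {
    key <- pack_state(state)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      attractor_start <- prev
      break
    }
    t <- t + 1L
    if (t > max_steps) {
      stop(sprintf("no attractor found within max_steps = %d ticks", max_steps),
           call. = FALSE)
    }
    if (t > length(states)) states <- c(states, vector("list", length(states)))
    states[[t]] <- state
    seen[[key]] <- t
    state <- model$step_fun(unname(state))
    names(state) <- model$nodes
    state <- apply_clamps(state, clamp)
  }
  mat <- do.call(cbind, states[seq_len(t)])
  rownames(mat) <- model$nodes
  colnames(mat) <- as.character(seq_len(t) - 1L)
  structure(
    list(states = mat, attractor_start = attractor_start, clamps = clamp),
    class = "boolean_trajectory"
  )
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("Boolean trajectory: %d nodes, %d ticks (transient %d, cycle length %d)\n",
              nrow(x$states), ncol(x$states), x$attractor_start - 1L,
              ncol(x$states) - x$attractor_start + 1L))
  invisible(x)
}

new_boolean_attractor <- function(cycle, clamp = clamps()) {
  structure(list(cycle = cycle, clamps = clamp), class = "boolean_attractor")
}

# Canonical rotation: the lexicographically smallest packed state leads.
canonicalize_cycle <- function(cycle) {
  keys <- apply(cycle, 2L, pack_state)
  rot <- which(keys == min(keys))[[1L]]
  if (rot > 1L) {
    idx <- c(rot:ncol(cycle), seq_len(rot - 1L))
    cycle <- cycle[, idx, drop = FALSE]
  }
  colnames(cycle) <- as.character(seq_len(ncol(cycle)) - 1L)
  cycle
}

#' Extract the (canonical) attractor of a trajectory
#'
#' The attractor cycle is rotated so that its lexicographically smallest state
#' comes first, making attractor identity a simple equality and the "first
#' state of the attractor" well defined.
#'
#' @param traj A trajectory from [simulate_path()], or a `boolean_attractor`
#'   (returned unchanged after canonicalization).
#' @return A `boolean_attractor`: list with `cycle` (logical matrix, nodes x
#'   cycle states) and `clamps`.
#' @export
attractor <- function(traj) {
  if (inherits(traj, "boolean_attractor")) {
    traj$cycle <- canonicalize_cycle(traj$cycle)
    return(traj)
  }
  stopifnot(inherits(traj, "boolean_trajectory"))
  cycle <- traj$states[, traj$attractor_start:ncol(traj$states), drop = FALSE]
  new_boolean_attractor(canonicalize_cycle(cycle), traj$clamps)
}

#' @export
print.boolean_attractor <- function(x, ...) {
  cat(sprintf("Boolean attractor: cycle length %d over %d nodes\n",
              ncol(x$cycle), nrow(x$cycle)))
  invisible(x)
}

attractor_key <- function(att) {
  paste(apply(att$cycle, 2L, pack_state), collapse = ";")
}

first_state <- function(att) {
  stats::setNames(att$cycle[, 1L], rownames(att$cycle))
}

#' Attractor-averaged output activities
#'
#' Fraction of attractor states in which each output node is ON: 0 (always
#' off) to 1 (always on), exact fractions.
#'
#' @param att A `boolean_attractor`.
#' @param outputs Character vector of node names.
#' @return Named numeric vector in `[0, 1]`.
#' @export
quantify_attractor <- function(att, outputs) {
  stopifnot(inherits(att, "boolean_attractor"))
  unknown <- setdiff(outputs, rownames(att$cycle))
  if (length(unknown) > 0L) {
    stop("unknown output node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rowMeans(att$cycle[outputs, , drop = FALSE])
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0L) x else gcd(y, x %% y)
  as.integer(a / gcd(a, b) * b)
}

#' Phase-shift-aware Hamming distance between attractors
#'
#' Both cycles are repeated to the least common multiple of their lengths; the
#' distance is the minimum, over all cyclic phase shifts, of the mean per-node
#' per-tick Hamming distance. Symmetric, in `[0, 1]`, and 0 exactly when the
#' two cycles are equal up to rotation.
#'
#' @param a,b `boolean_attractor` objects over the same node set.
#' @return A number in `[0, 1]`.
#' @export
attractor_distance <- function(a, b) {
  stopifnot(inherits(a, "boolean_attractor"), inherits(b, "boolean_attractor"))
  if (!setequal(rownames(a$cycle), rownames(b$cycle))) {
    stop("attractors are defined over different node sets", call. = FALSE)
  }
  bc <- b$cycle[rownames(a$cycle), , drop = FALSE]
  la <- ncol(a$cycle)
  lb <- ncol(bc)
  L <- lcm_int(la, lb)
  A <- a$cycle[, rep(seq_len(la), length.out = L), drop = FALSE]
  B <- bc[, rep(seq_len(lb), length.out = L), drop = FALSE]
  best <- 1
  for (s in seq_len(L) - 1L) {
    idx <- ((seq_len(L) - 1L + s) %% L) + 1L
    d <- mean(A != B[, idx, drop = FALSE])
    if (d < best) best <- d
    if (best == 0) break
  }
  best
}

#' Attractor identity up to rotation
#'
#' `TRUE` iff the two attractors have equal cycle lengths and zero
#' phase-shift-aware Hamming distance, i.e. they are the same cycle up to
#' rotation.
#'
#' @param a,b `boolean_attractor` objects over the same node set.
#' @return Logical scalar.
#' @export
attractors_equal <- function(a, b) {
  if (ncol(a$cycle) != ncol(b$cycle)) return(FALSE)
  attractor_distance(a, b) == 0
}

# Trajectory CSV dialect ------------------------------------------------------

#' Write a trajectory as CSV
#'
#' The interchange dialect consumed by the plotting functions: first column
#' `node`, subsequent columns the tick indices `0`, `1`, ...; cell values 0/1.
#' A leading `attractor` row flags the cycle ticks with 1.
#'
#' @param traj A `boolean_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "boolean_trajectory"))
  ticks <- ncol(traj$states)
  flags <- as.integer(seq_len(ticks) >= traj$attractor_start)
  df <- rbind(flags, traj$states * 1L)
  df <- data.frame(node = c("attractor", rownames(traj$states)), df,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("node", colnames(traj$states))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path Path to a CSV written by [write_trajectory_csv()].
#' @return A `boolean_trajectory` (with empty clamps).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "node") || nrow(df) < 2L ||
      !identical(df$node[1], "attractor") || ncol(df) < 2L) {
    stop("malformed trajectory CSV: expected a 'node' column and a leading 'attractor' row",
         call. = FALSE)
  }
  mat <- as.matrix(df[-1, -1, drop = FALSE]) == 1
  rownames(mat) <- df$node[-1]
  colnames(mat) <- names(df)[-1]
  flags <- as.integer(df[1, -1])
  start <- which(flags == 1L)
  if (length(start) == 0L) stop("trajectory CSV flags no attractor ticks", call. = FALSE)
  structure(
    list(states = mat, attractor_start = min(start), clamps = clamps()),
    class = "boolean_trajectory"
  )
}
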