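# Small models and independent oracles used across the suite.

neg_model <- function() boolean_model("A", list(A = "! A"))

copy2_model <- function() boolean_model(c("A", "B"), list(A = "B", B = "A"))

rotor3_model <- function() {
  boolean_model(c("A", "B", "C"), list(A = "C", B = "A", C = "B"))
}

# Ligand L drives an oscillator T; a memory node M latches T's value at the
# moment the ligand disappears, so ligand removal from the two phases of the
# with-ligand cycle reaches two different no-ligand attractors (branching).
branching_model <- function() {
  boolean_model(c("L", "T", "M"),
                list(L = "L", T = "L & ! T", M = "M | (T & ! L)"))
}

state_from_index <- function(model, i) {
  n <- length(model$nodes)
  bits <- bitwAnd(i - 1L, 2L^(seq_len(n) - 1L)) > 0L
  stats::setNames(bits, model$nodes)
}

index_from_state <- function(state) {
  sum(2L^(seq_along(state) - 1L) * as.integer(state)) + 1L
}

# Independent attractor oracle: build the full synchronous transition graph
# over all 2^n states and extract its cycles by binary lifting (iterating the
# successor map >= 2^n times lands every state on its cycle), then walking
# each cycle once. Shares only the one-step semantics with the simulator; the
# cycle detection itself is a different algorithm than first-revisit hashing.
oracle_attractor_keys <- function(model, clamp = clamps()) {
  n <- length(model$nodes)
  n_states <- 2L^n
  succ <- integer(n_states)
  for (i in seq_len(n_states)) {
    nxt <- state_transition(model, state_from_index(model, i), clamp)
    succ[[i]] <- index_from_state(nxt)
  }
  z <- succ
  reps <- ceiling(log2(n_states)) + 1L
  for (k in seq_len(reps)) z <- z[z]
  cycle_entry <- unique(z)
  keys <- character(0)
  seen <- logical(n_states)
  for (s in cycle_entry) {
    if (seen[[s]]) next
    cyc <- integer(0)
    cur <- s
    repeat {
      cyc <- c(cyc, cur)
      seen[[cur]] <- TRUE
      cur <- succ[[cur]]
      if (cur == s) break
    }
    cycle <- vapply(cyc, function(i) state_from_index(model, i), logical(n))
    if (n == 1L) cycle <- matrix(cycle, nrow = 1L)
    rownames(cycle) <- model$nodes
    att <- attractor(boolvvv:::new_boolean_attractor(cycle, clamp))
    keys <- c(keys, boolvvv:::attractor_key(att))
  }
  sort(keys)
}

# Attractor set found by the implementation: simulate from every state.
simulated_attractor_keys <- function(model, clamp = clamps()) {
  n <- length(model$nodes)
  keys <- character(0)
  for (i in seq_len(2L^n)) {
    tr <- simulate_path(model, state_from_index(model, i), clamp)
    keys <- c(keys, boolvvv:::attractor_key(attractor(tr)))
  }
  sort(unique(keys))
}

write_model_file <- function(lines) {
  f <- tempfile(fileext = ".boolnet")
  writeLines(lines, f)
  f
}

cascade_init <- function(cas) {
  lig <- ligand_spec(cas$model, cas$ligand)
  remove_ligand(neutral_state(cas$model), lig, cas$model)
}
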