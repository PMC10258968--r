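# Programmatic fixtures: cascade models, random models, synthetic MIDAS ------

#' Build a ligand-receptor-kinase-substrate cascade model
#'
#' Constructs a small reaction-contingency Boolean network: a ligand `L`
#' binds a receptor `R` (`L_ppi+_R_[ext]`, producing the bond
#' `L_[lig]--R_[ext]` and consuming both unbound states); the bond activates
#' a kinase reaction `K_p+_S_[site]` that phosphorylates the substrate
#' (`S_[site]-{0}` -> `S_[site]-{p}`). With `with_phosphatase = TRUE` a
#' dephosphorylation reaction `P_p-_S_[site]` (active only when the bond is
#' absent, so kinase and phosphatase never fire together) reverses the
#' modification, and ligand cycling is fully reversible. Without it the
#' substrate stays phosphorylated after ligand removal — a "trap" that
#' [verify_model()] flags as inconsistent.
#'
#' Contingencies are encoded as conjunction terms in the reaction rules
#' (required state AND available substrate), the standard reading of a
#' reaction-contingency network in Boolean form. `n_extra_layers` appends
#' further kinase tiers in which each phosphorylated substrate acts as the
#' kinase of the next (`S_p+_S2_[site]`, `S2_p+_S3_[site]`, ...), each tier
#' with its own phosphatase reaction when `with_phosphatase = TRUE`.
#'
#' @param with_phosphatase Include the dephosphorylation reaction(s)?
#' @param n_extra_layers Number of additional kinase->substrate tiers
#'   (>= 0).
#' @param seed Accepted for interface uniformity with the other generators;
#'   the cascade construction is fully deterministic and ignores it.
#' @return A list with elements `model` (a [boolean_model()]), `annotations`
#'   (a module/quality annotation tibble as read by [read_annotations()]) and
#'   `ligand` (the ligand's unbound presence node name, `"L_[lig]--0"`).
#' @export
make_cascade <- function(with_phosphatase = TRUE, n_extra_layers = 0L,
                         seed = NULL) {
  stopifnot(n_extra_layers >= 0L)
  nodes <- character(0)
  rules <- character(0)
  ann <- list()
  add <- function(node, rule, modules, quality) {
    nodes <<- c(nodes, node)
    rules <<- c(rules, stats::setNames(rule, node))
    ann[[length(ann) + 1L]] <<- tibble::tibble(
      id = node, modules = list(modules), quality = quality
    )
  }

  bind <- "L_ppi+_R_[ext]"
  bond <- "L_[lig]--R_[ext]"
  add("L_[lig]--0", sprintf("L_[lig]--0 & ! %s", bind), "binding", 3)
  add("R_[ext]--0", sprintf("R_[ext]--0 & ! %s", bind), "binding", 3)
  add(bind, "L_[lig]--0 & R_[ext]--0", "binding", 3)
  add(bond, sprintf("%s | %s", bind, bond), "binding", 3)

  # One phosphorylation tier: `kin_state` (the activating context) gates the
  # kinase reaction; the phosphatase is inhibited by the same context so the
  # two reactions are mutually exclusive and attractors stay fixed points.
  sub_names <- c("S", if (n_extra_layers > 0L) paste0("S", 1L + seq_len(n_extra_layers)))
  kin_names <- c("K", utils::head(sub_names, -1L))
  kin_state <- bond
  for (i in seq_along(sub_names)) {
    s <- sub_names[[i]]
    module <- paste0("layer", i)
    s0 <- sprintf("%s_[site]-{0}", s)
    sp <- sprintf("%s_[site]-{p}", s)
    kin <- sprintf("%s_p+_%s_[site]", kin_names[[i]], s)
    add(kin, sprintf("%s & %s", kin_state, s0), module, 2)
    if (with_phosphatase) {
      pase <- sprintf("P_p-_%s_[site]", s)
      add(pase, sprintf("%s & ! %s", sp, kin_state), module, 1)
      add(s0, sprintf("(%s & ! %s) | %s", s0, kin, pase), module, 2)
      add(sp, sprintf("(%s & ! %s) | %s", sp, pase, kin), module, 2)
    } else {
      add(s0, sprintf("%s & ! %s", s0, kin), module, 2)
      add(sp, sprintf("%s | %s", sp, kin), module, 2)
    }
    kin_state <- sp
  }

  model <- boolean_model(nodes, as.list(rules))
  list(model = model, annotations = dplyr::bind_rows(ann),
       ligand = "L_[lig]--0")
}

#' Generate a seeded random Boolean network
#'
#' Each node gets `k_inputs` distinct regulators drawn uniformly (self-loops
#' allowed) and a uniformly random Boolean function over them, materialized
#' as a disjunctive-normal-form rule. Reproducible from `seed`. Intended for
#' property-based testing against exhaustive state-space enumeration.
#'
#' @param n_nodes Number of nodes (2..14).
#' @param k_inputs Regulators per node (1..`n_nodes - 1`).
#' @param seed Integer RNG seed.
#' @return A [boolean_model()] with nodes `n01`, `n02`, ...
#' @export
make_random_model <- function(n_nodes, k_inputs, seed) {
  if (n_nodes < 2L || n_nodes > 14L || k_inputs < 1L || k_inputs >= n_nodes) {
    stop("need 1 <= k_inputs < n_nodes <= 14 (and n_nodes >= 2)", call. = FALSE)
  }
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  rules <- lapply(nodes, function(nd) {
    regs <- sample(nodes, k_inputs)
    tt <- sample(c(TRUE, FALSE), 2^k_inputs, replace = TRUE)
    if (all(tt)) return(rule_const(TRUE))
    if (!any(tt)) return(rule_const(FALSE))
    terms <- lapply(which(tt), function(row) {
      bits <- as.logical(bitwAnd(row - 1L, 2^(seq_len(k_inputs) - 1L)) > 0L)
      lits <- lapply(seq_len(k_inputs), function(j) {
        if (bits[[j]]) rule_var(regs[[j]]) else rule_not(rule_var(regs[[j]]))
      })
      if (length(lits) == 1L) lits[[1L]] else rule_and(lits)
    })
    if (length(terms) == 1L) terms[[1L]] else rule_or(terms)
  })
  names(rules) <- nodes
  boolean_model(nodes, rules)
}

#' Generate a synthetic MIDAS database from a model
#'
#' For every combination of the given treatments, simulates the model's
#' pre-/post-stimulation responses (the same procedure as
#' [predict_responses()]) and writes one experiment sheet whose `t = 0`
#' values equal the simulated pre-stimulation activities and whose `t > 0`
#' values equal the post-stimulation activities, plus clipped Gaussian noise.
#' A `TreatmentDefs` sheet is included. The database is written as a
#' directory of CSV sheets, byte-reproducible from `seed`.
#'
#' @param model A [boolean_model()].
#' @param treatments List of [treatment_def()] objects (targets must be model
#'   nodes).
#' @param outputs Character vector of readout node names.
#' @param dir Output directory (created if needed).
#' @param timepoints Acquisition times; must include 0 and at least one
#'   positive time.
#' @param noise_sd Standard deviation of the Gaussian noise added to every
#'   value before clipping to `[0, 1]`; 0 gives exact model predictions.
#' @param seed Integer RNG seed.
#' @param init Initial state for the simulations; defaults to
#'   [neutral_state()].
#' @return The generated database, read back with [read_midas()], invisibly.
#' @export
make_synthetic_midas <- function(model, treatments, outputs, dir,
                                 timepoints = c(0, 10, 30), noise_sd = 0,
                                 seed = 1L, init = NULL) {
  stopifnot(inherits(model, "boolean_model"), noise_sd >= 0,
            any(timepoints == 0), any(timepoints > 0))
  for (td in treatments) {
    stopifnot(inherits(td, "treatment_def"))
    unknown <- setdiff(td$nodes, model$nodes)
    if (length(unknown) > 0L) {
      stop("treatment '", td$name, "' targets node(s) not in the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  unknown <- setdiff(outputs, model$nodes)
  if (length(unknown) > 0L) {
    stop("output node(s) not in the model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(init)) init <- neutral_state(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  tnames <- vapply(treatments, `[[`, character(1), "name")
  names(treatments) <- tnames
  fake_db <- list(treatments = treatments)
  n_t <- length(treatments)
  clip <- function(x) pmin(1, pmax(0, x + if (noise_sd > 0) {
    stats::rnorm(length(x), 0, noise_sd)
  } else 0))

  for (mask in seq_len(2^n_t) - 1L) {
    active <- tnames[bitwAnd(mask, 2^(seq_len(n_t) - 1L)) > 0L]
    eff <- combo_effects(fake_db, active)
    pred <- predict_combo(model, eff, outputs, init)
    rows <- lapply(timepoints, function(t) {
      vals <- if (t == 0) pred$sim_pre else pred$sim_post
      row <- c(as.integer(tnames %in% active), t, clip(unname(vals)))
      stats::setNames(row, c(paste0("TR:", tnames), "DA:ALL",
                             paste0("DV:", outputs)))
    })
    df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("Experiment%02d.csv", mask + 1L)),
                     row.names = FALSE)
  }
  td_df <- data.frame(
    name = tnames,
    effect = vapply(treatments, `[[`, character(1), "effect"),
    nodes = vapply(treatments, function(d) paste(d$nodes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(td_df, file.path(dir, "TreatmentDefs.csv"), row.names = FALSE)
  invisible(read_midas(dir))
}
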