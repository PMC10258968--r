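# rxncon node-name semantics -------------------------------------------------

#' Node-name grammar for rxncon-style Boolean networks
#'
#' The verification and scoring algorithms need to know what each Boolean node
#' *is*: a reaction, an elemental state (bound or neutral), an input, or a
#' logical gate. That information is recovered from the node name using the
#' rxncon naming conventions, which this grammar object encodes. The defaults
#' cover the standard rxncon reaction verbs; supply your own verb list if your
#' models use additional reaction types.
#'
#' @param reaction_verbs Character vector of reaction-verb infixes; a name of
#'   the form `"A_<verb>_B"` (domains allowed on either component) is
#'   classified as a reaction.
#' @param input_pattern Regular expression recognising input/output nodes
#'   (default: the whole name wrapped in square brackets, e.g. `"[EGF]"`).
#' @param gate_pattern Regular expression recognising Boolean gate nodes
#'   (default: the whole name wrapped in angle brackets, e.g. `"<AND1>"`).
#' @return An object of class `rxncon_grammar`.
#' @export
rxncon_grammar <- function(reaction_verbs = c(
                             "ppi+", "ppi-", "i+", "i-", "p+", "p-",
                             "ap", "pt", "gef", "gap", "ub+", "ub-",
                             "cut", "trsc", "trsl", "deg", "syn",
                             "lip+", "lip-", "me+", "me-"
                           ),
                           input_pattern = "^\\[.*\\]$",
                           gate_pattern = "^<.*>$") {
  structure(
    list(reaction_verbs = reaction_verbs,
         input_pattern = input_pattern,
         gate_pattern = gate_pattern),
    class = "rxncon_grammar"
  )
}

new_node_meta <- function(node_class = "unknown",
                          components = character(0),
                          bound_partner = character(0),
                          is_neutral = FALSE,
                          modules = character(0),
                          quality = NA_real_) {
  list(node_class = node_class, components = components,
       bound_partner = bound_partner, is_neutral = is_neutral,
       modules = modules, quality = quality)
}

# "A_[dom]" -> "A"
strip_domain <- function(x) sub("_\\[[^]]*\\]$", "", x)

spec_side_ok <- function(x) {
  grepl("^[A-Za-z0-9.]+(_\\[[^]]*\\])?$", x)
}

#' Classify a node name by the rxncon naming convention
#'
#' Determines the node class and component membership of a Boolean node from
#' its name. Bond states (`"A_[d]--B_[e]"`) record, for each of the two
#' components, the name of the *partner's* neutral (unbound) node, which the
#' ligand-removal transform of [verify_model()] uses to keep the partner in the
#' system when a complex is dissolved. The function is total: a name matching
#' no convention is classified `"unknown"`, never an error.
#'
#' @param name A non-empty node name.
#' @param grammar An [rxncon_grammar()] object.
#' @return A node-meta list with elements `node_class` (one of `"reaction"`,
#'   `"state"`, `"input"`, `"gate"`, `"unknown"`), `components`,
#'   `bound_partner` (named character vector: component -> partner neutral
#'   node), `is_neutral`, `modules`, `quality`.
#' @examples
#' parse_node_name("L_[lig]--R_[ext]")$components
#' parse_node_name("S_[site]-{0}")$is_neutral
#' parse_node_name("K_p+_S_[site]")$node_class
#' @export
parse_node_name <- function(name, grammar = rxncon_grammar()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))

  if (grepl(grammar$input_pattern, name)) {
    return(new_node_meta("input",
                         components = gsub("^\\[|\\]$", "", name)))
  }
  if (grepl(grammar$gate_pattern, name)) {
    return(new_node_meta("gate"))
  }

  # Bond states: "A_[d]--B_[e]" or neutral "A_[d]--0".
  if (grepl("--", name, fixed = TRUE)) {
    sides <- strsplit(name, "--", fixed = TRUE)[[1]]
    if (length(sides) == 2L && spec_side_ok(sides[[1]])) {
      lhs <- sides[[1]]
      rhs <- sides[[2]]
      if (identical(rhs, "0")) {
        return(new_node_meta("state", components = strip_domain(lhs),
                             is_neutral = TRUE))
      }
      if (spec_side_ok(rhs)) {
        c1 <- strip_domain(lhs)
        c2 <- strip_domain(rhs)
        partner <- stats::setNames(
          c(paste0(rhs, "--0"), paste0(lhs, "--0")),
          c(c1, c2)
        )
        return(new_node_meta("state", components = unique(c(c1, c2)),
                             bound_partner = partner))
      }
    }
  }

  # Modification states: "A_[r]-{p}", neutral "A_[r]-{0}".
  mod <- regmatches(name, regexec("^(.*)-\\{([^}]*)\\}$", name))[[1]]
  if (length(mod) == 3L && spec_side_ok(mod[[2]])) {
    return(new_node_meta("state", components = strip_domain(mod[[2]]),
                         is_neutral = identical(mod[[3]], "0")))
  }

  # Reactions: "<comp1>_<verb>_<comp2>" with optional domains.
  verbs <- grammar$reaction_verbs
  verbs_re <- paste(vapply(verbs, function(v) {
    gsub("([+\\-])", "\\\\\\1", v)
  }, character(1)), collapse = "|")
  rx <- sprintf("^(.+?)_(%s)_(.+)$", verbs_re)
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 4L) {
    c1 <- strip_domain(m[[2]])
    c2 <- strip_domain(m[[4]])
    if (spec_side_ok(m[[2]]) && spec_side_ok(m[[4]])) {
      return(new_node_meta("reaction", components = unique(c(c1, c2))))
    }
  }

  new_node_meta("unknown")
}

#' The rxncon neutral state of a model
#'
#' The default initial condition of a reaction-contingency Boolean network:
#' all reactions OFF, every component in its unbound and unmodified form
#' (neutral state nodes ON), all other state, input, gate and unclassified
#' nodes OFF.
#'
#' @param model A [boolean_model()].
#' @return A named logical vector over the model's nodes.
#' @export
neutral_state <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  vals <- vapply(model$meta, function(m) isTRUE(m$is_neutral), logical(1))
  stats::setNames(vals, model$nodes)
}
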