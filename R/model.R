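# BooleanModel container and BoolNet-format I/O ------------------------------

#' Construct a Boolean network model
#'
#' A `boolean_model` holds an ordered node list, one Boolean update rule per
#' node (over the operators `!`, `&`, `|`, parentheses and the constants
#' `0`/`1`), and per-node metadata recovered from the rxncon naming convention
#' by [parse_node_name()]. Every identifier appearing in a rule must be a
#' declared node; node order is the document order of the input and is stable.
#'
#' @param nodes Character vector of unique, non-empty node names.
#' @param rules Named list (or character vector) of rule expressions, one per
#'   node. Character rules are parsed; pre-parsed rule ASTs are accepted
#'   internally.
#' @param grammar Node-name grammar, see [rxncon_grammar()].
#' @return An object of class `boolean_model` with elements `nodes`, `rules`
#'   (ASTs), `meta` (per-node metadata) and a compiled synchronous update
#'   function.
#' @export
boolean_model <- function(nodes, rules, grammar = rxncon_grammar()) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("model must have at least one node", call. = FALSE)
  if (any(!nzchar(nodes))) stop("node names must be non-empty", call. = FALSE)
  dup <- nodes[duplicated(nodes)]
  if (length(dup) > 0L) {
    stop("duplicate node(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (is.character(rules)) rules <- as.list(rules)
  if (is.null(names(rules)) || !setequal(names(rules), nodes)) {
    stop("rules must be named, with exactly one rule per node", call. = FALSE)
  }
  rules <- rules[nodes]
  rules <- lapply(nodes, function(nd) {
    r <- rules[[nd]]
    if (is.character(r)) parse_rule(r, context = sprintf("rule for '%s'", nd)) else r
  })
  names(rules) <- nodes

  undeclared <- lapply(rules, function(r) setdiff(rule_vars(r), nodes))
  bad <- vapply(undeclared, length, integer(1)) > 0L
  if (any(bad)) {
    msgs <- vapply(nodes[bad], function(nd) {
      sprintf("rule for '%s' references undeclared node(s): %s",
              nd, paste(undeclared[[nd]], collapse = ", "))
    }, character(1))
    stop(paste(msgs, collapse = "\n"), call. = FALSE)
  }

  meta <- lapply(nodes, parse_node_name, grammar = grammar)
  names(meta) <- nodes

  model <- structure(
    list(nodes = nodes, rules = rules, meta = meta, grammar = grammar),
    class = "boolean_model"
  )
  model$step_fun <- compile_step(model)
  model
}

compile_step <- function(model) {
  index <- stats::setNames(seq_along(model$nodes), model$nodes)
  exprs <- vapply(model$nodes, function(nd) {
    rule_expr_text(model$rules[[nd]], index)
  }, character(1))
  text <- sprintf("function(.x) c(%s)", paste(exprs, collapse = ", "))
  eval(parse(text = text)[[1]], envir = baseenv())
}

#' @export
print.boolean_model <- function(x, ...) {
  classes <- vapply(x$meta, `[[`, character(1), "node_class")
  cat(sprintf("Boolean reaction-contingency model: %d nodes\n", length(x$nodes)))
  cat("  ", paste(sprintf("%s: %d", names(table(classes)), table(classes)),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-node metadata as a tibble
#'
#' @param model A [boolean_model()].
#' @return A tibble with one row per node: name, class, components, neutral
#'   flag, module tags and quality score.
#' @export
node_meta <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  tibble::tibble(
    node = model$nodes,
    node_class = vapply(model$meta, `[[`, character(1), "node_class"),
    components = lapply(model$meta, `[[`, "components"),
    is_neutral = vapply(model$meta, `[[`, logical(1), "is_neutral"),
    modules = lapply(model$meta, `[[`, "modules"),
    quality = vapply(model$meta, `[[`, numeric(1), "quality")
  )
}

#' Read a Boolean network model in BoolNet text format
#'
#' Parses the "targets, factors" rule-line format emitted by the rxncon
#' compiler for the BoolNet simulator. Blank lines and lines starting with
#' `#` are ignored. The first non-comment line must be the header
#' `targets, factors`; every subsequent line is `<node>, <expression>`.
#'
#' @param path Path to a BoolNet-format model file.
#' @param grammar Node-name grammar, see [rxncon_grammar()].
#' @return A [boolean_model()].
#' @examples
#' f <- tempfile(fileext = ".boolnet")
#' writeLines(c("targets, factors", "A, ! A"), f)
#' read_boolnet(f)
#' @export
read_boolnet <- function(path, grammar = rxncon_grammar()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  if (length(keep) == 0L) stop("empty model file: ", path, call. = FALSE)
  header <- keep[[1]]
  if (!grepl("^\\s*targets\\s*[,\t]\\s*factors\\s*$", raw[[header]],
             ignore.case = TRUE)) {
    stop(sprintf("line %d: expected header 'targets, factors', got '%s'",
                 header, trimws(raw[[header]])), call. = FALSE)
  }
  body <- keep[-1]
  nodes <- character(0)
  rules <- list()
  for (i in body) {
    line <- raw[[i]]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L) {
      stop(sprintf("line %d: malformed rule line (no comma): '%s'",
                   i, trimws(line)), call. = FALSE)
    }
    node <- trimws(substr(line, 1L, comma - 1L))
    expr <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!nzchar(node) || !nzchar(expr)) {
      stop(sprintf("line %d: malformed rule line: '%s'", i, trimws(line)),
           call. = FALSE)
    }
    if (node %in% nodes) {
      stop(sprintf("line %d: duplicate node '%s'", i, node), call. = FALSE)
    }
    nodes <- c(nodes, node)
    rules[[node]] <- parse_rule(expr, context = sprintf("line %d", i))
  }
  boolean_model(nodes, rules, grammar = grammar)
}

#' Write a model in BoolNet text format
#'
#' The emitted file re-reads (with [read_boolnet()]) to a model with an
#' identical node list and logically identical rules. Constant rules are
#' written with the `0`/`1` constants.
#'
#' @param model A [boolean_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boolnet <- function(model, path) {
  stopifnot(inherits(model, "boolean_model"))
  lines <- c("targets, factors",
             vapply(model$nodes, function(nd) {
               paste0(nd, ", ", render_rule(model$rules[[nd]]))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Shared state checks used across the simulation and verification code.
check_state <- function(model, state) {
  if (!is.logical(state) || length(state) != length(model$nodes)) {
    stop(sprintf("state must be a logical vector of length %d (one value per node)",
                 length(model$nodes)), call. = FALSE)
  }
  if (!is.null(names(state))) {
    if (!setequal(names(state), model$nodes)) {
      stop("state names do not match model nodes", call. = FALSE)
    }
    state <- state[model$nodes]
  } else {
    names(state) <- model$nodes
  }
  state
}
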