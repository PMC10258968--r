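# Boolean rule expressions ---------------------------------------------------
#
# Rules are stored as small ASTs (nested lists) so they can be rendered back to
# BoolNet text, compiled to fast R expressions, and rewritten when nodes are
# removed during module extraction. Node names in the rxncon world contain
# characters such as "[", "]", "{", "}", "-" and "+", so rules cannot be parsed
# or deparsed with R's own parser; the only reserved characters in the rule
# grammar are the operators "!", "&", "|" and parentheses, plus the constants
# "0"/"1".

rule_const <- function(value) list(type = "const", value = isTRUE(value))
rule_var <- function(name) list(type = "var", name = name)
rule_not <- function(arg) list(type = "not", arg = arg)
rule_and <- function(args) list(type = "and", args = args)
rule_or <- function(args) list(type = "or", args = args)

tokenize_rule <- function(text) {
  padded <- gsub("([!&|()])", " \\1 ", text)
  toks <- strsplit(trimws(padded), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser, precedence NOT > AND > OR.
parse_rule <- function(text, context = "rule") {
  toks <- tokenize_rule(text)
  if (length(toks) == 0L) {
    stop(sprintf("empty Boolean expression in %s", context), call. = FALSE)
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  bad <- function(what) {
    stop(sprintf("malformed Boolean expression in %s: %s (near token %d of '%s')",
                 context, what, pos, text), call. = FALSE)
  }

  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) bad("unexpected end of expression")
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) bad("missing closing parenthesis")
      advance()
      return(e)
    }
    if (t %in% c("0", "FALSE")) { advance(); return(rule_const(FALSE)) }
    if (t %in% c("1", "TRUE")) { advance(); return(rule_const(TRUE)) }
    if (t %in% c(")", "&", "|", "!")) bad(sprintf("unexpected operator '%s'", t))
    advance()
    rule_var(t)
  }
  parse_unary <- function() {
    if (identical(peek(), "!")) {
      advance()
      return(rule_not(parse_unary()))
    }
    parse_primary()
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (identical(peek(), "&")) {
      advance()
      args <- c(args, list(parse_unary()))
    }
    if (length(args) == 1L) args[[1L]] else rule_and(args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else rule_or(args)
  }

  ast <- parse_or()
  if (pos <= length(toks)) bad(sprintf("trailing input '%s'", peek()))
  ast
}

# Render back to BoolNet text; parenthesises only where precedence demands.
render_rule <- function(ast) {
  wrap_if <- function(a, types) {
    s <- render_rule(a)
    if (a$type %in% types) paste0("(", s, ")") else s
  }
  switch(ast$type,
    const = if (ast$value) "1" else "0",
    var = ast$name,
    not = paste0("! ", wrap_if(ast$arg, c("and", "or"))),
    and = paste(vapply(ast$args, wrap_if, character(1), types = "or"),
                collapse = " & "),
    or = paste(vapply(ast$args, render_rule, character(1)), collapse = " | "),
    stop("unknown rule node type: ", ast$type)
  )
}

rule_vars <- function(ast) {
  switch(ast$type,
    const = character(0),
    var = ast$name,
    not = rule_vars(ast$arg),
    unique(unlist(lapply(ast$args, rule_vars), use.names = FALSE))
  )
}

# Polarity of each variable in a rule: +1 if it only occurs under an even
# number of negations, -1 if only odd, 0 if mixed. Used for regulatory-graph
# edge typing.
rule_polarity <- function(ast, sign = 1L) {
  switch(ast$type,
    const = integer(0),
    var = stats::setNames(sign, ast$name),
    not = rule_polarity(ast$arg, -sign),
    {
      polys <- lapply(ast$args, rule_polarity, sign = sign)
      all_names <- unique(unlist(lapply(polys, names), use.names = FALSE))
      out <- stats::setNames(integer(length(all_names)), all_names)
      for (nm in all_names) {
        vals <- unique(unlist(lapply(polys, function(p) unname(p[names(p) == nm]))))
        out[[nm]] <- if (length(vals) == 1L) vals else 0L
      }
      out
    }
  )
}

# Replace variables by Boolean constants (named logical vector `values`).
substitute_rule <- function(ast, values) {
  switch(ast$type,
    const = ast,
    var = if (ast$name %in% names(values)) {
      rule_const(values[[ast$name]])
    } else {
      ast
    },
    not = rule_not(substitute_rule(ast$arg, values)),
    and = rule_and(lapply(ast$args, substitute_rule, values = values)),
    or = rule_or(lapply(ast$args, substitute_rule, values = values))
  )
}

# Constant folding.
simplify_rule <- function(ast) {
  switch(ast$type,
    const = ast,
    var = ast,
    not = {
      a <- simplify_rule(ast$arg)
      if (a$type == "const") rule_const(!a$value) else rule_not(a)
    },
    and = {
      args <- lapply(ast$args, simplify_rule)
      if (any(vapply(args, function(a) a$type == "const" && !a$value, logical(1)))) {
        return(rule_const(FALSE))
      }
      args <- Filter(function(a) !(a$type == "const" && a$value), args)
      if (length(args) == 0L) rule_const(TRUE)
      else if (length(args) == 1L) args[[1L]]
      else rule_and(args)
    },
    or = {
      args <- lapply(ast$args, simplify_rule)
      if (any(vapply(args, function(a) a$type == "const" && a$value, logical(1)))) {
        return(rule_const(TRUE))
      }
      args <- Filter(function(a) !(a$type == "const" && !a$value), args)
      if (length(args) == 0L) rule_const(FALSE)
      else if (length(args) == 1L) args[[1L]]
      else rule_or(args)
    }
  )
}

# Compile a rule to R expression text over the positional state vector `.x`.
rule_expr_text <- function(ast, index) {
  switch(ast$type,
    const = if (ast$value) "TRUE" else "FALSE",
    var = sprintf(".x[[%dL]]", index[[ast$name]]),
    not = sprintf("!(%s)", rule_expr_text(ast$arg, index)),
    and = paste0("(", paste(vapply(ast$args, rule_expr_text, character(1),
                                   index = index), collapse = " & "), ")"),
    or = paste0("(", paste(vapply(ast$args, rule_expr_text, character(1),
                                  index = index), collapse = " | "), ")")
  )
}
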