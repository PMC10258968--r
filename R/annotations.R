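# Module/quality annotations and module extraction ---------------------------

#' Read a node annotation table
#'
#' A sidecar CSV/TSV attaching module tags and quality scores to model nodes.
#' The header must contain the columns `id`, `modules` and `quality`;
#' `modules` holds a comma-separated list of module names (whitespace around
#' tags is trimmed), `quality` a numeric score or empty.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` (tab-separated) file.
#' @return A tibble with columns `id`, `modules` (list of character vectors)
#'   and `quality` (numeric, `NA` when empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  need <- c("id", "modules", "quality")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  quality <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    q <- trimws(df$quality[[i]])
    if (nzchar(q)) {
      qn <- suppressWarnings(as.numeric(q))
      if (is.na(qn)) {
        stop(sprintf("row %d (id '%s'): non-numeric quality value '%s'",
                     i, df$id[[i]], q), call. = FALSE)
      }
      quality[[i]] <- qn
    }
  }
  modules <- lapply(df$modules, function(m) {
    tags <- trimws(strsplit(m, ",", fixed = TRUE)[[1]])
    tags[nzchar(tags)]
  })
  tibble::tibble(id = trimws(df$id), modules = modules, quality = quality)
}

#' Attach annotations to a model
#'
#' Copies module tags and quality scores from an annotation table onto the
#' model's per-node metadata. Annotation ids with no matching node are
#' reported with a warning, never silently dropped.
#'
#' @param model A [boolean_model()].
#' @param annotations A table from [read_annotations()].
#' @return The annotated model.
#' @export
annotate_model <- function(model, annotations) {
  stopifnot(inherits(model, "boolean_model"))
  unknown <- setdiff(annotations$id, model$nodes)
  if (length(unknown) > 0L) {
    warning("annotation id(s) not present in the model: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(annotations))) {
    id <- annotations$id[[i]]
    if (id %in% model$nodes) {
      model$meta[[id]]$modules <- annotations$modules[[i]]
      model$meta[[id]]$quality <- annotations$quality[[i]]
    }
  }
  model
}

#' Extract a tagged module from a model
#'
#' Keeps the nodes tagged with at least one of the requested modules (plus any
#' untagged "boundary" nodes referenced, directly or transitively, by kept
#' rules) and drops everything else, including any node whose quality score
#' falls below `quality_threshold`. Rules of kept nodes are rewritten by
#' substituting each removed node with its neutral-state value (ON for neutral
#' state nodes, OFF otherwise) and folding constants, so the extracted model
#' is closed over its own node set.
#'
#' @param model A [boolean_model()].
#' @param annotations Annotation table ([read_annotations()]) supplying the
#'   module tags and quality scores.
#' @param modules Character vector of module tags to keep.
#' @param quality_threshold Optional numeric; annotated nodes with
#'   `quality < quality_threshold` are removed regardless of tags.
#' @return A [boolean_model()] over the kept nodes (original order).
#' @export
extract_module <- function(model, annotations, modules,
                           quality_threshold = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  model <- suppressWarnings(annotate_model(model, annotations))
  all_tags <- unique(unlist(annotations$modules, use.names = FALSE))
  unknown_tags <- setdiff(modules, all_tags)
  if (length(unknown_tags) > 0L) {
    warning("requested module tag(s) not present in the annotation table: ",
            paste(unknown_tags, collapse = ", "), call. = FALSE)
  }

  tags_of <- lapply(model$meta, `[[`, "modules")
  quality_of <- vapply(model$meta, `[[`, numeric(1), "quality")
  quality_drop <- if (is.null(quality_threshold)) character(0) else {
    model$nodes[!is.na(quality_of) & quality_of < quality_threshold]
  }

  tagged <- model$nodes[vapply(tags_of, function(t) {
    length(intersect(t, modules)) > 0L
  }, logical(1))]
  untagged <- model$nodes[vapply(tags_of, length, integer(1)) == 0L]

  keep <- setdiff(tagged, quality_drop)
  repeat {
    refs <- unique(unlist(lapply(keep, function(nd) {
      rule_vars(model$rules[[nd]])
    }), use.names = FALSE))
    add <- setdiff(intersect(refs, untagged), union(keep, quality_drop))
    if (length(add) == 0L) break
    keep <- c(keep, add)
  }
  keep <- model$nodes[model$nodes %in% keep]
  if (length(keep) == 0L) {
    stop("module extraction produced an empty model", call. = FALSE)
  }

  removed <- setdiff(model$nodes, keep)
  neutral_vals <- neutral_state(model)[removed]
  new_rules <- lapply(keep, function(nd) {
    simplify_rule(substitute_rule(model$rules[[nd]], neutral_vals))
  })
  names(new_rules) <- keep

  out <- boolean_model(keep, new_rules, grammar = model$grammar)
  for (nd in keep) {
    out$meta[[nd]]$modules <- model$meta[[nd]]$modules
    out$meta[[nd]]$quality <- model$meta[[nd]]$quality
  }
  out
}
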