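#' Gating rules for valley-threshold cell-type annotation
#'
#' A rule set is a data frame with one row per (cell type, marker condition):
#' columns `cell_type`, `parent` (empty/`NA` for roots), `marker`,
#' `relation` (`above_valley`, `below_valley` or `between_valleys`) and
#' `valley` (1-based valley index; for `between_valleys` the band between
#' valley `i` and valley `i + 1`). A cell type's full condition is the
#' conjunction of its own rows and all of its ancestors'. Cell types without
#' children are terminal labels.
#'
#' @param path TSV (or JSON array of row objects) rule file.
#' @return validated data frame of class `gating_rules`.
#' @export
read_gating_rules <- function(path) {
  rules <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    # cell types like "T" must not be parsed as logicals
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", na.strings = c("NA", ""))
  }
  if (!is.null(rules$valley)) rules$valley <- as.integer(rules$valley)
  gating_rules(rules)
}

#' @rdname read_gating_rules
#' @param rules data frame as described above.
#' @export
gating_rules <- function(rules) {
  need <- c("cell_type", "marker", "relation")
  if (!all(need %in% names(rules)))
    stop("gating rules need columns: ", toString(need))
  if (is.null(rules$parent)) rules$parent <- NA_character_
  if (is.null(rules$valley)) rules$valley <- 1L
  rules$valley[is.na(rules$valley)] <- 1L
  bad <- !rules$relation %in% c("above_valley", "below_valley",
                                "between_valleys")
  if (any(bad)) stop("unknown relation: ", toString(unique(rules$relation[bad])))
  # hierarchy must be acyclic and parents must exist
  kids <- unique(rules$cell_type)
  parents <- unique(stats::na.omit(rules$parent))
  if (!all(parents %in% kids))
    stop("unknown parent cell type(s): ", toString(setdiff(parents, kids)))
  for (ct in kids) {
    seen <- character(0); cur <- ct
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in gating hierarchy at '", cur, "'")
      seen <- c(seen, cur)
      cur <- rules$parent[match(cur, rules$cell_type)]
    }
  }
  structure(rules, class = c("gating_rules", "data.frame"))
}

rule_chain <- function(rules, ct) {
  rows <- NULL; cur <- ct
  while (!is.na(cur)) {
    rows <- rbind(rules[rules$cell_type == cur, , drop = FALSE], rows)
    cur <- rules$parent[match(cur, rules$cell_type)]
  }
  rows
}

#' Automated valley-threshold gating
#'
#' Evaluates the rule hierarchy top-down on normalized values. A cell is
#' positive for a marker iff its value is at or above the marker's aligned
#' valley (ties at the threshold are positive). Because thresholds come from
#' the shared post-alignment valleys, one rule set serves all batches. The
#' first matching terminal cell type (file order) wins; cells matching no
#' terminal rule are labeled `"ungated"`.
#'
#' @param values cells x markers matrix of normalized arcsinh values.
#' @param valleys named list (by marker) of aligned valley locations, e.g.
#'   from [aligned_valleys()].
#' @param rules a [gating_rules()] data frame.
#' @return An object of class `gate_result`: list with `labels` (per-cell
#'   character vector) and `thresholds` (long data frame of the valley
#'   thresholds used).
#' @export
auto_gate <- function(values, valleys, rules) {
  rules <- gating_rules(as.data.frame(rules))
  miss <- setdiff(unique(rules$marker), colnames(values))
  if (length(miss) > 0) stop("rules reference missing marker(s): ",
                             toString(miss))
  get_valley <- function(mk, j, ct) {
    v <- valleys[[mk]]
    if (is.null(v) || length(v) < j || is.na(v[j]))
      stop("rule for '", ct, "' references missing valley ", j,
           " of marker ", mk)
    v[j]
  }
  terminals <- setdiff(unique(rules$cell_type), stats::na.omit(rules$parent))
  labels <- rep("ungated", nrow(values))
  for (ct in terminals) {
    chain <- rule_chain(rules, ct)
    match_ct <- rep(TRUE, nrow(values))
    for (i in seq_len(nrow(chain))) {
      mk <- chain$marker[i]; j <- chain$valley[i]
      x <- values[, mk]
      cond <- switch(chain$relation[i],
        above_valley = x >= get_valley(mk, j, ct),
        below_valley = x < get_valley(mk, j, ct),
        between_valleys = x >= get_valley(mk, j, ct) &
                          x < get_valley(mk, j + 1L, ct))
      cond[is.na(cond)] <- FALSE
      match_ct <- match_ct & cond
    }
    labels[match_ct & labels == "ungated"] <- ct
  }
  thr <- do.call(rbind, lapply(names(valleys), function(mk) {
    v <- valleys[[mk]]
    if (length(v) == 0) return(NULL)
    data.frame(marker = mk, valley = seq_along(v), threshold = unname(v))
  }))
  structure(list(labels = labels, thresholds = thr), class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  tb <- sort(table(x$labels), decreasing = TRUE)
  cat("gate_result:", length(x$labels), "cells;",
      paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Auto-gating accuracy against reference labels
#'
#' Per reference cell type: the fraction of its cells whose auto-gate label
#' matches (after optional label mapping). Classes absent from the reference
#' are reported `NA` and excluded from the macro average.
#'
#' @param result a [auto_gate()] result (or a character label vector).
#' @param reference per-cell reference labels.
#' @param label_map optional named character vector mapping reference labels
#'   to gate labels; every reference label must be mapped when given.
#' @return list with `per_class` (data frame `cell_type`, `n`, `accuracy`)
#'   and `macro` (mean over non-`NA` classes).
#' @export
gating_accuracy <- function(result, reference, label_map = NULL) {
  pred <- if (inherits(result, "gate_result")) result$labels else result
  if (length(pred) != length(reference))
    stop("reference must cover the gated cells")
  ref <- as.character(reference)
  if (!is.null(label_map)) {
    unmapped <- setdiff(unique(ref), names(label_map))
    if (length(unmapped) > 0)
      stop("unmapped reference label(s): ", toString(unmapped))
    ref <- unname(label_map[ref])
  }
  classes <- sort(unique(ref))
  acc <- vapply(classes, function(ct) {
    sel <- ref == ct
    if (!any(sel)) NA_real_ else mean(pred[sel] == ct)
  }, numeric(1))
  per_class <- data.frame(cell_type = classes,
                          n = as.vector(table(factor(ref, classes))),
                          accuracy = unname(acc))
  list(per_class = per_class, macro = mean(acc, na.rm = TRUE))
}

#' Percent positivity of a marker in a cell subset
#'
#' Fraction of the subset's cells at or above the marker's aligned valley.
#' A rank-based quantity: it is invariant under any strictly monotone
#' re-normalization that fixes the valley's rank position, so per-batch
#' positivity is preserved by alignment.
#'
#' @param values cells x markers matrix of (normalized) arcsinh values.
#' @param valleys named list of aligned valley locations per marker.
#' @param marker marker name.
#' @param subset logical or integer index of the cells to summarize
#'   (default: all).
#' @param valley_index which valley is the positivity threshold (default 1).
#' @return fraction in `[0, 1]`.
#' @export
percent_positive <- function(values, valleys, marker,
                             subset = seq_len(nrow(values)),
                             valley_index = 1L) {
  x <- values[subset, marker]
  if (length(x) == 0) stop("empty cell subset")
  v <- valleys[[marker]]
  if (is.null(v) || length(v) < valley_index)
    stop("marker '", marker, "' has no valley ", valley_index)
  mean(x >= v[valley_index], na.rm = TRUE)
}
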