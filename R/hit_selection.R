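# Annotation-driven hit-filter cascade: from the ranked specific-neighbour
# list to an experimentally testable hit list, with a full audit trail.

#' Configuration of the hit-filter cascade
#'
#' Filters are applied in this fixed order (each may be disabled):
#' exclusion of proteins found in the initial experimental interactor sets;
#' restriction to the top fraction of the ranked list; exclusion by tissue
#' expression level; exclusion by functional keyword; exclusion of known
#' prior interactors; intersection with an explicit manual keep list (the
#' stand-in for a non-reproducible literature-mining step — it can only
#' remove, never add).
#'
#' @param exclude_experimental_sets Drop proteins flagged
#'   `in_experimental_sets` (default `TRUE`).
#' @param top_fraction Keep only the first `ceiling(top_fraction * n)` of
#'   the ranked candidates surviving so far (default 0.25).
#' @param exclude_expression_levels Expression levels to drop (default
#'   `"low"`; proteins with level `"not_available"` are kept — absence of
#'   evidence is not treated as low expression).
#' @param exclude_keywords Functional keywords whose carriers are dropped.
#'   Matching is a case-insensitive exact comparison of annotation labels,
#'   not substring search, so every exclusion is auditable. The default
#'   removes nucleic-acid/translation machinery unlikely to act at the
#'   plasma membrane.
#' @param exclude_prior_interactors Drop proteins flagged as known
#'   interactors of the anchor from earlier interactome studies (default
#'   `TRUE`).
#' @param manual_keep_list Optional character vector; when supplied, the
#'   surviving candidates are intersected with it.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(exclude_experimental_sets = TRUE,
                          top_fraction = 0.25,
                          exclude_expression_levels = "low",
                          exclude_keywords = c("ribosomal", "elongation",
                                               "transcription factor",
                                               "HNRNP", "RNA processing",
                                               "nuclear"),
                          exclude_prior_interactors = TRUE,
                          manual_keep_list = NULL) {
  stopifnot(is.null(top_fraction) ||
              (top_fraction > 0 && top_fraction <= 1))
  structure(list(
    exclude_experimental_sets = isTRUE(exclude_experimental_sets),
    top_fraction = top_fraction,
    exclude_expression_levels = exclude_expression_levels,
    exclude_keywords = exclude_keywords,
    exclude_prior_interactors = isTRUE(exclude_prior_interactors),
    manual_keep_list = manual_keep_list
  ), class = "filter_config")
}

#' Read a protein annotation table
#'
#' Expects a tab-separated file with columns `protein`,
#' `expression_level` (one of low/medium/high/not_available),
#' `keywords` (semicolon-separated functional labels, may be empty),
#' `prior_interactor` and `in_experimental_sets` (TRUE/FALSE).
#'
#' @param path TSV file path.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein", "expression_level", "keywords",
                "prior_interactor", "in_experimental_sets")
  miss <- setdiff(required, names(ann))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ann
}

# internal: align annotations to a candidate vector, applying the defaults
# for unknown proteins (not_available expression, no keywords, flags off).
annotation_lookup <- function(candidates, ann) {
  n <- length(candidates)
  out <- data.frame(protein = candidates,
                    expression_level = rep("not_available", n),
                    keywords = rep("", n),
                    prior_interactor = rep(FALSE, n),
                    in_experimental_sets = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (!is.null(ann) && nrow(ann)) {
    i <- match(candidates, ann$protein)
    hit <- !is.na(i)
    out$expression_level[hit] <- as.character(ann$expression_level[i[hit]])
    out$keywords[hit] <- as.character(ann$keywords[i[hit]])
    out$prior_interactor[hit] <- as.logical(ann$prior_interactor[i[hit]])
    out$in_experimental_sets[hit] <-
      as.logical(ann$in_experimental_sets[i[hit]])
  }
  out$keyword_list <- lapply(strsplit(out$keywords, ";", fixed = TRUE),
                             function(k) tolower(trimws(k[nzchar(trimws(k))])))
  out
}

#' Apply the hit-filter cascade to a ranked candidate list
#'
#' Runs the filters of a [filter_config()] in their declared order over a
#' ranked candidate table and returns the surviving hits together with an
#' audit table attributing every removal to exactly one filter, so that
#' per-filter removals plus survivors always add up to the input size.
#'
#' @param ranked Data frame with at least a `candidate` column, ordered
#'   best candidate first (e.g. the `selected` element of
#'   [select_specific_neighbors()]).
#' @param annotations Annotation data frame as from [read_annotations()] or
#'   [generate_annotations()]; proteins absent from it get the defaults
#'   (expression `not_available`, no keywords, flags `FALSE`). May be
#'   `NULL`.
#' @param config A [filter_config()].
#' @return List with `hits` (surviving rows of `ranked`, order preserved)
#'   and `audit` (data frame `filter`, `removed`, `remaining`).
#' @export
apply_filters <- function(ranked, annotations = NULL,
                          config = filter_config()) {
  stopifnot(inherits(config, "filter_config"),
            "candidate" %in% names(ranked))
  ann <- annotation_lookup(ranked$candidate, annotations)
  keep <- rep(TRUE, nrow(ranked))
  audit <- data.frame(filter = character(), removed = integer(),
                      remaining = integer(), stringsAsFactors = FALSE)
  log_step <- function(name, keep_now) {
    audit <<- rbind(audit, data.frame(
      filter = name, removed = sum(keep) - sum(keep_now),
      remaining = sum(keep_now), stringsAsFactors = FALSE))
    keep <<- keep_now
  }

  if (config$exclude_experimental_sets) {
    log_step("experimental_sets", keep & !ann$in_experimental_sets)
  }
  if (!is.null(config$top_fraction) && config$top_fraction < 1) {
    k <- ceiling(config$top_fraction * sum(keep))
    surv <- which(keep)
    keep_now <- keep
    if (length(surv) > k) keep_now[surv[-seq_len(k)]] <- FALSE
    log_step("top_fraction", keep_now)
  }
  if (length(config$exclude_expression_levels)) {
    bad <- ann$expression_level %in% config$exclude_expression_levels
    log_step("expression", keep & !bad)
  }
  if (length(config$exclude_keywords)) {
    excl <- tolower(config$exclude_keywords)
    bad <- vapply(ann$keyword_list, function(k) any(k %in% excl),
                  logical(1))
    log_step("keywords", keep & !bad)
  }
  if (config$exclude_prior_interactors) {
    log_step("prior_interactors", keep & !ann$prior_interactor)
  }
  if (!is.null(config$manual_keep_list)) {
    log_step("manual_keep_list",
             keep & ranked$candidate %in% config$manual_keep_list)
  }

  if (!any(keep)) warning("no candidate survives the filter cascade")
  attr(audit, "input_size") <- nrow(ranked)
  list(hits = ranked[keep, , drop = FALSE], audit = audit)
}
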