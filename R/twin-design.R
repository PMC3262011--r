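#' Sample sheet for a discordant twin cohort
#'
#' Wraps a data frame with one row per array/sample. Pairing logic for all
#' paired analyses is driven from this object. Technical replicates point at
#' the sample they replicate via `replicate_of`; excluded samples never enter
#' any statistic.
#'
#' @param df data frame with columns `sample_id`, `pair_id`, `status`
#'   (`affected`/`unaffected`), `cell_type`, and optionally `replicate_of`
#'   (NA for primary samples) and `excluded` (logical) + `exclude_reason`.
#' @return Object of class `twin_design` (a data frame).
#' @export
twin_design <- function(df) {
  req <- c("sample_id", "pair_id", "status", "cell_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) ct_abort("sample sheet misses column(s): ",
                             paste(miss, collapse = ", "))
  if (is.null(df$replicate_of)) df$replicate_of <- NA_character_
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$exclude_reason)) df$exclude_reason <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  df$pair_id <- as.character(df$pair_id)
  df$status <- as.character(df$status)
  df$cell_type <- as.character(df$cell_type)
  df$replicate_of <- as.character(df$replicate_of)
  df$excluded <- as.logical(df$excluded)
  if (anyDuplicated(df$sample_id))
    ct_abort("duplicate sample_id in sample sheet: ",
             df$sample_id[duplicated(df$sample_id)][1])
  bad <- setdiff(df$status, c("affected", "unaffected"))
  if (length(bad)) ct_abort("invalid status value(s): ",
                            paste(bad, collapse = ", "))
  refs <- df$replicate_of[!is.na(df$replicate_of)]
  orphan <- setdiff(refs, df$sample_id)
  if (length(orphan)) ct_abort("replicate_of references unknown sample(s): ",
                               paste(orphan, collapse = ", "))
  class(df) <- c("twin_design", "data.frame")
  df
}

is_replicate <- function(design) !is.na(design$replicate_of)

#' Primary (non-replicate, non-excluded) samples of a design
#' @param design a [twin_design()].
#' @param cell_type optional cell type filter.
#' @return A `twin_design` subset.
#' @export
active_samples <- function(design, cell_type = NULL) {
  keep <- !design$excluded & !is_replicate(design)
  if (!is.null(cell_type)) keep <- keep & design$cell_type %in% cell_type
  design[keep, , drop = FALSE]
}

#' Complete discordant pairs for a cell type
#'
#' A pair is complete when it has exactly one affected and one unaffected
#' primary, non-excluded sample in the given cell type.
#'
#' @param design a [twin_design()].
#' @param cell_type cell type to pair within.
#' @return Data frame with columns `pair_id`, `unaffected`, `affected`
#'   (sample ids), ordered by `pair_id`.
#' @export
complete_pairs <- function(design, cell_type) {
  act <- active_samples(design, cell_type)
  out <- lapply(split(act, act$pair_id), function(g) {
    u <- g$sample_id[g$status == "unaffected"]
    a <- g$sample_id[g$status == "affected"]
    if (length(u) == 1L && length(a) == 1L)
      data.frame(pair_id = g$pair_id[1], unaffected = u, affected = a,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(pair_id = character(), unaffected = character(),
                      affected = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$pair_id), , drop = FALSE]
}

#' Validate a design against the matrices it will be analysed with
#'
#' Checks pair completeness per cell type, sample presence in each matrix,
#' the set of pairs shared across assays (required by the integration step),
#' and that exclusions are applied. Side-effect-free; returns a report.
#'
#' @param design a [twin_design()].
#' @param matrices named list of [feature_matrix()] objects (e.g.
#'   `list(methylation = beta, expression = expr)`).
#' @param require_complete if `TRUE`, incomplete pairs raise an error
#'   naming the pair.
#' @return A list of class `cotwin_validation` with per-cell-type pair
#'   counts, missing samples per matrix, shared pairs, and exclusions.
#' @export
validate_inputs <- function(design, matrices = list(),
                            require_complete = FALSE) {
  cts <- sort(unique(design$cell_type))
  pairs_by_ct <- lapply(setNames(cts, cts),
                        function(ct) complete_pairs(design, ct))
  n_pairs <- vapply(pairs_by_ct, nrow, integer(1))
  incomplete <- lapply(setNames(cts, cts), function(ct) {
    act <- active_samples(design, ct)
    setdiff(unique(act$pair_id), pairs_by_ct[[ct]]$pair_id)
  })
  if (require_complete) {
    bad <- unlist(incomplete)
    if (length(bad))
      ct_abort("incomplete pair(s) in paired analysis: ",
               paste(unique(bad), collapse = ", "))
  }
  missing <- lapply(matrices, function(m)
    setdiff(design$sample_id[!design$excluded], sample_ids(m)))
  shared_pairs <- lapply(setNames(cts, cts), function(ct) {
    p <- pairs_by_ct[[ct]]
    if (!length(matrices)) return(p$pair_id)
    ok <- rep(TRUE, nrow(p))
    for (m in matrices) {
      sid <- sample_ids(m)
      ok <- ok & p$unaffected %in% sid & p$affected %in% sid
    }
    p$pair_id[ok]
  })
  structure(list(
    n_pairs = n_pairs,
    pairs = pairs_by_ct,
    incomplete_pairs = incomplete,
    missing_samples = missing,
    shared_pairs = shared_pairs,
    excluded = design$sample_id[design$excluded],
    ok = all(!vapply(missing, length, integer(1)))
  ), class = "cotwin_validation")
}

#' @export
print.cotwin_validation <- function(x, ...) {
  cat("<cotwin_validation>\n  complete pairs:",
      paste(sprintf("%s=%d", names(x$n_pairs), x$n_pairs), collapse = ", "),
      "\n  excluded samples:", length(x$excluded),
      "\n  matrices ok:", x$ok, "\n")
  invisible(x)
}
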