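#' Feature-by-sample matrix with a value-kind tag
#'
#' The central container of the pipeline: a numeric matrix with features
#' (CpG probes or genes) in rows and samples in columns, tagged with the
#' kind of value it holds. Methylation beta values and gene-level beta
#' averages must lie in \[0, 1\].
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids).
#' @param kind one of `"methylation-beta"`, `"expression-intensity"`,
#'   `"expression-log2"`, `"gene-beta"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values,
                           kind = c("methylation-beta", "expression-intensity",
                                    "expression-log2", "gene-beta")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    ct_abort("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ct_abort("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    ct_abort("duplicate feature ids: ",
             paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
                   collapse = ", "))
  if (anyDuplicated(colnames(values)))
    ct_abort("duplicate sample ids: ",
             paste(unique(colnames(values)[duplicated(colnames(values))])[1:3],
                   collapse = ", "))
  if (kind %in% c("methylation-beta", "gene-beta")) {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      ct_abort(sprintf(
        "beta value out of [0,1] at feature '%s', sample '%s' (value %g)",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        values[bad[1, 1], bad[1, 2]]))
    }
  }
  if (kind == "expression-intensity" && any(values < 0, na.rm = TRUE))
    ct_abort("expression intensities must be non-negative")
  structure(list(values = values, kind = kind), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of a feature matrix
#' @param x a [feature_matrix()].
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Per-pair co-twin differences
#'
#' Holds one column per complete twin pair, oriented unaffected minus
#' affected throughout the pipeline.
#'
#' @param values numeric matrix, features x pairs, rownames = feature ids,
#'   colnames = pair ids.
#' @param kind `"deltaBeta"` (from beta-valued input) or `"logFC"`
#'   (from log2 expression input).
#' @param cell_type cell type the differences were computed in.
#' @return Object of class `paired_differences`.
#' @export
paired_differences <- function(values, kind = c("deltaBeta", "logFC"),
                               cell_type = NA_character_) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    ct_abort("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ct_abort("'values' must carry feature and pair ids as dimnames")
  if (kind == "deltaBeta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1 || rng[2] > 1)
      ct_abort("deltaBeta values must lie in [-1, 1]")
  }
  structure(list(values = values, kind = kind, cell_type = cell_type,
                 orientation = "unaffected-minus-affected"),
            class = "paired_differences")
}

#' @export
print.paired_differences <- function(x, ...) {
  cat(sprintf("<paired_differences> %d features x %d pairs, kind = %s (%s)\n",
              nrow(x$values), ncol(x$values), x$kind, x$orientation))
  invisible(x)
}

#' @export
dim.paired_differences <- function(x) dim(x$values)
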