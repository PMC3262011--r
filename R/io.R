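#' Read / write feature matrices as TSV
#'
#' The canonical matrix dialect is tab-separated UTF-8 with '.' as decimal
#' separator, a header row of sample ids and the feature id in the first
#' column. Missing values are written as `NA`. Round-tripping preserves
#' values to at least 12 significant digits.
#'
#' @param path file path.
#' @param kind value kind, see [feature_matrix()].
#' @return `read_matrix` returns a [feature_matrix()]; `write_matrix`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path, kind = c("methylation-beta",
                                       "expression-intensity",
                                       "expression-log2", "gene-beta")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) ct_abort("matrix file needs >= 1 sample column: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    ct_abort("duplicate feature id '", ids[duplicated(ids)][1],
             "' in ", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    ct_abort(sprintf("non-numeric cell '%s' at row %d (feature '%s'), column '%s' in %s",
                     vals[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                     colnames(vals)[bad[1, 2]], path))
  dimnames(num) <- list(ids, colnames(vals))
  feature_matrix(num, kind)
}

#' @param x a [feature_matrix()].
#' @param digits significant digits for output.
#' @rdname read_matrix
#' @export
write_matrix <- function(x, path, digits = 15) {
  stopifnot(inherits(x, "feature_matrix"))
  df <- data.frame(feature_id = feature_ids(x),
                   signif(x$values, digits), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a twin-design sample sheet
#'
#' TSV with columns `sample_id`, `pair_id`, `status`, `cell_type` and
#' optional `replicate_of`, `excluded`, `exclude_reason`.
#'
#' @param path file path.
#' @return `read_design` returns a [twin_design()].
#' @export
read_design <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!is.null(df$excluded))
    df$excluded <- toupper(df$excluded) %in% c("TRUE", "T", "1", "YES")
  df$replicate_of[df$replicate_of %in% c("", "NA")] <- NA
  twin_design(df)
}

#' @param design a [twin_design()].
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a probe-to-gene map
#'
#' Two-column TSV `probe_id`, `gene_id`; many probes may map to one gene,
#' each probe maps to at most one gene.
#'
#' @param path file path.
#' @return `read_probe_map` returns a data frame of class `probe_gene_map`.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  probe_gene_map(df)
}

#' @param map probe map data frame.
#' @rdname read_probe_map
#' @export
write_probe_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @param df data frame with columns `probe_id` and `gene_id`.
#' @rdname read_probe_map
#' @export
probe_gene_map <- function(df) {
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    ct_abort("probe map needs columns probe_id, gene_id")
  df$probe_id <- as.character(df$probe_id)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$probe_id))
    ct_abort("probe mapped twice: ", df$probe_id[duplicated(df$probe_id)][1])
  class(df) <- c("probe_gene_map", "data.frame")
  df
}
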