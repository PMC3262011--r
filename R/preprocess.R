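#' Restrict a probe matrix to a whitelist
#'
#' Keeps the rows in `whitelist` (in their original matrix order), e.g. the
#' subset of array probes that map unambiguously to the genome.
#'
#' @param beta a [feature_matrix()].
#' @param whitelist character vector of probe ids to keep.
#' @return Filtered [feature_matrix()].
#' @export
filter_probes <- function(beta, whitelist) {
  stopifnot(inherits(beta, "feature_matrix"))
  if (!length(whitelist)) ct_abort("empty probe whitelist")
  keep <- feature_ids(beta) %in% whitelist
  if (!any(keep)) ct_abort("whitelist shares no probes with the matrix")
  ct_log("filter_probes: ", sum(keep), " of ", nrow(beta$values),
         " probes retained")
  feature_matrix(beta$values[keep, , drop = FALSE], beta$kind)
}

#' Quantile normalization
#'
#' Forces every sample (column) onto a common distribution: the across-column
#' mean of order statistics. Within-column ranks are preserved; ties receive
#' the mean of the reference values their ranks span. Idempotent up to float
#' tolerance.
#'
#' @param x a [feature_matrix()] with at least 2 samples and no NAs.
#' @return Normalized [feature_matrix()] of the same kind.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  v <- x$values
  if (ncol(v) < 2L) ct_abort("quantile normalization needs >= 2 samples")
  if (anyNA(v)) ct_abort("quantile normalization requires complete data")
  ref <- rowMeans(apply(v, 2, sort))
  cref <- cumsum(ref)
  out <- apply(v, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # mean of reference values spanned by each (possibly tied) rank group:
    # group of size t with average rank a occupies positions a-(t-1)/2 ...
    # a+(t-1)/2 in the sorted reference.
    t_sz <- ave(col, col, FUN = length)
    lo <- r - (t_sz - 1) / 2
    hi <- r + (t_sz - 1) / 2
    base <- ifelse(lo > 1, cref[pmax(lo - 1, 1)], 0)
    (cref[hi] - base) / t_sz
  })
  dimnames(out) <- dimnames(v)
  feature_matrix(out, x$kind)
}

#' Log2 transform of expression intensities
#'
#' `log2(value + offset)`; the default offset of 1 tolerates zero
#' intensities. The result is tagged `expression-log2`.
#'
#' @param x an intensity-valued [feature_matrix()].
#' @param offset additive offset applied before the log.
#' @return [feature_matrix()] of kind `expression-log2`.
#' @export
log2_transform <- function(x, offset = 1.0) {
  stopifnot(inherits(x, "feature_matrix"))
  v <- x$values + offset
  if (any(v <= 0, na.rm = TRUE))
    ct_abort("non-positive value after offset ", offset,
             "; cannot log2 transform")
  feature_matrix(log2(v), "expression-log2")
}

#' Average CpG probes to gene-level beta values
#'
#' Per gene and sample, the unweighted arithmetic mean of the beta values of
#' all of that gene's probes present in the matrix. Genes with no probes
#' present are omitted.
#'
#' @param beta a beta-valued [feature_matrix()].
#' @param map a [probe_gene_map()].
#' @return [feature_matrix()] of kind `gene-beta`, rows ordered by gene id.
#' @export
aggregate_cpgs_to_gene <- function(beta, map) {
  stopifnot(inherits(beta, "feature_matrix"))
  idx <- match(feature_ids(beta), map$probe_id)
  present <- !is.na(idx)
  if (!any(present)) ct_abort("no probe of the matrix appears in the map")
  v <- beta$values[present, , drop = FALSE]
  gene <- map$gene_id[idx[present]]
  gl <- rowsum(v, gene, reorder = TRUE)
  cnt <- as.vector(table(gene)[rownames(gl)])
  out <- gl / cnt
  feature_matrix(out, "gene-beta")
}

#' Per-pair co-twin differences (unaffected minus affected)
#'
#' Computes one column per complete pair within a cell type. Beta-valued
#' input yields kind `deltaBeta`; log2 expression yields `logFC`. Replicate
#' and excluded samples never contribute.
#'
#' @param x a [feature_matrix()] of kind `methylation-beta`, `gene-beta`
#'   or `expression-log2`.
#' @param design the [twin_design()].
#' @param cell_type cell type to pair within.
#' @return A [paired_differences()] object.
#' @export
compute_pair_differences <- function(x, design, cell_type) {
  stopifnot(inherits(x, "feature_matrix"))
  if (x$kind == "expression-intensity")
    ct_abort("expression must be log2 transformed before differencing")
  pairs <- complete_pairs(design, cell_type)
  sid <- sample_ids(x)
  ok <- pairs$unaffected %in% sid & pairs$affected %in% sid
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs))
    ct_abort("no complete pair with both samples in the matrix for cell type ",
             cell_type)
  d <- x$values[, pairs$unaffected, drop = FALSE] -
    x$values[, pairs$affected, drop = FALSE]
  colnames(d) <- pairs$pair_id
  kind <- if (x$kind == "expression-log2") "logFC" else "deltaBeta"
  paired_differences(d, kind, cell_type)
}

#' Within-individual cell-type differences
#'
#' The cell-type contrast front-end: pairs the two cell-type samples of the
#' same individual (by default unaffected twins only) and returns first
#' minus second cell type, suitable for the same paired statistics as the
#' co-twin contrast.
#'
#' @param x a [feature_matrix()].
#' @param design the [twin_design()].
#' @param cell_types length-2 character: contrast is
#'   `cell_types[1] - cell_types[2]`.
#' @param status which twins to use (`"unaffected"` by default).
#' @return A [paired_differences()] keyed by individual (sample pair).
#' @export
compute_celltype_differences <- function(x, design,
                                         cell_types = c("CD4", "CD8"),
                                         status = "unaffected") {
  stopifnot(inherits(x, "feature_matrix"), length(cell_types) == 2L)
  act <- active_samples(design)
  act <- act[act$status %in% status, , drop = FALSE]
  a <- act[act$cell_type == cell_types[1], , drop = FALSE]
  b <- act[act$cell_type == cell_types[2], , drop = FALSE]
  key_a <- paste(a$pair_id, a$status)
  key_b <- paste(b$pair_id, b$status)
  common <- intersect(key_a, key_b)
  sa <- a$sample_id[match(common, key_a)]
  sb <- b$sample_id[match(common, key_b)]
  sid <- sample_ids(x)
  ok <- sa %in% sid & sb %in% sid
  if (!any(ok)) ct_abort("no individual measured in both cell types")
  d <- x$values[, sa[ok], drop = FALSE] - x$values[, sb[ok], drop = FALSE]
  colnames(d) <- sub(" .*", "", common[ok])
  kind <- if (x$kind == "expression-log2") "logFC" else "deltaBeta"
  pd <- paired_differences(d, kind, paste(cell_types, collapse = "-vs-"))
  pd$orientation <- paste(cell_types[1], "minus", cell_types[2])
  pd
}
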