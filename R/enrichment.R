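#' Fisher overrepresentation of a gene set in a top-ranked list
#'
#' One-sided hypergeometric upper tail: with a background universe of size
#' `N` containing `K` members of the set, and a top list of size `n`
#' overlapping the set in `k` genes, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param top_list character vector, the ranked sublist (must be contained
#'   in `background`).
#' @param gene_set character vector of set members (intersected with the
#'   background before testing).
#' @param background character vector, the tested gene universe.
#' @return List with the 2x2 `table`, `overlap`, `p_value`, and the margins.
#' @export
fisher_overrepresentation <- function(top_list, gene_set, background) {
  background <- unique(background)
  if (!length(background)) ct_abort("empty background universe")
  top_list <- unique(top_list)
  stray <- setdiff(top_list, background)
  if (length(stray))
    ct_abort("input gene absent from background: ", stray[1])
  set_bg <- intersect(unique(gene_set), background)
  N <- length(background); K <- length(set_bg); n <- length(top_list)
  k <- length(intersect(top_list, set_bg))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2,
                dimnames = list(c("in_set", "not_in_set"),
                                c("in_top", "not_in_top")))
  list(table = tab, overlap = k, set_size = K, top_size = n,
       background_size = N, p_value = p)
}

#' Term enrichment of an input gene list with BH correction
#'
#' Per term: overlap count, frequency (percent of the input list, one
#' decimal), one-sided hypergeometric p (optionally the conservative EASE
#' variant, which decrements the observed count by one), then
#' Benjamini-Hochberg adjustment across the tested terms. Terms with zero
#' overlap are excluded before adjustment.
#'
#' @param input_list character vector of genes (subset of `background`).
#' @param terms a [gene_set_collection()].
#' @param background character vector, the tested universe.
#' @param ease use the EASE score (count - 1) instead of the standard
#'   Fisher tail.
#' @param fdr FDR threshold for the significance flag.
#' @return Data frame of enrichment records sorted by raw p: `term_id`,
#'   `term_name`, `count`, `input_size`, `frequency_pct`,
#'   `background_hits`, `background_size`, `p_raw`, `p_adj`, `significant`.
#' @export
term_enrichment <- function(input_list, terms, background, ease = FALSE,
                            fdr = 0.05) {
  stopifnot(inherits(terms, "gene_set_collection"))
  background <- unique(background)
  input_list <- unique(input_list)
  stray <- setdiff(input_list, background)
  if (length(stray))
    ct_abort("input gene absent from background: ", stray[1])
  N <- length(background); n <- length(input_list)
  recs <- lapply(names(terms), function(nm) {
    set_bg <- intersect(terms[[nm]]$genes, background)
    K <- length(set_bg)
    k <- length(intersect(input_list, set_bg))
    if (k == 0L || K == 0L) return(NULL)
    k_eff <- if (ease) k - 1L else k
    p <- phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = nm, term_name = terms[[nm]]$description,
               count = k, input_size = n,
               frequency_pct = round(100 * k / n, 1),
               background_hits = K, background_size = N,
               p_raw = p, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    return(data.frame(term_id = character(), term_name = character(),
                      count = integer(), input_size = integer(),
                      frequency_pct = numeric(), background_hits = integer(),
                      background_size = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  adj <- bh_adjust(recs$p_raw, q = fdr)
  recs$p_adj <- adj$p_adj
  recs$significant <- adj$significant
  recs <- recs[order(recs$p_raw, recs$term_id), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}
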