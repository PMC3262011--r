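#' Gene-set collections and the GMT format
#'
#' A gene-set collection maps a set name to a description and a deduplicated,
#' nonempty member list — the container used both for the disease gene set
#' (Fisher overrepresentation) and for term collections (GO-style
#' enrichment). GMT is the usual line format: name, description, then one
#' gene per tab-separated field.
#'
#' @param sets named list; each element either a character vector of genes or
#'   a list with elements `description` and `genes`.
#' @return Object of class `gene_set_collection`: named list with
#'   `description` and `genes` per set.
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    ct_abort("gene-set collection needs named, nonempty sets")
  out <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- list(description = "", genes = s)
    genes <- unique(as.character(s$genes))
    if (!length(genes)) ct_abort("gene set '", nm, "' is empty")
    list(description = as.character(s$description %||% ""), genes = genes)
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' @param path GMT file path.
#' @rdname gene_set_collection
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) ct_abort("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      ct_abort("GMT line with fewer than 3 fields: ", substr(l, 1, 60))
    list(description = f[2], genes = f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  gene_set_collection(sets)
}

#' @param x a `gene_set_collection`.
#' @rdname gene_set_collection
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x), function(nm)
    paste(c(nm, x[[nm]]$description, x[[nm]]$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
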