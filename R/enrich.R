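## Over-representation analysis: one-sided hypergeometric tail with
## Benjamini-Hochberg correction. The same machinery serves GO-style term
## maps and eQTL enrichment (term = the set of traits associated with a
## SNP, see associationTermMap).

#' Hypergeometric enrichment of a trait module
#'
#' For each term, tests over-representation of the term's traits in the
#' module: with a universe of K traits of which t carry the term and a
#' module of m traits with overlap o, the p-value is
#' P(X >= o) for X ~ Hypergeometric(t, K - t, m). Zero overlap gives p = 1
#' under this tail convention.
#'
#' @param module character vector of trait ids (non-empty, subset of the
#'   universe).
#' @param termMap named list: term id -> character vector of trait ids.
#' @param universe character vector of trait ids; defaults to all traits
#'   carrying at least one annotation.
#' @return data.frame with columns term, overlap, term_size, module_size,
#'   universe_size, p, q (BH-adjusted), sorted by p
#' @export
enrichHypergeom <- function(module, termMap, universe = NULL) {
    if (length(module) == 0) stop("empty module")
    if (is.null(universe)) universe <- sort(unique(unlist(termMap)))
    module <- unique(as.character(module))
    if (!all(module %in% universe)) stop("module must be a subset of the universe")
    K <- length(universe)
    m <- length(module)
    res <- lapply(names(termMap), function(term) {
        tt <- intersect(unique(termMap[[term]]), universe)
        t_ <- length(tt)
        o <- length(intersect(module, tt))
        p <- stats::phyper(o - 1, t_, K - t_, m, lower.tail = FALSE)
        data.frame(term = term, overlap = o, term_size = t_,
                   module_size = m, universe_size = K,
                   p = min(max(p, 0), 1), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out[order(out$p, out$term), , drop = FALSE]
}

#' Term map for eQTL enrichment: each SNP's associated trait set
#'
#' @param fit a FitResult or CoefficientMatrix from an association fit
#'   (rows = SNPs, columns = traits).
#' @param minGenes drop SNPs associated with fewer traits than this
#'   (default 1).
#' @return named list snp id -> character vector of associated trait ids,
#'   usable as \code{termMap} in \code{\link{enrichHypergeom}}
#' @export
associationTermMap <- function(fit, minGenes = 1) {
    B <- if (methods::is(fit, "FitResult")) coef(fit) else fit@B
    tri <- Matrix::summary(B)
    tri <- tri[abs(tri$x) > 0, , drop = FALSE]
    tm <- split(colnames(B)[tri$j], rownames(B)[tri$i])
    tm[vapply(tm, length, 1L) >= minGenes]
}
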