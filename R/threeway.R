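## Two-stage genome -> transcriptome -> phenome analysis and the
## post-processing of association results: cis/trans classification,
## merging of nearby SNPs, hotspot detection, triplet assembly.

.support_triples <- function(fit) {
    B <- if (methods::is(fit, "FitResult")) coef(fit) else fit@B
    tri <- Matrix::summary(B)
    tri <- tri[abs(tri$x) > 0, , drop = FALSE]
    data.frame(row = rownames(B)[tri$i], col = colnames(B)[tri$j],
               beta = tri$x, stringsAsFactors = FALSE)
}

#' Two-stage three-way association analysis
#'
#' Stage 1 maps SNPs to gene expressions with the graph-guided fused lasso;
#' stage 2 maps gene expressions (the measured values, not fitted ones) to
#' clinical traits with the two-graph fused lasso. Triplets are assembled
#' from the support product: (snp j, gene m, trait t) is reported whenever
#' B[j, m] != 0 and A[m, t] != 0.
#'
#' @param X genotypes (n x J).
#' @param Y gene expression traits (n x K).
#' @param Z clinical traits (n x q).
#' @param geneNet \linkS4class{TraitNetwork} over the genes.
#' @param traitNet \linkS4class{TraitNetwork} over the clinical traits.
#' @param hyper list with stage-1 \code{lambda}, \code{gamma} and stage-2
#'   \code{lambda2}, \code{gammaGene}, \code{gammaTrait}.
#' @param ... passed to the stage fitters (e.g. \code{signed}, \code{tol}).
#' @return list with elements \code{stage1} (FitResult, SNPs x genes),
#'   \code{stage2} (FitResult, genes x traits) and \code{triplets}
#'   (data.frame snp_id, gene_id, trait_id, beta_sg, beta_gt)
#' @export
runTwoStage <- function(X, Y, Z, geneNet, traitNet, hyper, ...) {
    s1 <- fitGFLasso(X, Y, geneNet, lambda = hyper$lambda,
                     gamma = hyper$gamma, ...)
    s2 <- fitGGFLasso(Y, Z, geneNet, traitNet, lambda = hyper$lambda2,
                      gammaGene = hyper$gammaGene,
                      gammaTrait = hyper$gammaTrait, ...)
    list(stage1 = s1, stage2 = s2, triplets = assembleTriplets(s1, s2))
}

#' Assemble SNP-gene-trait triplets from two fitted stages
#'
#' @param fitB stage-1 fit (SNPs x genes).
#' @param fitA stage-2 fit (genes x traits).
#' @return data.frame with columns snp_id, gene_id, trait_id, beta_sg,
#'   beta_gt; one row per support-product element
#' @export
assembleTriplets <- function(fitB, fitA) {
    sg <- .support_triples(fitB)
    gt <- .support_triples(fitA)
    if (nrow(sg) == 0 || nrow(gt) == 0)
        return(data.frame(snp_id = character(0), gene_id = character(0),
                          trait_id = character(0), beta_sg = numeric(0),
                          beta_gt = numeric(0), stringsAsFactors = FALSE))
    genes <- intersect(unique(sg$col), unique(gt$row))
    out <- do.call(rbind, lapply(genes, function(g) {
        a <- sg[sg$col == g, , drop = FALSE]
        b <- gt[gt$row == g, , drop = FALSE]
        data.frame(snp_id = rep(a$row, each = nrow(b)),
                   gene_id = g,
                   trait_id = rep(b$col, times = nrow(a)),
                   beta_sg = rep(a$beta, each = nrow(b)),
                   beta_gt = rep(b$beta, times = nrow(a)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out))
        return(data.frame(snp_id = character(0), gene_id = character(0),
                          trait_id = character(0), beta_sg = numeric(0),
                          beta_gt = numeric(0), stringsAsFactors = FALSE))
    out <- out[order(out$snp_id, out$gene_id, out$trait_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify associations as cis or trans
#'
#' An association between SNP j and gene m is cis when both lie on the same
#' chromosome and |pos(j) - tx_start(m)| <= window (default 10 Mb),
#' otherwise trans. Associations whose SNP or gene is absent from the maps
#' are labeled "unknown" with a warning.
#'
#' @param fit FitResult or CoefficientMatrix (SNPs x genes).
#' @param snpMap data.frame snp_id, chrom, pos.
#' @param geneMap data.frame trait_id, chrom, tx_start.
#' @param window window in bp (default 1e7).
#' @return data.frame snp_id, gene_id, beta, chrom_snp, chrom_gene,
#'   distance, label
#' @export
classifyCisTrans <- function(fit, snpMap, geneMap, window = 1e7) {
    sg <- .support_triples(fit)
    is_ <- match(sg$row, snpMap$snp_id)
    ig <- match(sg$col, geneMap$trait_id)
    chrS <- snpMap$chrom[is_]
    chrG <- geneMap$chrom[ig]
    dist <- abs(snpMap$pos[is_] - geneMap$tx_start[ig])
    label <- ifelse(is.na(is_) | is.na(ig), "unknown",
                    ifelse(chrS == chrG & dist <= window, "cis", "trans"))
    if (any(label == "unknown"))
        warning(sum(label == "unknown"), " association(s) with unmapped ids")
    data.frame(snp_id = sg$row, gene_id = sg$col, beta = sg$beta,
               chrom_snp = chrS, chrom_gene = chrG,
               distance = ifelse(chrS == chrG, dist, NA_real_),
               label = label, stringsAsFactors = FALSE)
}

#' Merge nearby SNPs associated with the same gene
#'
#' Within each gene, same-chromosome SNPs are chained by single linkage:
#' consecutive SNPs (by position) closer than \code{window} (default 2 Mb)
#' belong to one chain, and each chain collapses to a single association
#' represented by its strongest-|beta| SNP.
#'
#' @inheritParams classifyCisTrans
#' @param window merge window in bp (default 2e6).
#' @return data.frame gene_id, snp_id (representative), chrom, pos,
#'   n_snps, beta
#' @export
mergeNearbySNPs <- function(fit, snpMap, window = 2e6) {
    sg <- .support_triples(fit)
    if (nrow(sg) == 0)
        return(data.frame(gene_id = character(0), snp_id = character(0),
                          chrom = character(0), pos = integer(0),
                          n_snps = integer(0), beta = numeric(0)))
    ix <- match(sg$row, snpMap$snp_id)
    if (anyNA(ix)) stop("SNP(s) missing from the map: ",
                        paste(unique(sg$row[is.na(ix)]), collapse = ", "))
    sg$chrom <- snpMap$chrom[ix]
    sg$pos <- snpMap$pos[ix]
    out <- do.call(rbind, lapply(split(sg, list(sg$col, sg$chrom), drop = TRUE),
        function(d) {
            d <- d[order(d$pos, d$row), , drop = FALSE]
            chain <- cumsum(c(1, diff(d$pos) > window))
            do.call(rbind, lapply(split(d, chain), function(ch) {
                rep_ <- which.max(abs(ch$beta))
                data.frame(gene_id = ch$col[1], snp_id = ch$row[rep_],
                           chrom = ch$chrom[1], pos = ch$pos[rep_],
                           n_snps = nrow(ch), beta = ch$beta[rep_],
                           stringsAsFactors = FALSE)
            }))
        }))
    out <- out[order(out$gene_id, out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Detect eQTL hotspots
#'
#' Flags SNPs whose association support spans more than \code{minGenes}
#' genes (row support of the coefficient matrix).
#'
#' @param fit FitResult or CoefficientMatrix (SNPs x genes).
#' @param minGenes hotspot threshold (default 20: flagged when the SNP is
#'   associated with more than 20 genes).
#' @return data.frame snp_id, n_genes, hotspot (logical), sorted by
#'   n_genes decreasing; the threshold is in attr "minGenes"
#' @export
detectHotspots <- function(fit, minGenes = 20) {
    B <- if (methods::is(fit, "FitResult")) coef(fit) else fit@B
    counts <- Matrix::rowSums(B != 0)
    out <- data.frame(snp_id = rownames(B), n_genes = as.integer(counts),
                      hotspot = counts > minGenes, stringsAsFactors = FALSE)
    out <- out[order(-out$n_genes, out$snp_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "minGenes") <- minGenes
    out
}

#' Optionally drop X-chromosome associations
#'
#' @param assoc a data.frame with chrom_snp / chrom columns (as returned by
#'   \code{\link{classifyCisTrans}} or \code{\link{mergeNearbySNPs}}).
#' @param chromNames chromosome labels to drop (default "X").
#' @return filtered data.frame
#' @export
dropChromosome <- function(assoc, chromNames = "X") {
    col <- intersect(c("chrom_snp", "chrom"), names(assoc))[1]
    assoc[!(assoc[[col]] %in% chromNames), , drop = FALSE]
}
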