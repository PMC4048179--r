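## Synthetic three-layer data generator: genotypes with population
## structure and LD blocks, co-expressed gene modules driven by sparse SNP
## effects (including a planted trans hotspot), and clinical traits driven
## by genes. Ground truth (B, A, population labels, module membership) is
## returned for recovery experiments.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate a small cross-style eQTL panel: n = 200 haploid samples,
#' J = 100 SNPs in LD blocks of 10 (adjacent within-block correlation 0.5),
#' K = 50 genes in 5 equally sized co-expression modules (within-module
#' correlation 0.6 from a shared factor), q = 10 clinical traits. The
#' default causal architecture places one causal SNP in each of the first
#' three LD blocks driving all genes of modules 1-3, and a trans hotspot
#' SNP in block 4 regulating the last 30 genes; per-gene effect sizes are
#' heterogeneous (alternating 0.8 and 0.2 on the standardized scale: half
#' the target genes respond strongly, half weakly, as in real eQTL modules
#' where a regulator's downstream effects vary). The gene-to-trait layer
#' has modules 1-3 driving traits 1-2, 3 and 4 (effect 0.4 per gene). Unit
#' noise standard deviations. One population by default; with
#' \code{nPops > 1}, per-population allele frequencies follow the
#' Balding-Nichols construction at the given Fst.
#'
#' @param n,J,K,q sample, SNP, gene-expression and clinical-trait counts.
#' @param coding "haploid" (0/1) or "diploid" (0/1/2).
#' @param mafRange range of ancestral allele frequencies.
#' @param ldBlockSize,ldRho LD block length and within-block adjacent-SNP
#'   copying probability (adjacent correlation ~ ldRho, r^2 ~ ldRho^2).
#' @param nChrom chromosomes; SNPs and genes are laid out contiguously.
#' @param snpSpacing,geneSpacing bp between adjacent SNPs / gene starts.
#' @param nModules number of co-expression modules (contiguous equal
#'   partition of the genes).
#' @param moduleCor within-module trait correlation induced by the shared
#'   module factor.
#' @param causal list of \code{list(snp=, module=, beta=)} entries; NULL for
#'   the default three-block architecture.
#' @param hotspot \code{list(snp=, genes=, beta=)} or NULL for the default
#'   30-gene hotspot; \code{FALSE} disables it.
#' @param geneTrait list of \code{list(genes=, trait=, effect=)}; NULL for
#'   the default module-to-trait chains; \code{FALSE} disables the layer.
#' @param sigmaY,sigmaZ noise standard deviations of the two layers.
#' @param nPops,Fst population count and divergence.
#' @param seed integer seed; all generators are deterministic given the
#'   config.
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(n = 200, J = 100, K = 50, q = 10,
                      coding = c("haploid", "diploid"),
                      mafRange = c(0.1, 0.5), ldBlockSize = 10, ldRho = 0.5,
                      nChrom = 5, snpSpacing = 1e5, geneSpacing = 15e4,
                      nModules = 5, moduleCor = 0.6,
                      causal = NULL, hotspot = NULL, geneTrait = NULL,
                      sigmaY = 1, sigmaZ = 1, nPops = 1, Fst = 0.2,
                      seed = 1) {
    coding <- match.arg(coding)
    stopifnot(n >= 2, J >= 1, K >= 1, q >= 1,
              mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
              ldRho >= 0, ldRho < 1, ldBlockSize >= 1,
              nModules >= 1, nModules <= K, moduleCor >= 0, moduleCor < 1,
              sigmaY >= 0, sigmaZ >= 0, nPops >= 1, Fst >= 0, Fst < 1)
    modIdx <- split(seq_len(K), ceiling(seq_len(K) * nModules / K))
    hetBeta <- function(k) rep(c(0.8, 0.2), length.out = k)
    if (is.null(causal)) {
        nc <- min(3, nModules, floor((J - 1) / ldBlockSize) + 1)
        causal <- lapply(seq_len(nc), function(i)
            list(snp = (i - 1) * ldBlockSize + 1, module = i,
                 beta = hetBeta(length(modIdx[[i]]))))
    }
    if (is.null(hotspot)) {
        ng <- min(30, K)
        hotspot <- list(snp = min(3 * ldBlockSize + 1, J),
                        genes = seq(K - ng + 1, K), beta = hetBeta(ng))
    } else if (identical(hotspot, FALSE)) hotspot <- NULL
    if (is.null(geneTrait)) {
        ## planted chains run through modules 1-2 only, keeping them
        ## disjoint from the default hotspot targets (modules 3-5): the
        ## hotspot is a pure trans-regulatory phenomenon, not a mediator
        geneTrait <- list()
        targets <- list(intersect(1:2, seq_len(q)), intersect(3, seq_len(q)))
        for (i in seq_len(min(2, nModules))) {
            for (t in targets[[i]])
                geneTrait[[length(geneTrait) + 1L]] <-
                    list(genes = modIdx[[i]], trait = t, effect = 0.4)
        }
    } else if (identical(geneTrait, FALSE)) geneTrait <- list()
    for (cz in causal)
        stopifnot(cz$snp >= 1, cz$snp <= J, cz$module >= 1, cz$module <= nModules)
    if (!is.null(hotspot))
        stopifnot(hotspot$snp >= 1, hotspot$snp <= J,
                  all(hotspot$genes >= 1), all(hotspot$genes <= K))
    for (gt in geneTrait)
        stopifnot(all(gt$genes >= 1), all(gt$genes <= K),
                  gt$trait >= 1, gt$trait <= q)
    new("SimConfig", params = list(
        n = as.integer(n), J = as.integer(J), K = as.integer(K),
        q = as.integer(q), coding = coding, mafRange = mafRange,
        ldBlockSize = as.integer(ldBlockSize), ldRho = ldRho,
        nChrom = as.integer(nChrom), snpSpacing = snpSpacing,
        geneSpacing = geneSpacing, nModules = as.integer(nModules),
        moduleCor = moduleCor, modules = modIdx, causal = causal,
        hotspot = hotspot, geneTrait = geneTrait, sigmaY = sigmaY,
        sigmaZ = sigmaZ, nPops = as.integer(nPops), Fst = Fst,
        seed = as.integer(seed)))
}

#' Preset: cross-style haploid panel at the scale of a classic yeast cross
#' @param ... overrides passed to \code{\link{simConfig}}
#' @return a \linkS4class{SimConfig}
#' @export
yeastLikeConfig <- function(...) {
    args <- list(n = 112, J = 1260, K = 500, q = 10, coding = "haploid",
                 ldBlockSize = 20, nChrom = 16, nModules = 20)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

#' Preset: outbred-stock-style diploid panel with population structure
#' @param ... overrides passed to \code{\link{simConfig}}
#' @return a \linkS4class{SimConfig}
#' @export
mouseLikeConfig <- function(...) {
    args <- list(n = 218, J = 1000, K = 500, q = 50, coding = "diploid",
                 ldBlockSize = 10, nChrom = 19, nModules = 20,
                 nPops = 4, Fst = 0.2)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

.sim_pop_labels <- function(p) sort(rep(seq_len(p$nPops), length.out = p$n))

.snp_map <- function(p) {
    perChrom <- ceiling(p$J / p$nChrom)
    chrom <- paste0("chr", (seq_len(p$J) - 1) %/% perChrom + 1)
    pos <- ((seq_len(p$J) - 1) %% perChrom) * p$snpSpacing + 1
    data.frame(snp_id = paste0("snp", seq_len(p$J)), chrom = chrom,
               pos = as.integer(pos), stringsAsFactors = FALSE)
}

.gene_map <- function(p) {
    perChrom <- ceiling(p$K / p$nChrom)
    chrom <- paste0("chr", (seq_len(p$K) - 1) %/% perChrom + 1)
    tx <- ((seq_len(p$K) - 1) %% perChrom) * p$geneSpacing + 5e4
    data.frame(trait_id = paste0("g", seq_len(p$K)), chrom = chrom,
               tx_start = as.integer(tx), stringsAsFactors = FALSE)
}

#' Simulate genotypes with LD blocks and population structure
#'
#' Within each LD block, haplotype alleles follow a first-order Markov copy
#' process (copy the previous allele with probability ldRho, else draw fresh
#' at the block frequency), giving adjacent-SNP correlation ~ ldRho with
#' geometric decay. With multiple populations, block frequencies are drawn
#' per population by the Balding-Nichols construction
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral frequency p at the
#' configured Fst. Diploid genotypes are sums of two independent
#' haplotypes.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}) and
#'   \code{popLabels} (integer vector)
#' @export
simulateGenotypes <- function(cfg) {
    p <- cfg@params
    pops <- .sim_pop_labels(p)
    G <- .with_seed(p$seed + 101L, {
        blocks <- split(seq_len(p$J), (seq_len(p$J) - 1) %/% p$ldBlockSize)
        anc <- stats::runif(length(blocks), p$mafRange[1], p$mafRange[2])
        ## per-population block frequencies (Balding-Nichols)
        freq <- matrix(anc, length(blocks), p$nPops)
        if (p$nPops > 1 && p$Fst > 0) {
            a <- (1 - p$Fst) / p$Fst
            for (c in seq_len(p$nPops))
                freq[, c] <- stats::rbeta(length(blocks), anc * a, (1 - anc) * a)
            freq <- pmin(pmax(freq, 0.02), 0.98)
        }
        hap <- function() {
            H <- matrix(0L, p$n, p$J)
            for (b in seq_along(blocks)) {
                ix <- blocks[[b]]
                pb <- freq[b, pops]
                z <- stats::rbinom(p$n, 1, pb)
                H[, ix[1]] <- z
                for (j in ix[-1]) {
                    copy <- stats::rbinom(p$n, 1, p$ldRho)
                    fresh <- stats::rbinom(p$n, 1, pb)
                    z <- copy * z + (1 - copy) * fresh
                    H[, j] <- z
                }
            }
            H
        }
        if (p$coding == "haploid") hap() else hap() + hap()
    })
    dimnames(G) <- list(paste0("s", seq_len(p$n)), paste0("snp", seq_len(p$J)))
    list(genotypes = genotypeMatrix(G, map = .snp_map(p), coding = p$coding),
         popLabels = pops)
}

#' Simulate gene expression from genotypes
#'
#' Y = X_std B_true + module factors + Gaussian noise: each configured
#' causal SNP adds effect beta to every gene of its target module, the
#' hotspot SNP to its target genes; each module shares a latent factor with
#' loading chosen so the within-module (non-genetic) correlation equals
#' moduleCor.
#'
#' @param G \linkS4class{GenotypeMatrix} (as from
#'   \code{\link{simulateGenotypes}}).
#' @param cfg the same \linkS4class{SimConfig}.
#' @return list with \code{expression} (\linkS4class{TraitMatrix} with gene
#'   map), \code{B} (true J x K coefficient matrix) and \code{modules}
#'   (list of gene-id vectors)
#' @export
simulateExpression <- function(G, cfg) {
    p <- cfg@params
    Xs <- .standardize_cols(values(G))
    Btrue <- matrix(0, p$J, p$K,
                    dimnames = list(colnames(values(G)),
                                    paste0("g", seq_len(p$K))))
    for (cz in p$causal)
        Btrue[cz$snp, p$modules[[cz$module]]] <- cz$beta
    if (!is.null(p$hotspot))
        Btrue[p$hotspot$snp, p$hotspot$genes] <-
            Btrue[p$hotspot$snp, p$hotspot$genes] + p$hotspot$beta
    Y <- .with_seed(p$seed + 202L, {
        sig <- Xs %*% Btrue
        load <- p$sigmaY * sqrt(p$moduleCor / (1 - p$moduleCor))
        for (m in p$modules) {
            f <- stats::rnorm(p$n)
            sig[, m] <- sig[, m] + load * f
        }
        sig + matrix(stats::rnorm(p$n * p$K, sd = p$sigmaY), p$n, p$K)
    })
    rownames(Y) <- rownames(values(G))
    list(expression = traitMatrix(Y, kind = "expression",
                                  geneMap = .gene_map(p)),
         B = Btrue,
         modules = lapply(p$modules, function(m) colnames(Btrue)[m]))
}

#' Simulate clinical traits from gene expression
#'
#' Z = Y_centered A_true + Gaussian noise; shared parent genes induce
#' correlated trait clusters.
#'
#' @param Y \linkS4class{TraitMatrix} of gene expression.
#' @param cfg the same \linkS4class{SimConfig}.
#' @return list with \code{traits} (\linkS4class{TraitMatrix}, clinical) and
#'   \code{A} (true K x q coefficient matrix)
#' @export
simulateTraits <- function(Y, cfg) {
    p <- cfg@params
    Ym <- values(Y)
    Yc <- sweep(Ym, 2, colMeans(Ym))
    Atrue <- matrix(0, p$K, p$q,
                    dimnames = list(colnames(Ym), paste0("p", seq_len(p$q))))
    for (gt in p$geneTrait)
        Atrue[gt$genes, gt$trait] <- Atrue[gt$genes, gt$trait] + gt$effect
    Z <- .with_seed(p$seed + 303L,
                    Yc %*% Atrue + matrix(stats::rnorm(p$n * p$q, sd = p$sigmaZ),
                                          p$n, p$q))
    rownames(Z) <- rownames(Ym)
    list(traits = traitMatrix(Z, kind = "clinical"), A = Atrue)
}

#' Simulate a full three-layer dataset with ground truth
#'
#' @param cfg a \linkS4class{SimConfig}
#' @return list: \code{genotypes}, \code{expression}, \code{traits}, and
#'   \code{truth} (list with B, A, popLabels, modules)
#' @export
simulateDataset <- function(cfg) {
    g <- simulateGenotypes(cfg)
    e <- simulateExpression(g$genotypes, cfg)
    t <- simulateTraits(e$expression, cfg)
    list(genotypes = g$genotypes, expression = e$expression,
         traits = t$traits,
         truth = list(B = e$B, A = t$A, popLabels = g$popLabels,
                      modules = e$modules))
}
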