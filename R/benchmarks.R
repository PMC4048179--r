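## Simulation benchmarks: the package's standard evaluation protocols on
## synthetic data with known ground truth. These encode the study designs
## documented in the methods vignette (grids, selection rule, network
## threshold), so tests, scripts and users run the identical experiment.

.f1_support <- function(est, truth) {
    tp <- sum(est & truth); fp <- sum(est & !truth); fn <- sum(!est & truth)
    if (tp == 0) return(c(precision = 0, recall = 0, f1 = 0))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    c(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

## adjusted Rand index between two label vectors
.adjusted_rand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    exp_ <- si * sj / choose(n, 2)
    mx <- (si + sj) / 2
    if (mx == exp_) return(1)
    (sij - exp_) / (mx - exp_)
}

#' Support-recovery benchmark: CV-selected GFlasso vs CV-selected lasso
#'
#' For each seed, simulates the default three-layer panel
#' (\code{\link{simConfig}}), selects hyperparameters by 10-fold
#' cross-validation with the linear search and the one-standard-error rule
#' (lambda on a grid of fractions of the data's lambda_max with gamma = 0,
#' then gamma as multiples of the selected lambda), and scores the exact
#' support of the fitted coefficients against the true B. The GFlasso fit
#' is also screened for the planted trans hotspot.
#'
#' @param seeds integer vector of simulation seeds (default 1:20).
#' @param lambdaFractions lambda grid as fractions of lambda_max.
#' @param gammaFactors gamma grid as multiples of the selected lambda.
#' @param netThreshold absolute-correlation threshold of the trait network.
#' @param folds CV folds.
#' @param hotspotMin hotspot gene-count threshold (default 20).
#' @param cfg function(seed) returning a \linkS4class{SimConfig}; defaults
#'   to \code{simConfig(seed = seed)}.
#' @return data.frame with per-seed F1 of lasso and GFlasso, the selected
#'   hyperparameters, and whether the planted hotspot SNP was flagged
#' @export
benchmarkSupportRecovery <- function(seeds = 1:20,
                                     lambdaFractions = c(.1, .2, .3, .45, .65, .9),
                                     gammaFactors = c(.1, .3, 1, 3),
                                     netThreshold = 0.4, folds = 10,
                                     hotspotMin = 20,
                                     cfg = function(seed) simConfig(seed = seed)) {
    out <- lapply(seeds, function(seed) {
        config <- cfg(seed)
        d <- simulateDataset(config)
        X <- values(d$genotypes); Y <- values(d$expression)
        truth <- d$truth$B != 0
        Xs <- .standardize_cols(X); Ys <- .standardize_cols(Y)
        lamMax <- max(abs(crossprod(Xs, Ys)))
        lamGrid <- lamMax * lambdaFractions
        net <- correlationNetwork(Y, threshold = netThreshold)
        cvL <- crossValidate(function(x, y, l, g)
            fitLasso(x, y, l, standardize = FALSE, tol = 1e-5),
            X, Y, lamGrid, folds = folds, seed = seed)
        bl <- bestHyperparams(cvL)$lambda
        fl <- fitLasso(Xs, Ys, bl, standardize = FALSE)
        cvG <- crossValidate(function(x, y, l, g)
            fitGFLasso(x, y, net, l, g, standardize = FALSE, tol = 1e-5,
                       eps = 1e-4),
            X, Y, lamGrid, gammaGrid = bl * gammaFactors,
            folds = folds, seed = seed)
        bg <- bestHyperparams(cvG)
        fg <- fitGFLasso(Xs, Ys, net, bg$lambda, bg$gamma,
                         standardize = FALSE, eps = 1e-6)
        hot <- detectHotspots(fg, minGenes = hotspotMin)
        hotId <- if (!is.null(config@params$hotspot))
            paste0("snp", config@params$hotspot$snp) else NA_character_
        data.frame(seed = seed,
                   f1Lasso = .f1_support(as.matrix(coef(fl)) != 0, truth)["f1"],
                   f1GFlasso = .f1_support(as.matrix(coef(fg)) != 0, truth)["f1"],
                   lambda = bg$lambda, gamma = bg$gamma,
                   hotspotFlagged = if (is.na(hotId)) NA
                                    else hot$hotspot[hot$snp_id == hotId])
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Three-way chain-recovery benchmark
#'
#' Simulates strong planted SNP-module-trait chains (uniform effect 0.8 in
#' the genotype-to-expression layer), runs the two-stage pipeline with
#' fixed strong penalties quoted as fractions of each stage's lambda_max,
#' and scores the recovered triplets against the planted chains. Matching
#' uses the 2 Mb single-linkage merge convention: a recovered chain is
#' correct when its SNP lies on the same chromosome within 2 Mb of a causal
#' SNP for that (gene, trait) pair, and a planted chain counts as recovered
#' under the same window.
#'
#' @param seeds simulation seeds.
#' @param lambdaFrac1,gammaFrac1 stage-1 penalty fractions (of lambda_max
#'   and of the stage-1 lambda).
#' @param lambdaFrac2,gammaFrac2 stage-2 analogues.
#' @param netThreshold trait/gene network correlation threshold.
#' @param window merge window in bp (default 2e6).
#' @param hotspotMin hotspot gene-count threshold.
#' @return data.frame with per-seed precision, recall, triplet count and
#'   hotspot flag
#' @export
benchmarkChainRecovery <- function(seeds = 1:20, lambdaFrac1 = 0.65,
                                   gammaFrac1 = 0.3, lambdaFrac2 = 0.45,
                                   gammaFrac2 = 0.3, netThreshold = 0.4,
                                   window = 2e6, hotspotMin = 20) {
    out <- lapply(seeds, function(seed) {
        cfg <- simConfig(seed = seed,
                         causal = lapply(1:3, function(i)
                             list(snp = (i - 1) * 10 + 1, module = i, beta = 0.8)),
                         hotspot = list(snp = 31, genes = 21:50, beta = 0.8))
        d <- simulateDataset(cfg)
        X <- values(d$genotypes); Y <- values(d$expression); Z <- values(d$traits)
        smap <- snpMap(d$genotypes)
        geneNet <- correlationNetwork(Y, threshold = netThreshold)
        traitNet <- correlationNetwork(Z, threshold = netThreshold)
        l1 <- lambdaFrac1 * max(abs(crossprod(.standardize_cols(X),
                                              .standardize_cols(Y))))
        l2 <- lambdaFrac2 * max(abs(crossprod(.standardize_cols(Y),
                                              .standardize_cols(Z))))
        ts <- runTwoStage(X, Y, Z, geneNet, traitNet,
                          list(lambda = l1, gamma = gammaFrac1 * l1,
                               lambda2 = l2, gammaGene = gammaFrac2 * l2,
                               gammaTrait = gammaFrac2 * l2),
                          tol = 1e-6, eps = 1e-5)
        rec <- ts$triplets
        tb <- which(d$truth$B != 0, arr.ind = TRUE)
        ta <- which(d$truth$A != 0, arr.ind = TRUE)
        tru <- merge(data.frame(snp = rownames(d$truth$B)[tb[, 1]],
                                gene = colnames(d$truth$B)[tb[, 2]]),
                     data.frame(gene = rownames(d$truth$A)[ta[, 1]],
                                trait = colnames(d$truth$A)[ta[, 2]]))
        pos <- stats::setNames(smap$pos, smap$snp_id)
        chr <- stats::setNames(smap$chrom, smap$snp_id)
        near <- function(s1, s2) chr[s1] == chr[s2] & abs(pos[s1] - pos[s2]) <= window
        prec <- if (nrow(rec)) mean(mapply(function(s, g, t)
            any(tru$gene == g & tru$trait == t & near(tru$snp, s)),
            rec$snp_id, rec$gene_id, rec$trait_id)) else 0
        recl <- mean(mapply(function(s, g, t)
            any(rec$gene_id == g & rec$trait_id == t & near(rec$snp_id, s)),
            tru$snp, tru$gene, tru$trait))
        hot <- detectHotspots(ts$stage1, minGenes = hotspotMin)
        data.frame(seed = seed, precision = prec, recall = recl,
                   nTriplets = nrow(rec),
                   hotspotFlagged = hot$hotspot[hot$snp_id == "snp31"])
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Population-recovery benchmark: PCA + k-means against simulated truth
#'
#' @param seeds simulation seeds.
#' @param n,J panel size (default 200 samples, 1000 SNPs).
#' @param nPops,Fst simulated populations and divergence.
#' @return data.frame with the adjusted Rand index per seed
#' @export
benchmarkPopulationRecovery <- function(seeds = 1:20, n = 200, J = 1000,
                                        nPops = 4, Fst = 0.2) {
    out <- vapply(seeds, function(seed) {
        cfg <- simConfig(n = n, J = J, nPops = nPops, Fst = Fst, seed = seed,
                         hotspot = FALSE, geneTrait = FALSE)
        g <- simulateGenotypes(cfg)
        pa <- assignPopulations(values(g$genotypes), C = nPops, seed = seed)
        .adjusted_rand(populationLabels(pa), g$popLabels)
    }, numeric(1))
    data.frame(seed = seeds, ari = out)
}

#' Null calibration of the single-marker and heterogeneity tests
#'
#' Empirical type-I error at level \code{alpha} under independent null
#' replicates (genotype Bernoulli(0.3), Gaussian trait).
#'
#' @param nRep replicates per test (default 10000).
#' @param n samples per replicate (default 100).
#' @param alpha nominal level (default 0.05).
#' @param nPops populations for the heterogeneity test (default 4).
#' @param seed RNG seed.
#' @return named numeric vector of rejection rates for the Wald, t,
#'   likelihood-ratio and heterogeneity tests
#' @export
benchmarkTestCalibration <- function(nRep = 10000, n = 100, alpha = 0.05,
                                     nPops = 4, seed = 1) {
    .with_seed(seed, {
        pw <- pt_ <- pl <- ph <- numeric(nRep)
        pop <- rep(seq_len(nPops), length.out = n)
        for (i in seq_len(nRep)) {
            x <- stats::rbinom(n, 1, 0.3)
            y <- stats::rnorm(n)
            pw[i] <- .single_test_one(x, y, "wald")["p"]
            pt_[i] <- .single_test_one(x, y, "ttest")["p"]
            pl[i] <- .single_test_one(x, y, "lrt")["p"]
            ph[i] <- suppressWarnings(
                perPopulationAssociation(x, y, pop)$heterogeneity$p)
        }
        c(wald = mean(pw < alpha, na.rm = TRUE),
          ttest = mean(pt_ < alpha, na.rm = TRUE),
          lrt = mean(pl < alpha, na.rm = TRUE),
          heterogeneity = mean(ph < alpha, na.rm = TRUE))
    })
}
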