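## Single-marker association tests (PLINK-style baselines), genotype
## eigen-analysis, population assignment, and population-stratified
## association comparison.

.single_test_one <- function(x, y, test) {
    n <- length(x)
    if (length(unique(x)) < 2)
        return(c(stat = NA_real_, p = NA_real_, note = 1))
    if (test == "wald") {
        ## squared slope / SE from simple linear regression, chi2_1 reference
        r <- stats::cor(x, y)
        if (is.na(r) || abs(r) >= 1) {
            stat <- Inf
        } else {
            stat <- r^2 * (n - 2) / (1 - r^2)
        }
        c(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE), note = 0)
    } else if (test == "ttest") {
        g0 <- y[x == 0]
        g1 <- y[x > 0]
        if (length(g0) < 2 || length(g1) < 2)
            return(c(stat = NA_real_, p = NA_real_, note = 1))
        tt <- stats::t.test(g1, g0)   # Welch, two-sided
        c(stat = unname(tt$statistic), p = tt$p.value, note = 0)
    } else if (test == "lrt") {
        ## Gaussian likelihood ratio: 2*(l_full - l_null) = n*log(RSS0/RSS1)
        rss0 <- sum((y - mean(y))^2)
        fit <- stats::lm.fit(cbind(1, x), y)
        rss1 <- sum(fit$residuals^2)
        stat <- if (rss1 <= 0) Inf else n * log(rss0 / rss1)
        c(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE), note = 0)
    } else {   # chisq: allelic contingency test for a binary trait
        if (!all(y %in% c(0, 1)))
            stop("chisq test requires a binary (0/1) trait")
        ploidy <- if (max(x) > 1) 2 else 1
        a1 <- c(sum(x[y == 0]), sum(x[y == 1]))
        a0 <- c(ploidy * sum(y == 0), ploidy * sum(y == 1)) - a1
        tab <- rbind(a0, a1)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
            return(c(stat = NA_real_, p = NA_real_, note = 1))
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        c(stat = unname(ct$statistic), p = ct$p.value, note = 0)
    }
}

#' Single-marker association tests
#'
#' Per (SNP, trait): \code{"wald"} is the squared regression slope over its
#' standard error against a chi-squared(1) reference; \code{"ttest"} a
#' two-sided Welch t between genotype classes (carriers vs non-carriers);
#' \code{"lrt"} the Gaussian likelihood-ratio statistic n*log(RSS0/RSS1)
#' against chi-squared(1); \code{"chisq"} the allelic contingency test for
#' binary traits. Monomorphic SNPs are flagged and not computed. P-values
#' below 1e-3 are marked significant (the naive convention used for quick
#' screens); BH-adjusted q-values are also reported.
#'
#' @param X \linkS4class{GenotypeMatrix} or matrix (or single SNP vector).
#' @param Y \linkS4class{TraitMatrix}, matrix or single trait vector.
#' @param test one of "wald", "ttest", "lrt", "chisq".
#' @param sigLevel threshold for the \code{significant} flag (default 1e-3).
#' @return data.frame snp, trait, test, stat, p, q, significant, note
#'   ("monomorphic" where not computable)
#' @export
singleMarkerTest <- function(X, Y, test = c("wald", "ttest", "lrt", "chisq"),
                             sigLevel = 1e-3) {
    test <- match.arg(test)
    Xm <- if (is.numeric(X) && is.null(dim(X)))
        matrix(X, ncol = 1, dimnames = list(NULL, "snp1"))
    else .as_matrix_input(X)
    Ym <- if (is.numeric(Y) && is.null(dim(Y)))
        matrix(Y, ncol = 1, dimnames = list(NULL, "trait1"))
    else .as_matrix_input(Y)
    stopifnot(nrow(Xm) == nrow(Ym))
    res <- expand.grid(snp = colnames(Xm), trait = colnames(Ym),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    vals <- t(mapply(function(j, k) .single_test_one(Xm[, j], Ym[, k], test),
                     res$snp, res$trait))
    res$test <- test
    res$stat <- vals[, 1]
    res$p <- vals[, 2]
    res$q <- stats::p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$p) & res$p < sigLevel
    res$note <- ifelse(vals[, 3] == 1, "monomorphic", "")
    res
}

#' Genotype frequency table of a trait by genotype class
#'
#' Formatting utility over test inputs: counts (binary trait) or summary
#' statistics (continuous trait) of the phenotype within each genotype
#' class.
#'
#' @param x genotype vector.
#' @param y trait vector.
#' @return data.frame, one row per genotype class
#' @export
genotypeFrequencyTable <- function(x, y) {
    cls <- sort(unique(x))
    if (all(y %in% c(0, 1))) {
        do.call(rbind, lapply(cls, function(g) data.frame(
            genotype = g, n = sum(x == g),
            n_cases = sum(y[x == g]), n_controls = sum(x == g) - sum(y[x == g]))))
    } else {
        do.call(rbind, lapply(cls, function(g) data.frame(
            genotype = g, n = sum(x == g), mean = mean(y[x == g]),
            sd = stats::sd(y[x == g]))))
    }
}

#' Principal components of the genotype matrix
#'
#' Top eigenvectors of the sample covariance of column-standardized
#' genotypes (the individual-coordinate eigen-analysis used to visualize and
#' stratify population structure). Deterministic sign convention: the
#' largest-magnitude loading of each eigenvector is positive.
#'
#' @param X \linkS4class{GenotypeMatrix} or matrix.
#' @param k number of components (default 5; capped at n - 1).
#' @return list with \code{eigvecs} (n x k, orthonormal) and \code{eigvals}
#'   (non-increasing)
#' @export
genotypePCA <- function(X, k = 5) {
    Xm <- .as_matrix_input(X)
    n <- nrow(Xm)
    Xs <- .standardize_cols(Xm)
    if (all(abs(Xs) < .Machine$double.eps^0.5))
        stop("genotype matrix has no variance (identical samples)")
    k <- min(k, n - 1L)
    sv <- svd(Xs, nu = k, nv = 0)
    U <- sv$u
    for (i in seq_len(ncol(U))) {
        top <- which.max(abs(U[, i]))
        if (U[top, i] < 0) U[, i] <- -U[, i]
    }
    rownames(U) <- rownames(Xm)
    list(eigvecs = U, eigvals = (sv$d[seq_len(k)]^2) / (n - 1))
}

#' Assign samples to populations by k-means on eigenvector coordinates
#'
#' k-means (20 restarts, deterministic under \code{seed}) on the top
#' eigenvector coordinates; labels are canonicalized by decreasing cluster
#' size.
#'
#' @param x output of \code{\link{genotypePCA}}, an eigvecs matrix, or a
#'   \linkS4class{GenotypeMatrix} (PCA is run first).
#' @param C number of populations (C = 1 labels all samples 1; C > n is an
#'   error).
#' @param seed integer seed for the k-means restarts.
#' @return a \linkS4class{PopulationAssignment}
#' @export
assignPopulations <- function(x, C, seed = 1) {
    ev <- if (is.list(x) && !is.null(x$eigvecs)) x$eigvecs
          else if (is.matrix(x)) x
          else genotypePCA(x)$eigvecs
    n <- nrow(ev)
    stopifnot(C >= 1)
    if (C > n) stop("more populations than samples")
    if (C == 1) {
        lab <- rep(1L, n)
    } else {
        km <- .with_seed(seed, stats::kmeans(ev, centers = C, nstart = 20,
                                             iter.max = 100))
        ## canonical labels: decreasing cluster size, ties by first sample
        sizes <- tabulate(km$cluster, C)
        first <- vapply(seq_len(C), function(c) min(which(km$cluster == c)), 1L)
        ord <- order(-sizes, first)
        lab <- match(km$cluster, ord)
    }
    names(lab) <- rownames(ev)
    new("PopulationAssignment", labels = as.integer(lab), eigvecs = ev,
        method = "kmeans_pca")
}

#' Population-stratified association with a heterogeneity test
#'
#' Runs the chosen single-marker test within each population (populations
#' below the size floor are skipped with a warning) and assesses
#' heterogeneity of the association across populations by the genotype x
#' population interaction F-test in the pooled linear model
#' y ~ x * population vs y ~ x + population. With a single population the
#' heterogeneity p-value is undefined (NA, flagged).
#'
#' @param x genotype vector (single SNP).
#' @param y trait vector.
#' @param pops \linkS4class{PopulationAssignment} or label vector.
#' @param test test passed to \code{\link{singleMarkerTest}}.
#' @param minSize minimum per-population sample size (default 3).
#' @return list with \code{perPopulation} (data.frame) and
#'   \code{heterogeneity} (list: statistic, df, p, note)
#' @export
perPopulationAssociation <- function(x, y, pops, test = "wald", minSize = 3) {
    lab <- if (methods::is(pops, "PopulationAssignment")) populationLabels(pops) else as.integer(as.factor(pops))
    stopifnot(length(lab) == length(x), length(x) == length(y))
    cs <- sort(unique(lab))
    per <- do.call(rbind, lapply(cs, function(c) {
        idx <- lab == c
        if (sum(idx) < minSize) {
            warning("population ", c, " below size floor; skipped")
            return(data.frame(pop = c, n = sum(idx), test = test,
                              stat = NA_real_, p = NA_real_,
                              note = "too_small", stringsAsFactors = FALSE))
        }
        r <- singleMarkerTest(x[idx], y[idx], test)
        data.frame(pop = c, n = sum(idx), test = test, stat = r$stat,
                   p = r$p, note = r$note, stringsAsFactors = FALSE)
    }))
    if (length(cs) < 2) {
        het <- list(statistic = NA_real_, df = c(NA_real_, NA_real_),
                    p = NA_real_, note = "single_population")
    } else {
        pf <- factor(lab)
        full <- stats::lm(y ~ x * pf)
        red <- stats::lm(y ~ x + pf)
        an <- stats::anova(red, full)
        het <- list(statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                    p = an$`Pr(>F)`[2], note = "interaction_F")
    }
    list(perPopulation = per, heterogeneity = het)
}
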