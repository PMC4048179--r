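test_that("matrix TSV round trips are lossless on canonical files", {
    set.seed(10)
    for (i in 1:5) {
        n <- sample(3:8, 1); J <- sample(2:6, 1)
        G <- matrix(as.numeric(rbinom(n * J, 1, 0.4)), n, J,
                    dimnames = list(paste0("s", 1:n), paste0("snp", 1:J)))
        map <- data.frame(snp_id = colnames(G),
                          chrom = sample(c("chr1", "chr2"), J, TRUE),
                          pos = sample.int(1e6, J))
        g <- genotypeMatrix(G, map = map, coding = "haploid")
        f1 <- tempfile(fileext = ".tsv")
        writeMatrix(g, f1)
        g2 <- readMatrix(f1, "genotype", coding = "haploid", map = map)
        expect_identical(values(g2), values(g))
        expect_identical(snpMap(g2), snpMap(g))
        ## writing the re-read object reproduces the file byte-for-byte
        f2 <- tempfile(fileext = ".tsv")
        writeMatrix(g2, f2)
        expect_identical(readLines(f1), readLines(f2))
        ## trait round trip with missing values
        Tm <- matrix(rnorm(n * J), n, J,
                     dimnames = list(paste0("s", 1:n), paste0("t", 1:J)))
        Tm[sample(length(Tm), 2)] <- NA
        tm <- traitMatrix(Tm, kind = "clinical")
        f3 <- tempfile(fileext = ".tsv")
        writeMatrix(tm, f3)
        expect_equal(values(readMatrix(f3, "trait", kind = "clinical")),
                     values(tm))
    }
})

test_that("readMatrix validates coding and reports offending cells", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tsnp1\tsnp2", "s1\t0\t1", "s2\t3\t0"), f)
    expect_error(readMatrix(f, "genotype", coding = "diploid"),
                 "row 's2', column 'snp1'")
    f2 <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tsnp1\tsnp2", "s1\t0\tabc", "s2\t1\t0"), f2)
    expect_error(readMatrix(f2, "genotype"), "non-numeric.*'abc'")
    f3 <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tsnp1\tsnp1", "s1\t0\t1"), f3)
    expect_error(readMatrix(f3, "genotype"), "duplicate")
    ## 3x2 identity round trip through the constructor
    f4 <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ta\tb", "s1\t0\t1", "s2\t1\t1", "s3\t0\t0"), f4)
    g <- readMatrix(f4, "genotype", coding = "haploid")
    expect_equal(dim(values(g)), c(3L, 2L))
    ## genotype missing values rejected at load
    f5 <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ta", "s1\tNA"), f5)
    expect_error(readMatrix(f5, "genotype"), "missing")
})

test_that("edge list and network round trip preserves edges and weights", {
    ids <- paste0("t", 1:5)
    net <- traitNetwork(ids, data.frame(a = c("t2", "t3"), b = c("t1", "t5"),
                                        w = c(0.4, 0.9), r = c(-0.4, 0.9)))
    ## canonicalized to node order
    expect_true(all(match(edges(net)$a, ids) < match(edges(net)$b, ids)))
    f <- tempfile(fileext = ".tsv")
    writeEdgeList(net, f)
    net2 <- readEdgeList(f, nodes = ids)
    expect_equal(edges(net2)$w, edges(net)$w)
    expect_equal(edges(net2)$r, edges(net)$r)
    expect_error(traitNetwork(ids, data.frame(a = "t1", b = "t1", w = 1, r = 1)),
                 "self-edge")
})

test_that("k-NN imputation matches the exhaustive-distance oracle", {
    knn_oracle <- function(M, k) {
        n <- nrow(M)
        out <- M
        for (i in seq_len(n)) for (j in seq_len(ncol(M))) {
            if (!is.na(M[i, j])) next
            d <- rep(Inf, n)
            for (u in seq_len(n)) {
                if (u == i) next
                sh <- which(!is.na(M[i, ]) & !is.na(M[u, ]))
                if (length(sh)) d[u] <- sqrt(mean((M[i, sh] - M[u, sh])^2))
            }
            cand <- order(d, seq_len(n))
            cand <- cand[!is.na(M[cand, j]) & is.finite(d[cand])]
            out[i, j] <- mean(M[cand[seq_len(min(k, length(cand)))], j])
        }
        out
    }
    set.seed(3)
    for (rep in 1:10) {
        n <- sample(4:8, 1); K <- sample(3:5, 1)
        M <- matrix(rnorm(n * K), n, K,
                    dimnames = list(paste0("s", 1:n), paste0("t", 1:K)))
        idx <- sample(length(M), 3)
        ## keep at least one observed value per row
        M[idx] <- NA
        if (any(rowSums(!is.na(M)) == 0)) next
        k <- sample(1:(n - 1), 1)
        expect_equal(imputeKNN(M, k), knn_oracle(M, k), tolerance = 1e-12)
    }
    ## no missing -> unchanged object
    M <- matrix(rnorm(12), 4, 3)
    tm <- traitMatrix(M)
    expect_identical(imputeKNN(tm, 2), tm)
    ## one missing cell, all other samples identical -> the shared value
    M2 <- rbind(c(1, 5), c(1, 5), c(1, 5), c(1, NA))
    expect_equal(imputeKNN(M2, 3)[4, 2], 5)
    ## a fully missing sample is an error
    M3 <- rbind(c(1, 2), c(NA, NA))
    expect_error(imputeKNN(M3, 1), "all traits missing")
})

test_that("missingness filter removes traits strictly above the threshold", {
    ## 31% missing removed at the 30% threshold; 30% retained
    M <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    M[1:31, 1] <- NA
    M[1:30, 2] <- NA
    out <- filterMissingTraits(M, 0.30)
    expect_identical(colnames(out), c("b", "c"))
    expect_identical(colnames(filterMissingTraits(M, 1.0)), c("a", "b", "c"))
    ## randomized masks match an independent counting filter, order kept,
    ## and filtering is idempotent
    set.seed(4)
    for (rep in 1:10) {
        M <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("t", 1:6)))
        M[sample(length(M), 25)] <- NA
        thr <- runif(1, 0.15, 0.9)
        keep <- colnames(M)[colMeans(is.na(M)) <= thr]
        out <- filterMissingTraits(M, thr)
        expect_identical(colnames(out), keep)
        expect_identical(filterMissingTraits(out, thr), out)
    }
})

test_that("standardization is exact, flags constant columns, and is idempotent", {
    M <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
    z <- standardizeMatrix(M, "zscore")
    expect_equal(colMeans(z), c(a = 0, b = 0))
    expect_equal(sd(z[, 1]), 1)
    expect_equal(z[, 2], c(0, 0, 0), ignore_attr = TRUE)
    expect_identical(attr(z, "zeroVariance"), c(a = FALSE, b = TRUE))
    set.seed(5)
    M2 <- matrix(rnorm(40), 8, 5)
    z1 <- standardizeMatrix(M2)
    expect_equal(standardizeMatrix(z1), z1, tolerance = 1e-12)
    cz <- standardizeMatrix(M2, "center")
    expect_equal(colMeans(cz), rep(0, 5))
})

test_that("SNP feature tables standardize continuous columns only", {
    f <- cbind(exon = c(0, 1, 0, 1), cons = c(0.2, 0.9, 0.4, 0.8))
    rownames(f) <- paste0("snp", 1:4)
    ft <- snpFeatureTable(f)
    expect_identical(values(ft)[, "exon"], f[, "exon"])
    expect_equal(mean(values(ft)[, "cons"]), 0)
    expect_equal(sd(values(ft)[, "cons"]), 1)
})
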