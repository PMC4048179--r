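test_that("correlation network matches an all-pairs oracle and edge cases", {
    set.seed(21)
    ## perfect correlation
    y1 <- rnorm(30)
    Y <- cbind(a = y1, b = 2 * y1, c = rnorm(30))
    net <- correlationNetwork(Y, threshold = 0.99)
    e <- edges(net)
    expect_equal(e$w[e$a == "a" & e$b == "b"], 1)
    ## independent traits, high threshold: no edges
    Y2 <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("t", 1:5)))
    expect_equal(nrow(edges(correlationNetwork(Y2, 0.99))), 0)
    ## brute-force oracle on a 6-trait matrix
    Y3 <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("t", 1:6)))
    thr <- 0.15
    net3 <- correlationNetwork(Y3, thr)
    want <- NULL
    for (i in 1:5) for (j in (i + 1):6) {
        r <- cor(Y3[, i], Y3[, j])
        if (abs(r) >= thr)
            want <- rbind(want, data.frame(a = paste0("t", i), b = paste0("t", j),
                                           w = abs(r), r = r))
    }
    got <- edges(net3)[order(edges(net3)$a, edges(net3)$b), ]
    want <- want[order(want$a, want$b), ]
    expect_equal(got$w, want$w, tolerance = 1e-12)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    ## zero-variance trait excluded with a warning
    Y4 <- cbind(Y3, const = 1)
    expect_warning(net4 <- correlationNetwork(Y4, thr), "zero-variance")
    expect_false("const" %in% nodes(net4))
})

test_that("soft-power network: beta = 1 reduction, closed form, and fit recomputation", {
    set.seed(22)
    Y <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("g", 1:8)))
    ## beta = 1 equals the correlation network at threshold 0
    sp <- softPowerNetwork(Y, betaGrid = 1, r2Target = 0)
    cn <- correlationNetwork(Y, threshold = 0)
    eo <- function(net) { e <- edges(net); e[order(e$a, e$b), ] }
    expect_equal(eo(sp)$w, eo(cn)$w, tolerance = 1e-12)
    ## equal pairwise correlation c -> every weight c^beta
    L <- rnorm(200)
    Yc <- sapply(1:5, function(i) L + rnorm(200, sd = 1))
    colnames(Yc) <- paste0("g", 1:5)
    for (b in c(2L, 4L)) {
        spb <- suppressWarnings(softPowerNetwork(Yc, betaGrid = b, r2Target = 0))
        R <- abs(cor(Yc))
        e <- edges(spb)
        for (k in seq_len(nrow(e)))
            expect_equal(e$w[k], R[e$a[k], e$b[k]]^b, tolerance = 1e-12)
    }
    ## chosen beta's R^2 matches an independent recomputation of the
    ## log-log fit on 3-block modular data
    set.seed(23)
    blocks <- do.call(cbind, lapply(1:3, function(m) {
        f <- rnorm(100)
        sapply(1:6, function(i) f + rnorm(100, sd = 0.6))
    }))
    colnames(blocks) <- paste0("g", 1:18)
    net <- suppressWarnings(softPowerNetwork(blocks, betaGrid = 1:8, r2Target = 0.8))
    beta <- net@params$beta
    A <- abs(cor(blocks))^beta
    diag(A) <- 0
    k <- rowSums(A)
    br <- exp(seq(log(min(k) * (1 - 1e-9)), log(max(k) * (1 + 1e-9)),
                  length.out = 11))
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(freq)
    r2 <- summary(lm(log10(freq[ok]) ~ log10(mk[ok])))$r.squared
    expect_equal(net@params$r2, r2, tolerance = 1e-10)
})

test_that("graphical lasso: degenerate, closed-form and stationarity checks", {
    set.seed(24)
    ## diagonal truth with a large penalty: empty edge set
    Y <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("g", 1:4)))
    expect_equal(nrow(edges(glassoNetwork(Y, rho = 2))), 0)
    ## K = 2: the nonzero pattern follows the soft-threshold of the
    ## off-diagonal covariance at rho
    L <- rnorm(80)
    Y2 <- cbind(a = L + rnorm(80, sd = 0.5), b = L + rnorm(80, sd = 0.5))
    S <- cov(Y2)
    for (rho in c(abs(S[1, 2]) * 0.5, abs(S[1, 2]) * 1.1)) {
        net <- glassoNetwork(Y2, rho)
        expect_equal(nrow(edges(net)), as.integer(abs(S[1, 2]) > rho))
    }
    ## stationarity: W = S + rho * Gamma with Gamma in the subdifferential
    Y3 <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
    Y3[, 2] <- Y3[, 1] + rnorm(100, sd = 0.7)
    rho <- 0.1
    net <- glassoNetwork(Y3, rho)
    S3 <- cov(Y3)
    W <- net@params$W
    Theta <- net@params$theta
    off <- which(upper.tri(W), arr.ind = TRUE)
    for (r in seq_len(nrow(off))) {
        i <- off[r, 1]; j <- off[r, 2]
        g <- (W[i, j] - S3[i, j]) / rho
        if (Theta[i, j] != 0) expect_equal(g, sign(Theta[i, j]), tolerance = 1e-4)
        else expect_lte(abs(g), 1 + 1e-4)
    }
    ## rho = 0 rejected in the K >= n regime
    expect_error(glassoNetwork(matrix(rnorm(5 * 6), 5, 6), 0), "rho")
})

test_that("trait trees: merge order, leaf invariant, newick round trip", {
    ## two identical traits merge at height 0
    y <- rnorm(20)
    Y <- cbind(a = y, b = y, c = rnorm(20))
    tr <- traitTree(Y)
    expect_equal(min(tr@height), 0)
    m1 <- treeMembers(tr)[[1]]
    expect_setequal(m1, c("a", "b"))
    ## 3 traits with known pairwise distances: closest pair merges first
    set.seed(25)
    base <- rnorm(50)
    Y3 <- cbind(p = base + rnorm(50, sd = 0.2), q = base + rnorm(50, sd = 0.2),
                r = rnorm(50))
    tr3 <- traitTree(Y3)
    expect_setequal(treeMembers(tr3)[[1]], c("p", "q"))
    expect_setequal(treeMembers(tr3)[[2]], c("p", "q", "r"))
    ## leaves are exactly the trait set
    expect_setequal(tr3@labels, colnames(Y3))
    ## newick round trip preserves topology, heights and node weights
    set.seed(26)
    Y8 <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("t", 1:8)))
    tr8 <- traitTree(Y8)
    f <- tempfile(fileext = ".nwk")
    writeTraitTree(tr8, f)
    tr8b <- readTraitTree(f)
    ms <- function(t) lapply(treeMembers(t), sort)
    expect_setequal(tr8b@labels, tr8@labels)
    expect_equal(ms(tr8b), ms(tr8))
    expect_equal(tr8b@height, tr8@height, tolerance = 1e-9)
    expect_equal(tr8b@nodeWeights, tr8@nodeWeights, tolerance = 1e-9)
    ## leaf weights match per trait id (leaf order follows the file)
    expect_equal(tr8b@leafWeights[match(tr8@labels, tr8b@labels)],
                 tr8@leafWeights, tolerance = 1e-9)
})

test_that("module extraction recovers planted cliques and keeps invariants", {
    ## block-diagonal network of 3 perfect cliques
    ids <- paste0("g", 1:12)
    cli <- list(ids[1:4], ids[5:8], ids[9:12])
    e <- do.call(rbind, lapply(cli, function(m) {
        cmb <- t(combn(m, 2))
        data.frame(a = cmb[, 1], b = cmb[, 2], w = 1, r = 1)
    }))
    net <- traitNetwork(ids, e)
    tr <- traitTree(net)
    ms <- extractModules(tr, net, M = 3, minSize = 3)
    expect_equal(length(modules(ms)), 3)
    got <- lapply(modules(ms), sort)
    expect_setequal(got, lapply(cli, sort))
    ## M = 1 on a single clique returns the whole clique
    net1 <- traitNetwork(ids[1:4], e[e$a %in% ids[1:4] & e$b %in% ids[1:4], ])
    ms1 <- suppressWarnings(extractModules(traitTree(net1), net1, M = 1, minSize = 2))
    expect_setequal(modules(ms1)[[1]], ids[1:4])
    ## disjointness and non-increasing scores on noisy modular data
    set.seed(27)
    Y <- do.call(cbind, lapply(1:3, function(m) {
        f <- rnorm(80)
        sapply(1:5, function(i) f + rnorm(80, sd = 0.5))
    }))
    colnames(Y) <- paste0("g", 1:15)
    netY <- correlationNetwork(Y, 0.2)
    msY <- suppressWarnings(extractModules(traitTree(Y), netY, M = 4, minSize = 3))
    expect_false(anyDuplicated(unlist(modules(msY))) > 0)
    expect_true(all(diff(moduleScores(msY)) <= 1e-12))
})

test_that("hypergeometric enrichment matches exact enumeration (universe <= 12)", {
    ## enumeration oracle: P(overlap >= o) over all size-m modules
    enum_p <- function(universe, term, module_size, obs_overlap) {
        all_mods <- combn(universe, module_size)
        hits <- apply(all_mods, 2, function(m) length(intersect(m, term)) >= obs_overlap)
        mean(hits)
    }
    set.seed(28)
    for (rep in 1:8) {
        K <- sample(6:12, 1)
        universe <- paste0("g", 1:K)
        term <- sample(universe, sample(2:(K - 1), 1))
        m <- sample(2:(K - 2), 1)
        module <- sample(universe, m)
        res <- enrichHypergeom(module, list(T = term), universe)
        o <- res$overlap[1]
        expect_equal(res$p[1], enum_p(universe, term, m, o), tolerance = 1e-12)
    }
    ## zero overlap gives p = 1 under the over-representation tail
    res0 <- enrichHypergeom(c("g1", "g2"), list(T = c("g5", "g6")),
                            universe = paste0("g", 1:6))
    expect_equal(res0$p[1], 1)
    ## BH q-values are monotone in p
    set.seed(29)
    universe <- paste0("g", 1:12)
    tm <- lapply(1:6, function(i) sample(universe, sample(2:8, 1)))
    names(tm) <- paste0("T", 1:6)
    res <- enrichHypergeom(sample(universe, 5), tm, universe)
    expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
    expect_error(enrichHypergeom(character(0), tm, universe), "empty")
    ## eQTL term maps come from the association support
    B <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 3), x = c(1, -2, 3),
                              dims = c(2, 3),
                              dimnames = list(c("snp1", "snp2"), c("g1", "g2", "g3")))
    cm <- new("CoefficientMatrix", B = B, provenance = list(algorithm = "test"))
    tm2 <- associationTermMap(cm)
    expect_setequal(tm2$snp1, c("g1", "g2"))
    expect_equal(tm2$snp2, "g3")
})

test_that("network overlap equals a set-intersection oracle", {
    ids <- paste0("t", 1:8)
    eA <- data.frame(a = c("t1", "t2", "t3"), b = c("t2", "t3", "t4"),
                     w = 1, r = 1)
    netA <- traitNetwork(ids[1:5], eA)
    expect_equal(networkOverlap(netA, netA),
                 list(pct_shared_nodes = 100, pct_shared_edges = 100))
    eB <- data.frame(a = c("t5", "t6"), b = c("t6", "t7"), w = 1, r = 1)
    netB <- traitNetwork(ids, eB)
    expect_equal(networkOverlap(netA, netB)$pct_shared_edges, 0)
    set.seed(30)
    for (rep in 1:5) {
        pick <- function() {
            cmb <- t(combn(ids, 2))
            sel <- cmb[sample(nrow(cmb), 10), ]
            traitNetwork(ids, data.frame(a = sel[, 1], b = sel[, 2], w = 1, r = 1))
        }
        nA <- pick(); nB <- pick()
        key <- function(net) paste(edges(net)$a, edges(net)$b)
        expect_equal(networkOverlap(nA, nB)$pct_shared_edges,
                     100 * mean(key(nA) %in% key(nB)))
    }
})
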