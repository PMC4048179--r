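test_that("lasso: unpenalized limit, full-shrinkage bound, and glmnet cross-check", {
    d <- rand_xy(20, 6, 2, seed = 31)
    ## lambda = 0 recovers least squares
    f0 <- fitLasso(d$X, d$Y, 0, standardize = FALSE, tol = 1e-14)
    bls <- qr.solve(d$X, d$Y)
    expect_equal(unname(as.matrix(coef(f0))), unname(bls), tolerance = 1e-6)
    ## lambda above max_j |x_j' y_k| shrinks everything to zero
    lmax <- max(abs(crossprod(d$X, d$Y)))
    fmax <- fitLasso(d$X, d$Y, lmax * 1.001, standardize = FALSE)
    expect_equal(Matrix::nnzero(coef(fmax)), 0)
    ## objective agrees with glmnet on the same problem
    skip_if_not_installed("glmnet")
    lam <- 0.3 * lmax
    f <- fitLasso(d$X, d$Y, lam, standardize = FALSE, tol = 1e-12)
    n <- nrow(d$X)
    Bg <- sapply(seq_len(ncol(d$Y)), function(k) {
        fit <- glmnet::glmnet(d$X, d$Y[, k], lambda = lam / n,
                              standardize = FALSE, intercept = FALSE,
                              thresh = 1e-14)
        as.numeric(coef(fit))[-1]
    })
    expect_equal(lasso_objective(d$X, d$Y, as.matrix(coef(f)), lam),
                 lasso_objective(d$X, d$Y, Bg, lam), tolerance = 1e-7)
})

test_that("lasso solution satisfies the KKT conditions", {
    d <- rand_xy(25, 8, 3, seed = 32)
    lam <- 2
    f <- fitLasso(d$X, d$Y, lam, standardize = FALSE, tol = 1e-13)
    B <- as.matrix(coef(f))
    G <- crossprod(d$X, d$X %*% B - d$Y)   # gradient of the quadratic part
    active <- B != 0
    expect_true(all(abs(G[active] + lam * sign(B[active])) < 1e-4))
    expect_true(all(abs(G[!active]) <= lam + 1e-4))
})

test_that("exact reductions to the lasso hold", {
    d <- rand_xy(20, 6, 3, seed = 33)
    lam <- 1.5
    fl <- fitLasso(d$X, d$Y, lam, standardize = FALSE, tol = 1e-15,
                   maxit = 50000)
    Bl <- as.matrix(coef(fl))
    tolC <- 1e-8   # max absolute coefficient discrepancy allowed
    ## gamma = 0 GFlasso
    net <- chain_net(colnames(d$Y))
    fg <- fitGFLasso(d$X, d$Y, net, lam, 0, standardize = FALSE, tol = 1e-15,
                     maxit = 50000)
    expect_lt(max(abs(as.matrix(coef(fg)) - Bl)), tolC)
    ## singleton groups with unit weights
    fgr <- fitGroupLasso(d$X, d$Y, as.list(1:6), lam, standardize = FALSE,
                         tol = 1e-15, maxit = 50000)
    expect_lt(max(abs(as.matrix(coef(fgr)) - Bl)), tolC)
    ## both-gamma-zero gGFlasso
    fgg <- fitGGFLasso(d$X, d$Y, chain_net(colnames(d$X)), net, lam, 0, 0,
                       standardize = FALSE, tol = 1e-15, maxit = 50000)
    expect_lt(max(abs(as.matrix(coef(fgg)) - Bl)), tolC)
    ## single-population MPGL equals the single-trait lasso
    y <- d$Y[, 1]
    fm <- fitMPGL(d$X, y, rep(1, nrow(d$X)), lam, standardize = TRUE,
                  tol = 1e-15, maxit = 50000)
    fl1 <- fitLasso(d$X, matrix(y, dimnames = list(NULL, "y1")), lam,
                    standardize = TRUE, tol = 1e-15, maxit = 50000)
    expect_lt(max(abs(as.matrix(coef(fm)) - as.matrix(coef(fl1)))), tolC)
    ## all-singleton structured input-output = lasso at lambda1 + lambda2
    fs <- fitStructIO(d$X, d$Y, as.list(1:6), as.list(1:3), 0.8, 0.7,
                      standardize = FALSE, tol = 1e-14, maxit = 50000)
    fl2 <- fitLasso(d$X, d$Y, 1.5, standardize = FALSE, tol = 1e-15)
    expect_lt(max(abs(as.matrix(coef(fs)) - as.matrix(coef(fl2)))), 1e-5)
    ## star tree with zero internal weight reduces TreeLasso to the lasso
    tr <- traitTree(d$Y)
    tr@nodeWeights[] <- 0
    tr@leafWeights[] <- 1
    ft <- fitTreeLasso(d$X, d$Y, tr, lam, standardize = FALSE, tol = 1e-13)
    expect_equal(as.matrix(coef(ft)), Bl, tolerance = 1e-6)
})

test_that("fusion limit: duplicated traits with a strong weight-1 edge fuse", {
    set.seed(34)
    n <- 30; J <- 6
    X <- scale(matrix(rnorm(n * J), n, J))
    y <- rnorm(n)
    Y <- cbind(y1 = y, y2 = y, y3 = rnorm(n))
    Y <- scale(Y)
    colnames(X) <- paste0("x", 1:J)
    net <- traitNetwork(colnames(Y), data.frame(a = "y1", b = "y2", w = 1, r = 1))
    lam <- 1
    f <- fitGFLasso(X, Y, net, lam, 1e3 * lam, standardize = FALSE,
                    tol = 1e-12, eps = 1e-9)
    B <- as.matrix(coef(f))
    expect_lt(max(abs(B[, "y1"] - B[, "y2"])), 1e-5)
})

test_that("objective traces are non-increasing across all solvers", {
    d <- rand_xy(25, 8, 4, seed = 35)
    net <- chain_net(colnames(d$Y), w = 0.7)
    tr <- traitTree(d$Y)
    fits <- list(
        fitLasso(d$X, d$Y, 1, standardize = FALSE),
        fitGroupLasso(d$X, d$Y, list(1:3, 4:6, 7:8), 1, standardize = FALSE),
        fitGFLasso(d$X, d$Y, net, 1, 0.5, standardize = FALSE),
        fitGFLasso(d$X, d$Y, net, 1, 0.5, engine = "spg", standardize = FALSE,
                   tol = 1e-8, maxit = 3000),
        fitTreeLasso(d$X, d$Y, tr, 1, standardize = FALSE, tol = 1e-8,
                     maxit = 3000),
        fitStructIO(d$X, d$Y, list(1:4, 5:8), list(1:2, 3:4), 0.5, 0.5,
                    standardize = FALSE),
        fitAMTL(d$X, d$Y, matrix(rnorm(16), 8, 2,
                                 dimnames = list(colnames(d$X), c("f1", "f2"))),
                1, 0.5, standardize = FALSE),
        fitMPGL(d$X, d$Y[, 1], rep(1:2, length.out = 25), 0.7))
    for (f in fits) expect_monotone_trace(f, slack = 1e-10)
})

test_that("group lasso zeroes orthogonalized groups by the KKT bound", {
    set.seed(36)
    n <- 40
    ## orthonormal design: group 2 orthogonal to group 1 AND to the part of
    ## y outside group 1's span, so its residual correlation is exactly 0
    Q <- qr.Q(qr(matrix(rnorm(n * 7), n, 7)))
    X <- Q[, 1:6] * sqrt(n - 1)
    colnames(X) <- paste0("x", 1:6)
    y <- X[, 1] * 0.8 + X[, 2] * 0.4 + Q[, 7] * 2
    Y <- matrix(y, dimnames = list(NULL, "y1"))
    f <- fitGroupLasso(X, Y, list(1:3, 4:6), 0.5, standardize = FALSE,
                       tol = 1e-12)
    B <- as.matrix(coef(f))
    expect_equal(unname(B[4:6, 1]), rep(0, 3))
    ## group-wise KKT at the solution
    G <- crossprod(X, X %*% B - Y)
    gw <- provenance(f)$groupWeights
    for (g in list(1:3, 4:6)) {
        gi <- if (identical(g, 1:3)) 1 else 2
        if (all(B[g, 1] == 0)) expect_lte(sqrt(sum(G[g, 1]^2)), 0.5 * gw[gi] + 1e-6)
        else expect_lt(sqrt(sum((G[g, 1] + 0.5 * gw[gi] * B[g, 1] /
                                 sqrt(sum(B[g, 1]^2)))^2)), 1e-4)
    }
})

test_that("TreeLasso: engines agree and the smoothing gap bound holds", {
    d <- rand_xy(25, 6, 4, seed = 37)
    tr <- traitTree(d$Y)
    lam <- 1
    fs <- fitTreeLasso(d$X, d$Y, tr, lam, standardize = FALSE, tol = 1e-10)
    fp <- fitTreeLasso(d$X, d$Y, tr, lam, engine = "prox",
                       standardize = FALSE, tol = 1e-12)
    os <- min(objectiveTrace(fs)); op <- min(objectiveTrace(fp))
    expect_lt(abs(os - op) / abs(op), 1e-4)
    ## halving mu changes the optimal objective by less than the smoothing
    ## bound mu * D
    f1 <- fitTreeLasso(d$X, d$Y, tr, lam, mu = 1e-3, standardize = FALSE,
                       tol = 1e-11)
    f2 <- fitTreeLasso(d$X, d$Y, tr, lam, mu = 5e-4, standardize = FALSE,
                       tol = 1e-11)
    D <- provenance(f1)$D
    expect_lt(abs(min(objectiveTrace(f1)) - min(objectiveTrace(f2))),
              1e-3 * D + 1e-6)
    ## hierarchical sparsity: fused subtrees share support per SNP
    B <- as.matrix(coef(fs))
    expect_true(all(dim(B) == c(6, 4)))
})

test_that("GFlasso coordinate-descent and SPG engines agree", {
    d <- rand_xy(30, 7, 4, seed = 38)
    net <- chain_net(colnames(d$Y), w = 0.8)
    cd <- fitGFLasso(d$X, d$Y, net, 1, 0.8, standardize = FALSE,
                     tol = 1e-10, eps = 1e-7)
    sp <- fitGFLasso(d$X, d$Y, net, 1, 0.8, engine = "spg",
                     standardize = FALSE, tol = 1e-10, maxit = 20000)
    obj <- function(B) {
        e <- edges(net)
        p <- lasso_objective(d$X, d$Y, B, 1)
        for (k in seq_len(nrow(e)))
            p <- p + 0.8 * e$w[k] * sum(abs(B[, e$a[k]] - B[, e$b[k]]))
        p
    }
    o1 <- obj(as.matrix(coef(cd))); o2 <- obj(as.matrix(coef(sp)))
    expect_lt(abs(o1 - o2) / abs(o1), 1e-4)
})

test_that("adaptive multi-task lasso learns to favour annotated causal SNPs", {
    ## frozen weights equal the uniform composite fit
    d <- rand_xy(25, 8, 3, seed = 39)
    fm <- matrix(rnorm(16), 8, 2, dimnames = list(colnames(d$X), c("f1", "f2")))
    f0 <- fitAMTL(d$X, d$Y, fm, 1, 0.5, updateWeights = FALSE,
                  standardize = FALSE, tol = 1e-12)
    expect_equal(unname(f0@extras$theta), c(0, 0))
    ## a binary feature marking the truly causal SNPs earns positive weight
    hits <- 0
    for (seed in 1:10) {
        set.seed(seed + 400)
        n <- 60; J <- 12
        X <- scale(matrix(rnorm(n * J), n, J))
        colnames(X) <- paste0("x", 1:J)
        B0 <- matrix(0, J, 3)
        B0[1:2, ] <- 1
        Y <- scale(X %*% B0 + matrix(rnorm(n * 3), n, 3))
        feat <- cbind(causal = c(1, 1, rep(0, J - 2)))
        rownames(feat) <- colnames(X)
        fit <- fitAMTL(X, Y, feat, 3, 1, standardize = FALSE, tol = 1e-8)
        if (fit@extras$theta["causal"] > 0) hits <- hits + 1
    }
    expect_gte(hits, 9)
})

test_that("MPGL selects SNPs with opposite-sign effects across populations", {
    wins <- 0
    for (seed in 1:10) {
        set.seed(seed + 500)
        n <- 200; J <- 10
        pops <- rep(1:2, each = n / 2)
        X <- matrix(rnorm(n * J), n, J)
        colnames(X) <- paste0("x", 1:J)
        ## opposite-sign effects cancel in the pooled analysis
        y <- ifelse(pops == 1, 1, -1) * X[, 1] * 0.8 + rnorm(n)
        fm <- fitMPGL(X, y, pops, lambda = 25)
        Bm <- as.matrix(coef(fm))
        fl <- fitLasso(X, matrix(y, dimnames = list(NULL, "y")), 25,
                       standardize = TRUE)
        sel_m <- any(Bm[1, ] != 0)
        sel_l <- as.matrix(coef(fl))[1, 1] != 0
        if (sel_m && !sel_l) wins <- wins + 1
    }
    expect_gte(wins, 7)
})

test_that("cross-validation: degenerate grid, determinism, and null behaviour", {
    d <- rand_xy(30, 5, 2, seed = 41)
    fitter <- function(x, y, l, g) fitLasso(x, y, l, standardize = FALSE,
                                            tol = 1e-6)
    cv1 <- crossValidate(fitter, d$X, d$Y, lambdaGrid = 2, folds = 5, seed = 9)
    expect_equal(bestHyperparams(cv1)$lambda, 2)
    ## folds partition the samples and the same seed reproduces them
    cv2 <- crossValidate(fitter, d$X, d$Y, c(1, 2, 4), folds = 5, seed = 9)
    expect_equal(sort(unique(cv2@folds)), 1:5)
    expect_equal(length(cv2@folds), 30)
    cv3 <- crossValidate(fitter, d$X, d$Y, c(1, 2, 4), folds = 5, seed = 9)
    expect_identical(cvGrid(cv2), cvGrid(cv3))
    expect_identical(cv2@folds, cv3@folds)
    ## pure-noise responses prefer the largest lambda (null model)
    hits <- 0
    for (seed in 1:10) {
        dn <- rand_xy(40, 6, 2, seed = seed + 600)
        lmax <- max(abs(crossprod(dn$X, dn$Y)))
        cv <- crossValidate(fitter, dn$X, dn$Y, lmax * c(0.05, 0.2, 0.5, 1),
                            folds = 5, seed = seed)
        if (bestHyperparams(cv)$lambda == lmax) hits <- hits + 1
    }
    expect_gte(hits, 9)
})
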