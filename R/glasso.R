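## Graphical lasso: block coordinate descent on the covariance estimate
## (Friedman-style), with each column subproblem solved as a lasso by the
## package's own coordinate-descent core. Maximizes
##   log det(Theta) - tr(S Theta) - rho * ||Theta||_1(off-diagonal)
## Stationarity: W = S + rho * Gamma with Gamma_ij in the subdifferential of
## |Theta_ij| (off-diagonal) and W_ii = S_ii (+ rho on the diagonal under the
## penalize-diagonal=FALSE convention used here: W_ii = S_ii).

.graphical_lasso <- function(S, rho, tol = 1e-8, maxit = 200) {
    K <- ncol(S)
    W <- S
    Bmat <- matrix(0, K - 1, K)   # lasso coefficients per column, warm starts
    off <- mean(abs(S[upper.tri(S)]))
    thr <- tol * max(off, 1e-12)
    for (it in seq_len(maxit)) {
        W_old <- W
        for (j in seq_len(K)) {
            idx <- setdiff(seq_len(K), j)
            W11 <- W[idx, idx, drop = FALSE]
            s12 <- S[idx, j, drop = FALSE]
            fit <- cpp_cd_l1l2(W11, s12, 0,
                               rep(rho, K - 1), rep(0, K - 1), list(),
                               Bmat[, j, drop = FALSE], 1e-12, 10000L)
            beta <- fit$B
            Bmat[, j] <- beta
            W[idx, j] <- W[j, idx] <- as.numeric(W11 %*% beta)
        }
        if (mean(abs(W - W_old)) < thr) break
    }
    ## recover Theta from W and the regression coefficients
    Theta <- matrix(0, K, K, dimnames = dimnames(S))
    for (j in seq_len(K)) {
        idx <- setdiff(seq_len(K), j)
        beta <- Bmat[, j]
        t22 <- 1 / (W[j, j] - sum(W[idx, j] * beta))
        Theta[j, j] <- t22
        Theta[idx, j] <- -beta * t22
    }
    Theta <- (Theta + t(Theta)) / 2
    ## enforce exact symmetric zeros from the soft-threshold steps
    Theta[abs(Theta) < 1e-12] <- 0
    list(Theta = Theta, W = W, niter = it)
}
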