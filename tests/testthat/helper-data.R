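## Shared fixture builders: small random matrices with ids, standardized
## design/response pairs, and simple networks.

rand_xy <- function(n, J, K, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * J), n, J)
    Y <- matrix(rnorm(n * K), n, K)
    X <- scale(X); Y <- scale(Y)
    attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
    attributes(Y)[c("scaled:center", "scaled:scale")] <- NULL
    colnames(X) <- paste0("x", seq_len(J))
    colnames(Y) <- paste0("y", seq_len(K))
    rownames(X) <- rownames(Y) <- paste0("s", seq_len(n))
    list(X = X, Y = Y)
}

chain_net <- function(ids, w = 0.8) {
    K <- length(ids)
    traitNetwork(ids, data.frame(a = ids[-K], b = ids[-1],
                                 w = rep(w, K - 1), r = rep(w, K - 1)))
}

## reference objective for the plain lasso (used in KKT checks)
lasso_objective <- function(X, Y, B, lambda) {
    0.5 * sum((Y - X %*% B)^2) + lambda * sum(abs(B))
}

## wrap a dense matrix as a CoefficientMatrix (for post-processing tests)
.cm <- function(M, rn, cn) {
    dimnames(M) <- list(rn, cn)
    new("CoefficientMatrix",
        B = methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix"),
        provenance = list(algorithm = "test"))
}

expect_monotone_trace <- function(fit, slack = 1e-9) {
    tr <- objectiveTrace(fit)
    expect_true(all(diff(tr) <= slack * pmax(abs(tr[-length(tr)]), 1)))
}
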