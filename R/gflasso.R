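## Graph-guided fused lasso (network over the responses) and its two-graph
## extension (networks over both the design columns and the responses of
## the gene-to-trait stage).

## edge arrays for the C++ core: 0-based endpoint indices into `ids`,
## fusion weight gamma * f(r) with f(r) = |r|, and the fusion sign
## (sign(r) in signed mode, +1 otherwise)
.fusion_edges <- function(net, ids, gamma, signed) {
    e <- edges(net)
    if (!all(nodes(net) %in% ids))
        stop("network nodes do not match the data columns")
    if (nrow(e) == 0)
        return(list(a = integer(0), b = integer(0),
                    w = numeric(0), s = numeric(0)))
    a <- match(e$a, ids); b <- match(e$b, ids)
    s <- if (signed) ifelse(e$r < 0, -1, 1) else rep(1, nrow(e))
    list(a = as.integer(a - 1L), b = as.integer(b - 1L),
         w = gamma * e$w, s = as.numeric(s))
}

#' Graph-guided fused lasso (GFlasso)
#'
#' Minimizes
#' 0.5*||Y - XB||_F^2 + lambda*||B||_1 +
#'   gamma * sum_{(m,l) in E} |r_ml| * sum_j |B_jm - s_ml * B_jl|
#' where E are the edges of the trait relevance network, r_ml the edge
#' values and s_ml = sign(r_ml) in signed mode (+1 otherwise). The total
#' variation fusion drives coefficients of network-linked traits to similar
#' magnitude, so they are selected jointly. Solved by the variational
#' reformulation of the fusion terms followed by coordinate descent on the
#' resulting quadratic (exact soft-threshold zeros for the L1 part); an
#' independent smoothing proximal-gradient engine is available as
#' \code{engine = "spg"} for cross-checking.
#'
#' @inheritParams fitLasso
#' @param net a \linkS4class{TraitNetwork} over the columns of Y.
#' @param gamma fusion weight >= 0; gamma = 0 reduces exactly to the lasso.
#' @param signed use sign(r) fusion (negatively correlated traits fused to
#'   opposite-sign coefficients); default FALSE (unsigned).
#' @param engine "cd" (variational coordinate descent, default) or "spg".
#' @param eps target smoothing of the fusion terms (the variational solver
#'   minimizes the fusion penalty smoothed as sqrt(x^2 + eps^2), driven down
#'   to this value by continuation; the objective gap is at most
#'   eps * sum of fusion weights).
#' @return a \linkS4class{FitResult}
#' @export
fitGFLasso <- function(X, Y, net, lambda, gamma, signed = FALSE,
                       engine = c("cd", "spg"), standardize = TRUE,
                       tol = 1e-8, maxit = 10000, eps = 1e-6) {
    engine <- match.arg(engine)
    stopifnot(lambda >= 0, gamma >= 0)
    d <- .prep_xy(X, Y, standardize)
    J <- ncol(d$X); K <- ncol(d$Y)
    hyper <- list(lambda = lambda, gamma = gamma, signed = signed,
                  engine = engine, standardize = standardize)
    ce <- .fusion_edges(net, d$trait_ids, gamma, signed)
    if (gamma > 0 && length(ce$a) == 0)
        warning("gamma > 0 with an empty edge set; fitting a plain lasso")
    if (gamma == 0 || length(ce$a) == 0) {
        fit <- cpp_cd_l1l2(d$XtX, d$XtY, d$yty, rep(lambda, J), rep(0, J),
                           list(), matrix(0, J, K), tol, as.integer(maxit))
        return(.fit_result(fit, d$snp_ids, d$trait_ids, "gflasso", hyper))
    }
    if (engine == "cd") {
        emptyE <- list(a = integer(0), b = integer(0),
                       w = numeric(0), s = numeric(0))
        fit <- .cd_gflasso_continuation(d, lambda, ce, emptyE, eps, tol, maxit)
        .fit_result(fit, d$snp_ids, d$trait_ids, "gflasso",
                    c(hyper, list(eps = eps)))
    } else {
        fit <- .spg_fusion(d, lambda, colE = ce, rowE = NULL,
                           tol = tol, maxit = maxit)
        .fit_result(fit, d$snp_ids, d$trait_ids, "gflasso", hyper,
                    threshold = 1e-8)
    }
}

## continuation on the fusion smoothing: solve with eps = 0.1 down to the
## target, warm-starting each stage; the concatenated smoothed-objective
## trace is non-increasing because the smoothed objective decreases in eps
.cd_gflasso_continuation <- function(d, lambda, colE, rowE, eps, tol, maxit) {
    J <- nrow(d$XtY); K <- ncol(d$XtY)
    B <- matrix(0, J, K)
    epsSeq <- 10^seq(-1, log10(eps), by = -1)
    if (epsSeq[length(epsSeq)] > eps) epsSeq <- c(epsSeq, eps)
    trace <- numeric(0)
    niter <- 0L
    for (i in seq_along(epsSeq)) {
        last <- i == length(epsSeq)
        fit <- cpp_cd_gflasso(d$XtX, d$XtY, d$yty, lambda,
                              colE$a, colE$b, colE$w, colE$s,
                              rowE$a, rowE$b, rowE$w, rowE$s,
                              B, if (last) tol else max(tol, 1e-7),
                              as.integer(maxit), epsSeq[i])
        B <- fit$B
        trace <- c(trace, fit$objective)
        niter <- niter + fit$niter
    }
    list(B = B, objective = trace, converged = fit$converged, niter = niter)
}

#' Graph-graph-guided fused lasso (gGFlasso): gene-to-trait stage
#'
#' Regresses clinical traits Z on gene expressions Y with fusion penalties
#' along both the gene network (rows of the coefficient matrix A) and the
#' trait network (columns of A):
#' 0.5*||Z - YA||_F^2 + lambda*||A||_1
#'   + gammaTrait * sum_{(s,t) in E_Z} |r_st| sum_m |A_ms - s * A_mt|
#'   + gammaGene  * sum_{(m,l) in E_Y} |r_ml| sum_t |A_mt - s * A_lt|
#' so related genes are encouraged to influence related traits. Same
#' variational coordinate-descent machinery as \code{\link{fitGFLasso}}.
#'
#' @param Y gene expression matrix (design of this stage).
#' @param Z clinical trait matrix (response).
#' @param geneNet \linkS4class{TraitNetwork} over the columns of Y.
#' @param traitNet \linkS4class{TraitNetwork} over the columns of Z.
#' @param lambda L1 weight.
#' @param gammaGene,gammaTrait fusion weights for the two networks.
#' @inheritParams fitGFLasso
#' @return a \linkS4class{FitResult} (rows = genes, columns = traits)
#' @export
fitGGFLasso <- function(Y, Z, geneNet, traitNet, lambda, gammaGene,
                        gammaTrait, signed = FALSE, standardize = TRUE,
                        tol = 1e-8, maxit = 10000, eps = 1e-6) {
    stopifnot(lambda >= 0, gammaGene >= 0, gammaTrait >= 0)
    d <- .prep_xy(Y, Z, standardize)
    K <- ncol(d$X); q <- ncol(d$Y)
    hyper <- list(lambda = lambda, gammaGene = gammaGene,
                  gammaTrait = gammaTrait, signed = signed,
                  standardize = standardize)
    re <- if (is.null(geneNet)) list(a = integer(0), b = integer(0), w = numeric(0), s = numeric(0))
          else .fusion_edges(geneNet, d$snp_ids, gammaGene, signed)
    ce <- if (is.null(traitNet)) list(a = integer(0), b = integer(0), w = numeric(0), s = numeric(0))
          else .fusion_edges(traitNet, d$trait_ids, gammaTrait, signed)
    if (gammaGene == 0) re <- list(a = integer(0), b = integer(0), w = numeric(0), s = numeric(0))
    if (gammaTrait == 0) ce <- list(a = integer(0), b = integer(0), w = numeric(0), s = numeric(0))
    if (length(re$a) == 0 && length(ce$a) == 0) {
        if (gammaGene > 0 || gammaTrait > 0)
            warning("fusion weights > 0 with empty edge sets; fitting a plain lasso")
        fit <- cpp_cd_l1l2(d$XtX, d$XtY, d$yty, rep(lambda, K), rep(0, K),
                           list(), matrix(0, K, q), tol, as.integer(maxit))
        return(.fit_result(fit, d$snp_ids, d$trait_ids, "ggflasso", hyper))
    }
    fit <- .cd_gflasso_continuation(d, lambda, ce, re, eps, tol, maxit)
    .fit_result(fit, d$snp_ids, d$trait_ids, "ggflasso",
                c(hyper, list(eps = eps)))
}
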