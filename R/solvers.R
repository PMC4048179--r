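## Penalized multi-task regression solvers. All models minimize
##   0.5 * ||Y - X B||_F^2 + penalty(B)
## (Frobenius loss without a 1/n factor; lambda grids are quoted on this
## scale). Inputs are column-standardized (z-score) by default so penalties
## are comparable across SNPs and traits and the intercept is handled by
## centering.

.prep_xy <- function(X, Y, standardize = TRUE) {
    Xm <- .as_matrix_input(X)
    Ym <- .as_matrix_input(Y)
    .assert_no_na(Xm, "X")
    .assert_no_na(Ym, "Y")
    if (nrow(Xm) != nrow(Ym)) stop("X and Y must have the same samples")
    if (standardize) {
        Xm <- .standardize_cols(Xm)
        Ym <- .standardize_cols(Ym)
    }
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
    if (is.null(colnames(Ym))) colnames(Ym) <- paste0("y", seq_len(ncol(Ym)))
    list(X = Xm, Y = Ym,
         XtX = crossprod(Xm), XtY = crossprod(Xm, Ym), yty = sum(Ym^2),
         snp_ids = colnames(Xm), trait_ids = colnames(Ym))
}

## groups: factor/integer vector over columns of X, or list of index
## vectors; must partition 1..J (overlap is an error)
.normalize_groups <- function(groups, J, what = "SNP") {
    if (is.list(groups)) idx <- lapply(groups, as.integer)
    else idx <- unname(split(seq_len(J), groups))
    all_ix <- unlist(idx)
    if (anyDuplicated(all_ix))
        stop("overlapping ", what, " groups are not supported")
    if (!setequal(all_ix, seq_len(J)))
        stop(what, " groups must partition the predictor set")
    idx
}

#' Multi-task lasso by cyclic coordinate descent
#'
#' Minimizes 0.5*||Y - XB||_F^2 + lambda*||B||_1 with covariance
#' (Gram-based) updates; zeros are exact soft-threshold zeros. Each response
#' column is an independent lasso, solved jointly.
#'
#' @param X genotypes: \linkS4class{GenotypeMatrix} or matrix (n x J).
#' @param Y traits: \linkS4class{TraitMatrix} or matrix (n x K).
#' @param lambda L1 weight >= 0.
#' @param standardize z-score columns of X and Y first (default TRUE).
#' @param tol relative objective-change convergence tolerance.
#' @param maxit maximum coordinate sweeps.
#' @param penaltyWeights optional per-SNP multipliers of lambda.
#' @return a \linkS4class{FitResult}
#' @export
fitLasso <- function(X, Y, lambda, standardize = TRUE, tol = 1e-6,
                     maxit = 10000, penaltyWeights = NULL) {
    stopifnot(lambda >= 0)
    d <- .prep_xy(X, Y, standardize)
    J <- ncol(d$X)
    w <- penaltyWeights %||% rep(1, J)
    fit <- cpp_cd_l1l2(d$XtX, d$XtY, d$yty, lambda * w, rep(0, J), list(),
                       matrix(0, J, ncol(d$Y)), tol, as.integer(maxit))
    .fit_result(fit, d$snp_ids, d$trait_ids, "lasso",
                list(lambda = lambda, standardize = standardize, tol = tol))
}

#' Group lasso over SNP groups
#'
#' Minimizes 0.5*||Y - XB||_F^2 + lambda * sum_k sum_g w_g ||B[G_g, k]||_2
#' by block coordinate descent with exact group updates (eigendecomposition
#' plus the secular equation); a group is exactly zero for a trait whenever
#' the norm of its residual correlation is at most lambda*w_g. Singleton
#' groups with unit weights reduce to the lasso.
#'
#' @inheritParams fitLasso
#' @param groups list of SNP index vectors, or a factor/integer vector of
#'   length J; must partition the SNPs (overlap is an error).
#' @param groupWeights per-group weights w_g (default 1).
#' @return a \linkS4class{FitResult}
#' @export
fitGroupLasso <- function(X, Y, groups, lambda, groupWeights = NULL,
                          standardize = TRUE, tol = 1e-8, maxit = 10000) {
    stopifnot(lambda >= 0)
    d <- .prep_xy(X, Y, standardize)
    J <- ncol(d$X)
    idx <- .normalize_groups(groups, J)
    gw <- groupWeights %||% rep(1, length(idx))
    stopifnot(length(gw) == length(idx))
    fit <- cpp_bcd_grouplasso(d$XtX, d$XtY, d$yty,
                              lapply(idx, function(i) i - 1L),
                              lambda * gw, matrix(0, J, ncol(d$Y)),
                              tol, as.integer(maxit))
    .fit_result(fit, d$snp_ids, d$trait_ids, "group_lasso",
                list(lambda = lambda, nGroups = length(idx),
                     groupWeights = gw, standardize = standardize))
}

#' Multi-population group lasso
#'
#' Fits one coefficient vector per population for a single trait, with the
#' L1/L2 penalty lambda * sum_j ||(beta_j^(1), ..., beta_j^(C))||_2 coupling
#' each SNP across populations: a SNP is selected jointly in all populations
#' or in none, while its per-population effects remain free (including
#' opposite signs). Solved as a group lasso on the population-block-diagonal
#' design; with a single population it reduces to the lasso.
#'
#' @param X genotypes (n x J).
#' @param y single trait: numeric vector or one-column matrix.
#' @param pops a \linkS4class{PopulationAssignment} or integer/factor vector
#'   of population labels.
#' @param lambda penalty weight.
#' @param standardize standardize X and center/scale y within each
#'   population block (default TRUE).
#' @param tol,maxit convergence controls.
#' @return a \linkS4class{FitResult}; \code{coef()} is J x C (one column per
#'   population)
#' @export
fitMPGL <- function(X, y, pops, lambda, standardize = TRUE,
                    tol = 1e-8, maxit = 10000) {
    Xm <- .as_matrix_input(X)
    yv <- if (is.matrix(y) || methods::is(y, "TraitMatrix")) .as_matrix_input(y)[, 1] else as.numeric(y)
    lab <- if (methods::is(pops, "PopulationAssignment")) populationLabels(pops) else pops
    lab <- as.integer(as.factor(lab))
    stopifnot(length(lab) == nrow(Xm), length(yv) == nrow(Xm))
    C <- max(lab)
    keep <- seq_len(C)
    for (c in seq_len(C)) {
        idx <- which(lab == c)
        if (length(idx) < 2 || stats::sd(yv[idx]) == 0) {
            warning("population ", c, " has <2 samples or zero trait variance; excluded")
            keep <- setdiff(keep, c)
        }
    }
    if (!length(keep)) stop("no usable population")
    J <- ncol(Xm)
    snp_ids <- colnames(Xm) %||% paste0("snp", seq_len(J))
    C2 <- length(keep)
    blocks <- lapply(keep, function(c) {
        idx <- which(lab == c)
        Xc <- Xm[idx, , drop = FALSE]
        yc <- yv[idx]
        if (standardize) {
            Xc <- .standardize_cols(Xc)
            yc <- as.numeric(.standardize_cols(matrix(yc)))
        }
        list(XtX = crossprod(Xc), Xty = crossprod(Xc, yc), yty = sum(yc^2))
    })
    if (C2 == 1L) {
        fit <- cpp_cd_l1l2(blocks[[1]]$XtX, blocks[[1]]$Xty, blocks[[1]]$yty,
                           rep(lambda, J), rep(0, J), list(),
                           matrix(0, J, 1), tol, as.integer(maxit))
        B <- fit$B
    } else {
        ## population-block-diagonal design; SNP j couples across blocks
        big <- matrix(0, J * C2, J * C2)
        XtY <- matrix(0, J * C2, 1)
        yty <- 0
        for (c in seq_len(C2)) {
            ix <- (c - 1) * J + seq_len(J)
            big[ix, ix] <- blocks[[c]]$XtX
            XtY[ix, 1] <- blocks[[c]]$Xty
            yty <- yty + blocks[[c]]$yty
        }
        grp <- lapply(seq_len(J), function(j) as.integer(j - 1 + (seq_len(C2) - 1) * J))
        fit <- cpp_bcd_grouplasso(big, XtY, yty, grp, rep(lambda, J),
                                  matrix(0, J * C2, 1), tol, as.integer(maxit))
        B <- matrix(fit$B, nrow = J, ncol = C2)
    }
    fit$B <- matrix(B, nrow = J, ncol = C2)
    .fit_result(fit, snp_ids, paste0("pop", keep), "mpgl",
                list(lambda = lambda, populations = keep,
                     standardize = standardize),
                extras = list(populations = keep))
}

## ---------------------------------------------------------------------------
## Proximal-gradient engine (monotone FISTA) for separable composite
## penalties; used by the structured input-output model and as the smoothing
## proximal-gradient backbone (treelasso.R supplies the smoothed part).
## ---------------------------------------------------------------------------

## prox: function(B, step) -> B; smooth: list(value=f(B), grad=f(B)) for an
## extra smooth penalty term (or NULL); penalty: exact nonsmooth penalty
## value for the objective trace.
.fista <- function(XtX, XtY, yty, L, prox, penalty, smooth = NULL,
                   B0, tol = 1e-7, maxit = 5000) {
    B <- B0
    Z <- B0
    tk <- 1
    objective <- function(M) .quad_loss(XtX, XtY, yty, M) + penalty(M)
    trace <- objective(B)
    best <- B
    for (it in seq_len(maxit)) {
        G <- XtX %*% Z - XtY
        if (!is.null(smooth)) G <- G + smooth$grad(Z)
        Bc <- prox(Z - G / L, 1 / L)
        ## monotone variant: keep the best iterate, restart momentum on it
        ob <- objective(Bc)
        if (ob <= trace[length(trace)] + 1e-14) {
            Bnew <- Bc
        } else {
            Bnew <- best
            ob <- trace[length(trace)]
        }
        tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
        Z <- Bc + ((tk - 1) / tk1) * (Bc - B)
        B <- Bc
        best <- Bnew
        denom <- max(abs(trace[length(trace)]), 1e-12)
        conv <- abs(trace[length(trace)] - ob) / denom < tol && it > 5
        trace <- c(trace, ob)
        if (conv) {
            return(list(B = best, objective = trace, converged = TRUE, niter = it))
        }
    }
    list(B = best, objective = trace, converged = FALSE, niter = maxit)
}

#' Structured input-output regression
#'
#' Minimizes
#' 0.5*||Y - XB||_F^2 + lambda1*||B||_1 +
#'   lambda2 * sum_g sum_h w_gh ||B[G_g, H_h]||_2
#' with SNP groups G_g (rows) and trait groups H_h (columns): whole
#' SNP-group x trait-group blocks are selected or zeroed together, on top of
#' elementwise sparsity. Solved by monotone accelerated proximal gradient;
#' the prox of the composite penalty is exact (soft-threshold, then
#' blockwise group shrinkage over the disjoint blocks). With all groups
#' singletons (unit weights) the fit equals a lasso at lambda1 + lambda2.
#'
#' @inheritParams fitLasso
#' @param snpGroups,traitGroups partitions of SNPs / traits (list of index
#'   vectors or factor).
#' @param lambda1 elementwise L1 weight.
#' @param lambda2 block L1/L2 weight.
#' @param blockWeights optional matrix of w_gh (default 1).
#' @return a \linkS4class{FitResult}
#' @export
fitStructIO <- function(X, Y, snpGroups, traitGroups, lambda1, lambda2,
                        blockWeights = NULL, standardize = TRUE,
                        tol = 1e-9, maxit = 20000) {
    stopifnot(lambda1 >= 0, lambda2 >= 0)
    d <- .prep_xy(X, Y, standardize)
    J <- ncol(d$X); K <- ncol(d$Y)
    gs <- .normalize_groups(snpGroups, J, "SNP")
    hs <- .normalize_groups(traitGroups, K, "trait")
    W <- blockWeights %||% matrix(1, length(gs), length(hs))
    stopifnot(nrow(W) == length(gs), ncol(W) == length(hs))
    penalty <- function(B) {
        p <- lambda1 * sum(abs(B))
        for (g in seq_along(gs)) for (h in seq_along(hs))
            p <- p + lambda2 * W[g, h] * sqrt(sum(B[gs[[g]], hs[[h]]]^2))
        p
    }
    prox <- function(B, step) {
        B <- sign(B) * pmax(abs(B) - step * lambda1, 0)
        for (g in seq_along(gs)) for (h in seq_along(hs)) {
            blk <- B[gs[[g]], hs[[h]], drop = FALSE]
            nrm <- sqrt(sum(blk^2))
            thr <- step * lambda2 * W[g, h]
            B[gs[[g]], hs[[h]]] <- if (nrm <= thr) 0 else blk * (1 - thr / nrm)
        }
        B
    }
    L <- max(eigen(d$XtX, symmetric = TRUE, only.values = TRUE)$values)
    fit <- .fista(d$XtX, d$XtY, d$yty, L, prox, penalty,
                  B0 = matrix(0, J, K), tol = tol, maxit = maxit)
    .fit_result(fit, d$snp_ids, d$trait_ids, "struct_io",
                list(lambda1 = lambda1, lambda2 = lambda2,
                     standardize = standardize))
}
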