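## Adaptive multi-task lasso: genome-annotation-driven penalty weights.
##
## Per-SNP penalty scales are log-linear in the SNP features and normalized
## to mean 1 across SNPs (a softmax),
##   rho_j  = J exp(-theta' f_j) / sum_i exp(-theta' f_i)   (L1 term)
##   rho'_j = J exp(-eta'   f_j) / sum_i exp(-eta'   f_i)   (L1/L2 term)
## The normalization acts as the regularizer that keeps the weight
## estimation well posed: without it the scale of the penalties is
## unidentified and the weights of SNPs with zero coefficients diverge. A
## small ridge on (theta, eta) adds numerical stability. B and (theta, eta)
## are estimated alternately: coordinate descent with SNP-specific
## penalties for B, backtracking gradient descent for the feature weights;
## each step decreases the joint objective.

.amtl_rho <- function(f, w) {
    ## softmax-normalized penalty scales: mean(rho) = 1 for every w, so the
    ## weights shift penalty between SNPs without changing the overall scale
    u <- exp(-as.numeric(f %*% w) - max(-as.numeric(f %*% w)))
    nrow(f) * u / sum(u)
}

.amtl_weight_step <- function(w, f, load, scale0, tau,
                              steps = 50, tol = 1e-10) {
    ## minimize  scale0 * sum_j rho_j(w) * load_j + tau/2 ||w||^2
    ## with rho the softmax-normalized scales above (the normalization is
    ## what keeps the problem bounded; see the methods vignette)
    obj <- function(w) scale0 * sum(.amtl_rho(f, w) * load) + tau / 2 * sum(w^2)
    gr <- function(w) {
        rho <- .amtl_rho(f, w)
        fbar <- colSums(rho / nrow(f) * f)   # softmax-weighted feature mean
        g <- numeric(ncol(f))
        for (m in seq_len(ncol(f)))
            g[m] <- scale0 * sum(load * rho * (fbar[m] - f[, m]))
        g + tau * w
    }
    o <- obj(w)
    for (i in seq_len(steps)) {
        g <- gr(w)
        step <- 1
        repeat {
            w2 <- w - step * g
            o2 <- obj(w2)
            if (o2 <= o - 0.5 * step * sum(g^2) || step < 1e-12) break
            step <- step / 2
        }
        if (abs(o - o2) / max(abs(o), 1e-12) < tol) { w <- w2; o <- o2; break }
        w <- w2
        o <- o2
    }
    w
}

#' Adaptive multi-task lasso (AMTL)
#'
#' Minimizes, over B and the feature weights (theta, eta),
#' 0.5*||Y - XB||_F^2
#'   + lambda * sum_j rho_j(theta) ||b_j||_1
#'   + gamma  * sum_j rho'_j(eta)  sum_g ||b_j[H_g]||_2
#'   + tau/2 * (||theta||^2 + ||eta||^2)
#' where f_j are annotation features of SNP j, H_g are trait groups
#' (default: all traits as one group), and the per-SNP penalty scales are
#' log-linear in the features and normalized to mean one,
#' rho_j = J exp(-theta'f_j) / sum_i exp(-theta'f_i). SNPs whose features
#' earn a large theta'f_j receive a small penalty and are more likely to be
#' selected; the normalization regularizes the weight estimation (it fixes
#' the overall penalty scale, which is otherwise unidentified). Fixing
#' theta = eta = 0 (\code{updateWeights = FALSE}) gives the uniform-penalty
#' composite lasso / multi-task fit.
#'
#' @inheritParams fitLasso
#' @param features \linkS4class{SNPFeatureTable} (or J x F matrix) aligned
#'   to the SNPs; all-zero (constant) feature columns are dropped with a
#'   warning.
#' @param gamma weight of the multi-task L1/L2 row term (default = lambda).
#' @param traitGroups optional partition of the traits for the L1/L2 term.
#' @param tau ridge on the feature weights (default 0.1).
#' @param updateWeights estimate (theta, eta)? With FALSE the weights stay
#'   frozen at their starting values (the inner B-step alone).
#' @param theta0,eta0 starting feature weights (default 0, i.e. uniform
#'   penalties).
#' @param outerMax maximum alternating cycles.
#' @return a \linkS4class{FitResult} with \code{extras$theta},
#'   \code{extras$eta}
#' @export
fitAMTL <- function(X, Y, features, lambda, gamma = lambda,
                    traitGroups = NULL, tau = 0.1, updateWeights = TRUE,
                    theta0 = NULL, eta0 = NULL,
                    standardize = TRUE, tol = 1e-6, maxit = 10000,
                    outerMax = 50) {
    stopifnot(lambda >= 0, gamma >= 0)
    d <- .prep_xy(X, Y, standardize)
    J <- ncol(d$X); K <- ncol(d$Y)
    f <- if (methods::is(features, "SNPFeatureTable")) values(features) else as.matrix(features)
    stopifnot(nrow(f) == J)
    keepF <- apply(f, 2, function(v) stats::sd(v) > 0)
    if (!all(keepF)) {
        warning("dropping constant feature column(s): ",
                paste(colnames(f)[!keepF], collapse = ", "))
        f <- f[, keepF, drop = FALSE]
    }
    nF <- ncol(f)
    hs <- if (is.null(traitGroups)) list(seq_len(K))
          else .normalize_groups(traitGroups, K, "trait")
    G <- length(hs)
    hs0 <- lapply(hs, function(i) as.integer(i - 1L))
    theta <- if (is.null(theta0)) numeric(nF) else rep(theta0, length.out = nF)
    eta <- if (is.null(eta0)) numeric(nF) else rep(eta0, length.out = nF)
    B <- matrix(0, J, K)
    objective <- function(B, theta, eta) {
        rho <- .amtl_rho(f, theta)
        rho2 <- .amtl_rho(f, eta)
        l1 <- rowSums(abs(B))
        l2 <- rowSums(vapply(hs, function(g)
            sqrt(rowSums(B[, g, drop = FALSE]^2)), numeric(J)))
        .quad_loss(d$XtX, d$XtY, d$yty, B) +
            lambda * sum(rho * l1) + gamma * sum(rho2 * l2) +
            tau / 2 * (sum(theta^2) + sum(eta^2))
    }
    trace <- objective(B, theta, eta)
    innerNiter <- 0L
    converged <- FALSE
    for (it in seq_len(outerMax)) {
        rho <- .amtl_rho(f, theta)
        rho2 <- .amtl_rho(f, eta)
        bfit <- cpp_cd_l1l2(d$XtX, d$XtY, d$yty, lambda * rho, gamma * rho2,
                            hs0, B, tol, as.integer(maxit))
        B <- bfit$B
        innerNiter <- innerNiter + bfit$niter
        if (updateWeights && nF > 0) {
            l1 <- rowSums(abs(B))
            theta <- .amtl_weight_step(theta, f, l1, lambda, tau)
            l2 <- rowSums(vapply(hs, function(g)
                sqrt(rowSums(B[, g, drop = FALSE]^2)), numeric(J)))
            eta <- .amtl_weight_step(eta, f, l2, gamma, tau)
        }
        onew <- objective(B, theta, eta)
        conv <- abs(trace[length(trace)] - onew) /
            max(abs(trace[length(trace)]), 1e-12) < tol
        trace <- c(trace, onew)
        if (conv || !updateWeights) { converged <- TRUE; break }
    }
    res <- list(B = B, objective = trace, converged = converged,
                niter = it)
    .fit_result(res, d$snp_ids, d$trait_ids, "amtl",
                list(lambda = lambda, gamma = gamma, tau = tau,
                     nTraitGroups = G, updateWeights = updateWeights,
                     standardize = standardize),
                extras = list(theta = stats::setNames(theta, colnames(f)),
                              eta = stats::setNames(eta, colnames(f))))
}
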