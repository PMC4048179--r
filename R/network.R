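## Trait relevance network builders: thresholded correlation, soft-power
## (scale-free) adjacency, and sparse inverse covariance (graphical lasso).

.drop_zero_variance <- function(Y) {
    s <- apply(Y, 2, stats::sd)
    zv <- s < .Machine$double.eps^0.5
    if (any(zv)) {
        warning("excluding zero-variance trait(s): ",
                paste(colnames(Y)[zv], collapse = ", "))
        Y <- Y[, !zv, drop = FALSE]
    }
    Y
}

.cor_edge_table <- function(R, weightFun = abs, threshold = 0) {
    ids <- colnames(R)
    idx <- which(upper.tri(R), arr.ind = TRUE)
    w <- weightFun(R[idx])
    keep <- w >= threshold & w > 0
    data.frame(a = ids[idx[keep, 1]], b = ids[idx[keep, 2]],
               w = pmin(w[keep], 1), r = R[idx][keep],
               stringsAsFactors = FALSE)
}

#' Thresholded correlation network
#'
#' Keeps an edge (i, j) with weight |pearson(y_i, y_j)| whenever the weight
#' is at least \code{threshold}. Zero-variance traits are excluded with a
#' warning.
#'
#' @param Y \linkS4class{TraitMatrix} or matrix (n >= 3 samples).
#' @param threshold minimum absolute correlation retained (default 0.5).
#' @return a \linkS4class{TraitNetwork}
#' @export
correlationNetwork <- function(Y, threshold = 0.5) {
    M <- .as_matrix_input(Y)
    .assert_no_na(M, "trait matrix")
    if (nrow(M) < 3) stop("need at least 3 samples")
    M <- .drop_zero_variance(M)
    R <- stats::cor(M)
    traitNetwork(colnames(M), .cor_edge_table(R, abs, threshold),
                 builder = "correlation", params = list(threshold = threshold))
}

## log-log scale-free fit: connectivity k_i binned into nbins log-spaced
## bins, least squares of log10(frequency) on log10(mean k)
.scale_free_r2 <- function(k, nbins = 10) {
    k <- k[k > 0]
    if (length(k) < 3 || diff(range(k)) < 1e-12) return(0)
    br <- exp(seq(log(min(k) * (1 - 1e-9)), log(max(k) * (1 + 1e-9)),
                  length.out = nbins + 1))
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3) return(0)
    fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
    summary(fit)$r.squared
}

#' Soft-thresholding (scale-free) network
#'
#' Weighted adjacency a_ij = |cor(y_i, y_j)|^beta, with beta chosen as the
#' smallest value on \code{betaGrid} whose connectivity distribution attains
#' a scale-free log-log fit R^2 of at least \code{r2Target}. If no beta
#' reaches the target, the beta with maximal R^2 is used with a warning.
#'
#' @param Y \linkS4class{TraitMatrix} or matrix.
#' @param betaGrid increasing positive integers (default 1:10).
#' @param r2Target target scale-free fit (default 0.8).
#' @param nbins number of log-spaced connectivity bins (default 10).
#' @return a \linkS4class{TraitNetwork}; the chosen beta and its R^2 are in
#'   \code{params}
#' @export
softPowerNetwork <- function(Y, betaGrid = 1:10, r2Target = 0.8, nbins = 10) {
    stopifnot(all(betaGrid > 0))
    M <- .as_matrix_input(Y)
    .assert_no_na(M, "trait matrix")
    M <- .drop_zero_variance(M)
    R <- abs(stats::cor(M))
    diag(R) <- 0
    r2 <- vapply(betaGrid, function(b) {
        A <- R^b
        .scale_free_r2(rowSums(A), nbins = nbins)
    }, numeric(1))
    hit <- which(r2 >= r2Target)
    if (length(hit)) {
        beta <- betaGrid[hit[1]]
    } else {
        beta <- betaGrid[which.max(r2)]
        warning(sprintf("no beta on the grid reaches R^2 >= %.2f; using beta=%d (R^2=%.3f)",
                        r2Target, beta, max(r2)))
    }
    Rsig <- stats::cor(M)
    A <- abs(Rsig)^beta
    et <- .cor_edge_table(A, identity, threshold = 0)
    ## carry the signed correlation for the signed fusion variant
    ids <- colnames(M)
    ia <- match(et$a, ids); ib <- match(et$b, ids)
    et$r <- sign(Rsig[cbind(ia, ib)]) * et$w
    traitNetwork(ids, et, builder = "softpower",
                 params = list(beta = beta, r2 = r2[match(beta, betaGrid)],
                               r2Grid = stats::setNames(r2, betaGrid),
                               r2Target = r2Target, nbins = nbins))
}

#' Markov network by the graphical lasso
#'
#' Estimates the L1-penalized Gaussian inverse covariance of the traits and
#' connects pairs with nonzero precision entries; edge weight is the
#' absolute partial correlation.
#'
#' @param Y \linkS4class{TraitMatrix} or matrix, n > 3 samples.
#' @param rho L1 penalty on the precision matrix, > 0 (rho = 0 is rejected
#'   when K >= n).
#' @param tol,maxit convergence controls of the block coordinate descent.
#' @return a \linkS4class{TraitNetwork}; the precision matrix is in
#'   \code{params$theta}
#' @export
glassoNetwork <- function(Y, rho, tol = 1e-8, maxit = 200) {
    M <- .as_matrix_input(Y)
    .assert_no_na(M, "trait matrix")
    if (nrow(M) <= 3) stop("need more than 3 samples")
    M <- .drop_zero_variance(M)
    if (rho <= 0 && ncol(M) >= nrow(M))
        stop("rho = 0 is not admissible when K >= n")
    S <- stats::cov(M)
    gl <- .graphical_lasso(S, rho, tol = tol, maxit = maxit)
    Theta <- gl$Theta
    P <- -Theta / sqrt(diag(Theta) %o% diag(Theta))   # partial correlations
    diag(P) <- 0
    ids <- colnames(M)
    dimnames(P) <- list(ids, ids)
    idx <- which(upper.tri(P) & abs(Theta) > 1e-10, arr.ind = TRUE)
    et <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                     w = pmin(abs(P[idx]), 1), r = P[idx],
                     stringsAsFactors = FALSE)
    traitNetwork(ids, et, builder = "glasso",
                 params = list(rho = rho, theta = Theta, W = gl$W))
}

#' Node and edge overlap between two networks
#'
#' @param netA,netB TraitNetwork objects.
#' @return list with \code{pct_shared_nodes} and \code{pct_shared_edges}:
#'   the percentage of A's nodes (edges, as unordered id pairs) present in B
#' @export
networkOverlap <- function(netA, netB) {
    nA <- nodes(netA)
    pct_nodes <- if (length(nA)) 100 * mean(nA %in% nodes(netB)) else NA_real_
    key <- function(net) {
        e <- edges(net)
        paste(pmin(e$a, e$b), pmax(e$a, e$b), sep = "\r")
    }
    eA <- key(netA)
    pct_edges <- if (length(eA)) 100 * mean(eA %in% key(netB)) else NA_real_
    list(pct_shared_nodes = pct_nodes, pct_shared_edges = pct_edges)
}
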