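## Cross-validated hyperparameter selection with the linear (one-axis-at-a-
## time) search: lambda is tuned on its grid with gamma = 0, then gamma is
## tuned at the selected lambda.

.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

.cv_folds <- function(n, folds, seed, X, maxTries = 10) {
    for (tr in seq_len(maxTries)) {
        f <- .with_seed(seed + tr - 1L,
                        sample(rep(seq_len(folds), length.out = n)))
        ok <- all(vapply(seq_len(folds), function(k) {
            Xtr <- X[f != k, , drop = FALSE]
            nrow(Xtr) >= 2 && all(apply(Xtr, 2, stats::sd) > 0)
        }, logical(1)))
        if (ok) return(f)
        warning("fold split produced a zero-variance training column; re-splitting")
    }
    f
}

#' Cross-validated (lambda, gamma) selection by linear search
#'
#' Splits the samples into \code{folds} deterministic folds (given
#' \code{seed}), tunes lambda on \code{lambdaGrid} with gamma = 0, then
#' tunes gamma on \code{gammaGrid} at the selected lambda. The error is the
#' mean held-out squared prediction error per matrix cell (averaged over
#' traits); ties prefer the stronger regularization.
#'
#' \code{rule} follows the usual cross-validation conventions: \code{"min"}
#' picks the error-minimizing grid point; \code{"1se"} (default) picks the
#' strongest regularization whose error is within one standard error (over
#' folds) of the minimum -- the parsimony rule commonly used when the fit is
#' read for its support rather than for prediction.
#'
#' X and Y are standardized once up front (when \code{standardize}) and the
#' fitter is called on raw training blocks, so it should not re-standardize
#' (pass \code{standardize = FALSE} in the closure).
#'
#' @param fitter function(X, Y, lambda, gamma) returning a
#'   \linkS4class{FitResult}.
#' @param X,Y data matrices (or containers).
#' @param lambdaGrid numeric grid for the sparsity weight.
#' @param gammaGrid optional numeric grid for the fusion/second weight;
#'   NULL keeps gamma = 0.
#' @param folds number of folds (default 10).
#' @param seed integer controlling the fold split.
#' @param standardize z-score X and Y before splitting (default TRUE).
#' @param rule "1se" (default) or "min"; see Details.
#' @return a \linkS4class{CVResult}
#' @export
crossValidate <- function(fitter, X, Y, lambdaGrid, gammaGrid = NULL,
                          folds = 10, seed = 1, standardize = TRUE,
                          rule = c("1se", "min")) {
    rule <- match.arg(rule)
    Xm <- .as_matrix_input(X)
    Ym <- .as_matrix_input(Y)
    if (standardize) {
        Xm <- .standardize_cols(Xm)
        Ym <- .standardize_cols(Ym)
    }
    n <- nrow(Xm)
    stopifnot(folds >= 2, folds <= n, length(lambdaGrid) >= 1)
    f <- .cv_folds(n, folds, seed, Xm)
    cvErr <- function(lambda, gamma) {
        errs <- vapply(seq_len(folds), function(k) {
            tr <- f != k
            fit <- fitter(Xm[tr, , drop = FALSE], Ym[tr, , drop = FALSE],
                          lambda, gamma)
            Yhat <- Xm[!tr, , drop = FALSE] %*% coef(fit)
            mean((Ym[!tr, , drop = FALSE] - as.matrix(Yhat))^2)
        }, numeric(1))
        c(mean(errs), stats::sd(errs) / sqrt(folds))
    }
    ## grids sorted so "largest admissible value" = strongest regularization;
    ## exact ties always prefer the stronger one
    pick <- function(grid_vals, err, se) {
        i_min <- which.min(err)
        cut <- if (rule == "1se") err[i_min] + se[i_min] else err[i_min]
        grid_vals[max(which(err <= cut + 1e-15))]
    }
    lambdaGrid <- sort(lambdaGrid)
    e1 <- vapply(lambdaGrid, cvErr, numeric(2), gamma = 0)
    best_l <- pick(lambdaGrid, e1[1, ], e1[2, ])
    grid <- data.frame(lambda = lambdaGrid, gamma = 0,
                       cvError = e1[1, ], cvSE = e1[2, ])
    best_g <- 0
    if (!is.null(gammaGrid) && length(gammaGrid)) {
        gammaGrid <- sort(gammaGrid)
        e2 <- vapply(gammaGrid, function(g) cvErr(best_l, g), numeric(2))
        best_g <- pick(gammaGrid, e2[1, ], e2[2, ])
        grid <- rbind(grid, data.frame(lambda = best_l, gamma = gammaGrid,
                                       cvError = e2[1, ], cvSE = e2[2, ]))
    }
    new("CVResult", grid = grid,
        best = list(lambda = best_l, gamma = best_g),
        folds = as.integer(f), seed = as.integer(seed))
}
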