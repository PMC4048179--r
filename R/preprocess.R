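## Trait preprocessing: k-NN imputation, missingness filtering,
## standardization.

#' k-nearest-neighbour imputation of missing trait values
#'
#' Each missing cell is replaced by the mean of that trait over the k
#' nearest samples among those with the trait observed. Distance between two
#' samples is the Euclidean distance over their mutually observed traits,
#' scaled by the number of shared traits (root mean squared difference), so
#' samples sharing few traits are comparable to samples sharing many. Ties
#' in neighbour distance are broken by sample order.
#'
#' @param T a \linkS4class{TraitMatrix} (or plain matrix) possibly holding
#'   NAs.
#' @param k number of neighbours; capped at n - 1 (default 10).
#' @return object of the same type with no missing values
#' @export
imputeKNN <- function(T, k = 10) {
    M <- .as_matrix_input(T)
    n <- nrow(M)
    k <- min(as.integer(k), n - 1L)
    if (k < 1) stop("need at least 2 samples for imputation")
    if (!anyNA(M)) return(T)
    obs <- !is.na(M)
    if (any(rowSums(obs) == 0))
        stop("sample(s) with all traits missing: ",
             paste(rownames(M)[rowSums(obs) == 0], collapse = ", "))
    ## pairwise root-mean-square distance over mutually observed traits
    D <- matrix(Inf, n, n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            shared <- obs[i, ] & obs[j, ]
            ns <- sum(shared)
            if (ns == 0) next
            D[i, j] <- sqrt(sum((M[i, shared] - M[j, shared])^2) / ns)
        }
    }
    out <- M
    for (i in seq_len(n)) {
        miss <- which(!obs[i, ])
        if (!length(miss)) next
        ord <- order(D[i, ], seq_len(n))   # ties broken by sample order
        for (jt in miss) {
            donors <- ord[obs[ord, jt]]
            donors <- donors[is.finite(D[i, donors])]
            if (!length(donors))
                stop("no donor sample observed for trait ", colnames(M)[jt])
            use <- donors[seq_len(min(k, length(donors)))]
            out[i, jt] <- mean(M[use, jt])
        }
    }
    if (methods::is(T, "TraitMatrix")) {
        T@values <- out
        T
    } else out
}

#' Drop traits with too much missingness
#'
#' Removes traits whose missing fraction is strictly greater than
#' \code{maxMissingFrac}; the order of surviving traits is preserved.
#'
#' @param T a \linkS4class{TraitMatrix} or matrix.
#' @param maxMissingFrac threshold in [0, 1] (default 0.30, i.e. drop traits
#'   missing in more than 30\% of samples).
#' @return filtered object of the same type
#' @export
filterMissingTraits <- function(T, maxMissingFrac = 0.30) {
    stopifnot(maxMissingFrac >= 0, maxMissingFrac <= 1)
    M <- .as_matrix_input(T)
    frac <- colMeans(is.na(M))
    keep <- frac <= maxMissingFrac
    if (methods::is(T, "TraitMatrix")) {
        gm <- T@geneMap
        if (nrow(gm)) gm <- gm[gm$trait_id %in% colnames(M)[keep], , drop = FALSE]
        traitMatrix(M[, keep, drop = FALSE], kind = T@kind,
                    geneMap = if (nrow(gm)) gm else NULL)
    } else M[, keep, drop = FALSE]
}

#' Column standardization
#'
#' Centers each column to mean zero; with \code{mode = "zscore"} also scales
#' to unit variance. Constant columns are left centered (all zeros) and
#' flagged in the \code{"zeroVariance"} attribute of the result.
#'
#' @param M matrix, GenotypeMatrix or TraitMatrix (no missing values).
#' @param mode "zscore" (default) or "center".
#' @return standardized object of the same type (plain matrix input returns
#'   a matrix carrying the \code{"zeroVariance"} attribute)
#' @export
standardizeMatrix <- function(M, mode = c("zscore", "center")) {
    mode <- match.arg(mode)
    X <- .as_matrix_input(M)
    .assert_no_na(X, "matrix to standardize")
    if (mode == "zscore") {
        out <- .standardize_cols(X)
    } else {
        out <- sweep(X, 2, colMeans(X))
        attr(out, "zeroVariance") <-
            apply(out, 2, function(v) all(abs(v) < .Machine$double.eps^0.5))
    }
    if (methods::is(M, "TraitMatrix")) {
        res <- M
        res@values <- out
        res
    } else if (methods::is(M, "GenotypeMatrix")) {
        ## standardized dosages leave the coding set; return a plain matrix
        out
    } else out
}
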