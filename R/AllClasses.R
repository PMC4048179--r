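#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' GenotypeMatrix: samples x SNPs allele dosages with a genomic map
#'
#' Holds an n x J matrix of allele dosages together with a per-SNP map of
#' chromosome and 1-based position. Haploid-cross data are coded 0/1,
#' diploid data 0/1/2. Missing genotypes are rejected at construction;
#' only trait matrices may carry missingness (prior to imputation).
#'
#' @slot values numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @slot snpMap data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp), one row per SNP in column order.
#' @slot coding character, \code{"haploid"} (values in 0/1) or
#'   \code{"diploid"} (values in 0/1/2).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(values = "matrix",
                        snpMap = "data.frame",
                        coding = "character"))

setValidity("GenotypeMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(colnames(v))) msg <- c(msg, "values must have SNP ids as colnames")
    if (anyNA(v)) msg <- c(msg, "missing genotypes are not allowed")
    if (!object@coding %in% c("haploid", "diploid"))
        msg <- c(msg, "coding must be 'haploid' or 'diploid'")
    allowed <- if (identical(object@coding, "diploid")) c(0, 1, 2) else c(0, 1)
    if (!all(v %in% allowed))
        msg <- c(msg, sprintf("genotype values outside coding set {%s}",
                              paste(allowed, collapse = ",")))
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate SNP ids")
    m <- object@snpMap
    if (nrow(m) > 0) {
        if (!all(c("snp_id", "chrom", "pos") %in% names(m)))
            msg <- c(msg, "snpMap needs columns snp_id, chrom, pos")
        else {
            if (!identical(as.character(m$snp_id), colnames(v)))
                msg <- c(msg, "snpMap rows must match SNP column order")
            if (any(m$pos < 1)) msg <- c(msg, "positions must be >= 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' TraitMatrix: samples x traits (expression or clinical)
#'
#' @slot values numeric matrix, samples in rows, traits in columns
#'   (colnames = trait ids). May contain NA before imputation.
#' @slot kind character, \code{"expression"} or \code{"clinical"}.
#' @slot geneMap data.frame with columns \code{trait_id}, \code{chrom},
#'   \code{tx_start} for expression traits (transcription start, 1-based bp),
#'   or a zero-row data.frame when no map is attached.
#' @exportClass TraitMatrix
setClass("TraitMatrix",
         representation(values = "matrix",
                        kind = "character",
                        geneMap = "data.frame"))

setValidity("TraitMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(colnames(v))) msg <- c(msg, "values must have trait ids as colnames")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate trait ids")
    if (!object@kind %in% c("expression", "clinical"))
        msg <- c(msg, "kind must be 'expression' or 'clinical'")
    m <- object@geneMap
    if (nrow(m) > 0 && !all(c("trait_id", "chrom", "tx_start") %in% names(m)))
        msg <- c(msg, "geneMap needs columns trait_id, chrom, tx_start")
    if (length(msg)) msg else TRUE
})

#' SNPFeatureTable: per-SNP annotation features for the adaptive penalty
#'
#' Row order matches the paired \code{GenotypeMatrix}; discrete location
#' indicators are 0/1 columns and continuous features (e.g. a conservation
#' score) are standardized to zero mean and unit variance at construction.
#'
#' @slot values numeric J x F matrix (rownames = SNP ids,
#'   colnames = feature names).
#' @exportClass SNPFeatureTable
setClass("SNPFeatureTable", representation(values = "matrix"))

setValidity("SNPFeatureTable", function(object) {
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
        "values needs SNP ids as rownames and feature names as colnames"
    else TRUE
})

#' TraitNetwork: weighted relevance graph over traits
#'
#' Undirected, self-edge-free graph guiding the fusion penalty. Edge weight
#' \code{w} is the absolute correlation (or builder-specific weight) in
#' [0, 1]; \code{r} retains the signed correlation so the signed fusion
#' variant can flip coefficient signs across negatively correlated traits.
#'
#' @slot nodes character vector of trait ids.
#' @slot edges data.frame with columns \code{a}, \code{b} (trait ids,
#'   a < b lexicographically by node index), \code{w} (weight in [0,1]) and
#'   \code{r} (signed value, \code{abs(r) == w} for correlation builders).
#' @slot builder character, one of "correlation", "softpower", "glasso",
#'   "external".
#' @slot params list of builder parameters.
#' @exportClass TraitNetwork
setClass("TraitNetwork",
         representation(nodes = "character",
                        edges = "data.frame",
                        builder = "character",
                        params = "list"))

setValidity("TraitNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("a", "b", "w", "r") %in% names(e)))
        msg <- c(msg, "edges needs columns a, b, w, r")
    else if (nrow(e) > 0) {
        if (any(e$a == e$b)) msg <- c(msg, "self-edges are not allowed")
        if (!all(c(e$a, e$b) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
        if (any(e$w < 0 | e$w > 1 + 1e-12)) msg <- c(msg, "weights must lie in [0,1]")
        ii <- match(e$a, object@nodes); jj <- match(e$b, object@nodes)
        if (any(ii > jj)) msg <- c(msg, "edges must be stored with a before b in node order")
        if (anyDuplicated(paste(e$a, e$b))) msg <- c(msg, "duplicate edges")
    }
    if (length(msg)) msg else TRUE
})

#' TraitTree: rooted binary tree over traits for the tree-guided penalty
#'
#' Built by agglomerative clustering; stored in \code{hclust} merge format
#' plus per-node group weights. Internal node v contributes a weighted
#' L2 norm over its member traits (per SNP); leaves contribute L1 terms,
#' so the penalty induces hierarchical group sparsity.
#'
#' @slot labels character, trait ids (the leaves).
#' @slot merge integer matrix as in \code{\link[stats]{hclust}}.
#' @slot height numeric merge heights, normalized to max 1.
#' @slot nodeWeights numeric, one weight per internal node (rows of merge).
#' @slot leafWeights numeric, one weight per leaf.
#' @slot scheme character, name of the node-weighting scheme.
#' @exportClass TraitTree
setClass("TraitTree",
         representation(labels = "character",
                        merge = "matrix",
                        height = "numeric",
                        nodeWeights = "numeric",
                        leafWeights = "numeric",
                        scheme = "character"))

setValidity("TraitTree", function(object) {
    msg <- character()
    nL <- length(object@labels)
    if (nL >= 2) {
        if (nrow(object@merge) != nL - 1L)
            msg <- c(msg, "merge must have length(labels)-1 rows")
        if (length(object@nodeWeights) != nrow(object@merge))
            msg <- c(msg, "one nodeWeight per internal node required")
        if (length(object@leafWeights) != nL)
            msg <- c(msg, "one leafWeight per leaf required")
    }
    if (length(msg)) msg else TRUE
})

#' CoefficientMatrix: sparse association-strength estimates
#'
#' Rows are predictors (SNPs, or genes in the gene-to-trait stage), columns
#' responses. Exact zeros are structural (produced by soft-thresholding /
#' proximal steps); when a numerical threshold was applied it is recorded in
#' \code{provenance$threshold}.
#'
#' @slot B a \code{dgCMatrix} with dimnames.
#' @slot provenance list: \code{algorithm}, hyperparameters, and optionally
#'   \code{threshold}.
#' @exportClass CoefficientMatrix
setClass("CoefficientMatrix",
         representation(B = "Matrix", provenance = "list"))

setValidity("CoefficientMatrix", function(object) {
    if (is.null(rownames(object@B)) || is.null(colnames(object@B)))
        "coefficient matrix must carry row and column ids"
    else TRUE
})

#' FitResult: solution of a penalized regression fit
#'
#' @slot coefficients a \code{CoefficientMatrix}.
#' @slot objective numeric vector, objective value per outer iteration
#'   (non-increasing for the descent methods used here).
#' @slot converged logical.
#' @slot niter integer, outer iterations used.
#' @slot extras list, solver-specific extras (e.g. adaptive feature weights
#'   \code{theta}, \code{eta}; the population layout for the
#'   multi-population model).
#' @exportClass FitResult
setClass("FitResult",
         representation(coefficients = "CoefficientMatrix",
                        objective = "numeric",
                        converged = "logical",
                        niter = "integer",
                        extras = "list"))

#' CVResult: cross-validated hyperparameter search
#'
#' @slot grid data.frame with columns \code{lambda}, \code{gamma},
#'   \code{cvError} (mean held-out squared prediction error per trait).
#' @slot best list with the selected \code{lambda} and \code{gamma}.
#' @slot folds integer vector of fold assignments (one per sample).
#' @slot seed integer seed that produced the fold split.
#' @exportClass CVResult
setClass("CVResult",
         representation(grid = "data.frame",
                        best = "list",
                        folds = "integer",
                        seed = "integer"))

#' ModuleSet: disjoint highly connected trait modules
#'
#' @slot modules list of character vectors (trait ids), disjoint.
#' @slot scores numeric connectivity scores, non-increasing.
#' @slot params list (M requested, min_size, ...).
#' @exportClass ModuleSet
setClass("ModuleSet",
         representation(modules = "list", scores = "numeric", params = "list"))

setValidity("ModuleSet", function(object) {
    msg <- character()
    all_ids <- unlist(object@modules)
    if (anyDuplicated(all_ids)) msg <- c(msg, "modules must be disjoint")
    if (length(object@scores) != length(object@modules))
        msg <- c(msg, "one score per module required")
    if (is.unsorted(rev(object@scores), strictly = FALSE) &&
        length(object@scores) > 1)
        msg <- c(msg, "scores must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' PopulationAssignment: sample-to-population labels with eigenvector coords
#'
#' @slot labels integer vector (named by sample id), populations 1..C,
#'   canonicalized so population 1 is the largest cluster.
#' @slot eigvecs numeric matrix, samples x top eigenvector coordinates.
#' @slot method character, "kmeans_pca" or "external".
#' @exportClass PopulationAssignment
setClass("PopulationAssignment",
         representation(labels = "integer",
                        eigvecs = "matrix",
                        method = "character"))

#' SimConfig: parameters of the synthetic three-layer generator
#'
#' The generator emulates a cross / stock panel: Balding-Nichols population
#' divergence, first-order Markov LD blocks, co-expressed gene modules driven
#' by sparse SNP effects (including a planted trans hotspot), and a second
#' linear layer from genes to clinical traits. See \code{\link{simConfig}}.
#'
#' @slot params named list of generator parameters (validated by
#'   \code{simConfig}).
#' @exportClass SimConfig
setClass("SimConfig", representation(params = "list"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d samples x %d SNPs (%s coding)\n",
                nrow(object@values), ncol(object@values), object@coding))
    if (nrow(object@snpMap))
        cat(sprintf("  map: %d chromosomes\n",
                    length(unique(object@snpMap$chrom))))
})

setMethod("show", "TraitMatrix", function(object) {
    nmiss <- sum(is.na(object@values))
    cat(sprintf("TraitMatrix (%s): %d samples x %d traits%s\n",
                object@kind, nrow(object@values), ncol(object@values),
                if (nmiss) sprintf(", %d missing entries", nmiss) else ""))
})

setMethod("show", "TraitNetwork", function(object) {
    cat(sprintf("TraitNetwork (%s): %d nodes, %d edges\n",
                object@builder, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "TraitTree", function(object) {
    cat(sprintf("TraitTree: %d leaves, scheme '%s'\n",
                length(object@labels), object@scheme))
})

setMethod("show", "CoefficientMatrix", function(object) {
    cat(sprintf("CoefficientMatrix: %d x %d, %d nonzero (%s)\n",
                nrow(object@B), ncol(object@B), Matrix::nnzero(object@B),
                if (is.null(object@provenance$algorithm)) "unknown"
                else object@provenance$algorithm))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: %s, %d iterations, %sconverged, objective %.6g\n",
                object@coefficients@provenance$algorithm %||% "fit",
                object@niter, if (object@converged) "" else "NOT ",
                utils::tail(object@objective, 1)))
    show(object@coefficients)
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d grid points, best lambda=%.4g gamma=%.4g\n",
                nrow(object@grid), object@best$lambda, object@best$gamma))
})

setMethod("show", "ModuleSet", function(object) {
    cat(sprintf("ModuleSet: %d modules, sizes %s\n", length(object@modules),
                paste(vapply(object@modules, length, 1L), collapse = ", ")))
})

setMethod("show", "PopulationAssignment", function(object) {
    cat(sprintf("PopulationAssignment (%s): %d samples, %d populations\n",
                object@method, length(object@labels),
                length(unique(object@labels))))
})

setMethod("show", "SimConfig", function(object) {
    p <- object@params
    cat(sprintf("SimConfig: n=%d J=%d K=%d q=%d, %d modules, %d population(s)\n",
                p$n, p$J, p$K, p$q, p$nModules, p$nPops))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @param x an object with a values slot
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setMethod("values", "GenotypeMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "TraitMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "SNPFeatureTable", function(x) x@values)

#' Accessors for structmap containers
#'
#' Small accessor family: \code{values} returns the underlying numeric
#' matrix; \code{snpIds}/\code{traitIds} the entity ids; \code{snpMap} and
#' \code{geneMap} the genomic maps; \code{edges}/\code{nodes} the network;
#' \code{coef} the (sparse) coefficient matrix of a fit.
#'
#' @name accessors
#' @param object,x a structmap object
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))
#' @rdname accessors
#' @export
setMethod("traitIds", "TraitMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypeMatrix", function(x) x@snpMap)

#' @rdname accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))
#' @rdname accessors
#' @export
setMethod("geneMap", "TraitMatrix", function(x) x@geneMap)

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setMethod("edges", "TraitNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setMethod("nodes", "TraitNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("coef", "FitResult", function(object) object@coefficients@B)
#' @rdname accessors
#' @export
setMethod("coef", "CoefficientMatrix", function(object) object@B)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "CoefficientMatrix", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "FitResult", function(x) x@coefficients@provenance)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FitResult", function(x) x@objective)

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))
#' @rdname accessors
#' @export
setMethod("populationLabels", "PopulationAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname accessors
#' @export
setMethod("modules", "ModuleSet", function(x) x@modules)

#' @rdname accessors
#' @export
setGeneric("moduleScores", function(x) standardGeneric("moduleScores"))
#' @rdname accessors
#' @export
setMethod("moduleScores", "ModuleSet", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("bestHyperparams", function(x) standardGeneric("bestHyperparams"))
#' @rdname accessors
#' @export
setMethod("bestHyperparams", "CVResult", function(x) x@best)

#' @rdname accessors
#' @export
setGeneric("cvGrid", function(x) standardGeneric("cvGrid"))
#' @rdname accessors
#' @export
setMethod("cvGrid", "CVResult", function(x) x@grid)
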