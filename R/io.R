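## Constructors and tab-delimited I/O for the core containers.
## TSV matrix convention: header row of entity ids, first column sample ids.

#' Construct a GenotypeMatrix
#'
#' @param values numeric matrix (samples x SNPs) with dimnames.
#' @param map optional data.frame with columns snp_id, chrom, pos matching
#'   the SNP column order.
#' @param coding "haploid" (0/1) or "diploid" (0/1/2).
#' @return a \linkS4class{GenotypeMatrix}
#' @export
genotypeMatrix <- function(values, map = NULL,
                           coding = c("haploid", "diploid")) {
    coding <- match.arg(coding)
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("snp", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- paste0("s", seq_len(nrow(values)))
    if (is.null(map))
        map <- data.frame(snp_id = character(0), chrom = character(0),
                          pos = integer(0), stringsAsFactors = FALSE)
    else {
        map <- as.data.frame(map)
        map$snp_id <- as.character(map$snp_id)
        map$chrom <- as.character(map$chrom)
        map$pos <- as.integer(map$pos)
    }
    new("GenotypeMatrix", values = values, snpMap = map, coding = coding)
}

#' Construct a TraitMatrix
#'
#' @param values numeric matrix (samples x traits) with dimnames; NAs allowed
#'   (flagging entries to be imputed).
#' @param kind "expression" or "clinical".
#' @param geneMap optional data.frame trait_id, chrom, tx_start.
#' @return a \linkS4class{TraitMatrix}
#' @export
traitMatrix <- function(values, kind = c("expression", "clinical"),
                        geneMap = NULL) {
    kind <- match.arg(kind)
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("t", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- paste0("s", seq_len(nrow(values)))
    if (is.null(geneMap))
        geneMap <- data.frame(trait_id = character(0), chrom = character(0),
                              tx_start = integer(0), stringsAsFactors = FALSE)
    else {
        geneMap <- as.data.frame(geneMap)
        geneMap$trait_id <- as.character(geneMap$trait_id)
        geneMap$chrom <- as.character(geneMap$chrom)
        geneMap$tx_start <- as.integer(geneMap$tx_start)
    }
    new("TraitMatrix", values = values, kind = kind, geneMap = geneMap)
}

#' Construct an SNPFeatureTable
#'
#' Continuous feature columns (anything not coded 0/1) are standardized to
#' zero mean, unit variance; discrete indicator columns are kept as-is.
#'
#' @param values numeric J x F matrix, rownames = SNP ids.
#' @param standardize standardize continuous columns (default TRUE).
#' @return an \linkS4class{SNPFeatureTable}
#' @export
snpFeatureTable <- function(values, standardize = TRUE) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("f", seq_len(ncol(values)))
    if (standardize) {
        for (j in seq_len(ncol(values))) {
            col <- values[, j]
            if (!all(col %in% c(0, 1))) {
                s <- stats::sd(col)
                values[, j] <- if (s > 0) (col - mean(col)) / s else col - mean(col)
            }
        }
    }
    new("SNPFeatureTable", values = values)
}

.read_tsv_matrix <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (ncol(d) < 2) stop("TSV must have a sample-id column plus data columns")
    ids <- d[[1]]
    if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
    cn <- colnames(d)[-1]
    if (anyDuplicated(cn)) stop("duplicate column ids in ", path)
    M <- matrix(NA_real_, nrow(d), length(cn), dimnames = list(ids, cn))
    for (j in seq_along(cn)) {
        raw <- d[[j + 1]]
        isna <- is.na(raw) | raw %in% c("", "NA", "na", "NaN")
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(num) & !isna)
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                         raw[bad[1]], ids[bad[1]], cn[j], path))
        M[, j] <- num
    }
    M
}

#' Read a genotype or trait matrix from a tab-delimited file
#'
#' The file has a header row of entity ids and a first column of sample ids.
#' For genotypes, every value must lie in the declared coding set and no
#' missing values are allowed; traits may contain NA entries (to be imputed).
#'
#' @param path file path.
#' @param role "genotype" or "trait".
#' @param coding genotype coding, "haploid" or "diploid".
#' @param kind trait kind, "expression" or "clinical".
#' @param map optional SNP map (genotype) or gene map (trait) data.frame, as
#'   from \code{\link{readSnpMap}} / \code{\link{readTraitMap}}.
#' @return a \linkS4class{GenotypeMatrix} or \linkS4class{TraitMatrix}
#' @export
readMatrix <- function(path, role = c("genotype", "trait"),
                       coding = c("haploid", "diploid"),
                       kind = c("expression", "clinical"), map = NULL) {
    role <- match.arg(role)
    M <- .read_tsv_matrix(path)
    if (role == "genotype") {
        coding <- match.arg(coding)
        if (anyNA(M)) stop("missing genotype values in ", path)
        allowed <- if (coding == "diploid") c(0, 1, 2) else c(0, 1)
        bad <- which(!(M %in% allowed))
        if (length(bad)) {
            i <- arrayInd(bad[1], dim(M))
            stop(sprintf("genotype value %g at row '%s', column '%s' outside coding set {%s}",
                         M[bad[1]], rownames(M)[i[1]], colnames(M)[i[2]],
                         paste(allowed, collapse = ",")))
        }
        genotypeMatrix(M, map = map, coding = coding)
    } else {
        traitMatrix(M, kind = match.arg(kind), geneMap = map)
    }
}

#' Write a matrix container to a canonical tab-delimited file
#'
#' @param x GenotypeMatrix, TraitMatrix or plain matrix with dimnames.
#' @param path output path.
#' @param id_col name of the first (sample id) column header.
#' @export
writeMatrix <- function(x, path, id_col = "sample_id") {
    M <- .as_matrix_input(x)
    d <- data.frame(rownames(M), M, check.names = FALSE,
                    stringsAsFactors = FALSE)
    colnames(d)[1] <- id_col
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a SNP map (snp_id, chrom, pos) or trait map (trait_id, chrom,
#' tx_start) from TSV
#'
#' @param path file path
#' @return data.frame
#' @export
readSnpMap <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("snp_id", "chrom", "pos") %in% names(d)))
    d$snp_id <- as.character(d$snp_id)
    d$chrom <- as.character(d$chrom)
    d$pos <- as.integer(d$pos)
    d
}

#' @rdname readSnpMap
#' @export
readTraitMap <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("trait_id", "chrom", "tx_start") %in% names(d)))
    d$trait_id <- as.character(d$trait_id)
    d$chrom <- as.character(d$chrom)
    d$tx_start <- as.integer(d$tx_start)
    d
}

#' Construct a TraitNetwork from an edge table
#'
#' Edges are canonicalized (endpoints ordered by node index, duplicates
#' collapsed keeping the first); self-edges are an error.
#'
#' @param nodes character vector of trait ids.
#' @param edgeTable data.frame with columns a, b, w and optionally r
#'   (signed value; defaults to w).
#' @param builder builder tag recorded on the network.
#' @param params list of builder parameters.
#' @return a \linkS4class{TraitNetwork}
#' @export
traitNetwork <- function(nodes, edgeTable = NULL, builder = "external",
                         params = list()) {
    nodes <- as.character(nodes)
    if (is.null(edgeTable) || nrow(edgeTable) == 0) {
        edgeTable <- data.frame(a = character(0), b = character(0),
                                w = numeric(0), r = numeric(0),
                                stringsAsFactors = FALSE)
    } else {
        edgeTable <- as.data.frame(edgeTable, stringsAsFactors = FALSE)
        if (is.null(edgeTable$r)) edgeTable$r <- edgeTable$w
        ii <- match(as.character(edgeTable$a), nodes)
        jj <- match(as.character(edgeTable$b), nodes)
        if (anyNA(ii) || anyNA(jj)) stop("edge endpoint not among nodes")
        swap <- ii > jj
        a <- ifelse(swap, nodes[jj], nodes[ii])
        b <- ifelse(swap, nodes[ii], nodes[jj])
        edgeTable <- data.frame(a = a, b = b, w = edgeTable$w,
                                r = edgeTable$r, stringsAsFactors = FALSE)
        edgeTable <- edgeTable[!duplicated(paste(a, b)), , drop = FALSE]
        rownames(edgeTable) <- NULL
    }
    new("TraitNetwork", nodes = nodes, edges = edgeTable,
        builder = builder, params = params)
}

#' Read / write a trait network edge list (TSV: trait_a, trait_b, weight
#' [, signed])
#'
#' @param path file path
#' @param nodes optional node universe; defaults to the ids present in the
#'   edge list.
#' @return a \linkS4class{TraitNetwork}
#' @export
readEdgeList <- function(path, nodes = NULL) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("trait_a", "trait_b", "weight") %in% names(d)))
    if (is.null(nodes)) nodes <- sort(unique(c(d$trait_a, d$trait_b)))
    traitNetwork(nodes,
                 data.frame(a = d$trait_a, b = d$trait_b, w = d$weight,
                            r = if (is.null(d$signed)) d$weight else d$signed,
                            stringsAsFactors = FALSE),
                 builder = "external", params = list(path = path))
}

#' @rdname readEdgeList
#' @param net a TraitNetwork
#' @export
writeEdgeList <- function(net, path) {
    e <- edges(net)
    utils::write.table(
        data.frame(trait_a = e$a, trait_b = e$b, weight = e$w, signed = e$r),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a trait-to-term annotation map (TSV: trait_id, term_id)
#'
#' @param path file path
#' @return named list: term id -> character vector of trait ids
#' @export
readAnnotationMap <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("trait_id", "term_id") %in% names(d)))
    split(as.character(d$trait_id), as.character(d$term_id))
}

#' Read an SNP feature table (TSV: first column snp_id, then features)
#'
#' @param path file path
#' @param standardize standardize continuous columns (default TRUE)
#' @return an \linkS4class{SNPFeatureTable}
#' @export
readSnpFeatures <- function(path, standardize = TRUE) {
    M <- .read_tsv_matrix(path)
    .assert_no_na(M, "SNP feature table")
    snpFeatureTable(M, standardize = standardize)
}

#' Write a sparse coefficient matrix as TSV (row_id, col_id, beta)
#'
#' @param fit a FitResult or CoefficientMatrix
#' @param path output path
#' @export
writeCoefficients <- function(fit, path) {
    B <- if (methods::is(fit, "FitResult")) coef(fit) else fit@B
    tri <- Matrix::summary(B)
    d <- data.frame(snp_id = rownames(B)[tri$i],
                    trait_id = colnames(B)[tri$j],
                    beta = tri$x, stringsAsFactors = FALSE)
    d <- d[abs(d$beta) > 0, , drop = FALSE]
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
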