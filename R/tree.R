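## Hierarchical trait trees for the tree-guided group penalty.
##
## A TraitTree is an agglomerative clustering of the traits (average linkage
## on 1 - |correlation| or 1 - edge weight), with heights normalized to
## [0, 1] and per-node group weights. The default weighting follows the
## standard tree-penalty recursion: internal node v at normalized height h_v
## carries a "joint selection" weight s_v = 1 - h_v and passes g_v = h_v to
## its descendants, so
##   nodeWeight(v) = s_v * prod(g_a, a proper ancestor of v)
##   leafWeight(l) =       prod(g_a, a ancestor of l)
## Tightly correlated subtrees (low merge height) are therefore penalized
## mostly as a group, loose subtrees mostly per trait; the weights sum to a
## telescoping total that keeps the overall penalty scale comparable to the
## lasso. The scheme is pluggable through `weights`.

.tree_members <- function(merge, nLeaves) {
    members <- vector("list", nrow(merge))
    for (v in seq_len(nrow(merge))) {
        m <- integer(0)
        for (child in merge[v, ]) {
            m <- c(m, if (child < 0) -child else members[[child]])
        }
        members[[v]] <- sort(m)
    }
    members
}

.tree_weights_height <- function(merge, height) {
    nV <- nrow(merge)
    nL <- nV + 1L
    s <- 1 - height
    g <- height
    nodeW <- numeric(nV)
    leafW <- numeric(nL)
    ## ancestor products by top-down recursion from the root (last merge row)
    prodAbove <- numeric(nV)
    for (v in rev(seq_len(nV))) {
        if (v == nV) prodAbove[v] <- 1
        nodeW[v] <- s[v] * prodAbove[v]
        for (child in merge[v, ]) {
            p <- prodAbove[v] * g[v]
            if (child < 0) leafW[-child] <- p else prodAbove[child] <- p
        }
    }
    list(node = nodeW, leaf = leafW)
}

#' Build a trait tree by hierarchical clustering
#'
#' @param x a \linkS4class{TraitMatrix} / matrix (distance
#'   1 - |correlation|) or a \linkS4class{TraitNetwork} (distance
#'   1 - edge weight, absent edges at distance 1).
#' @param linkage agglomeration method (default "average").
#' @param weights weighting scheme: \code{"height"} (default, see Details),
#'   \code{"uniform"} (all node and leaf weights 1), or a function
#'   \code{function(merge, height)} returning \code{list(node=, leaf=)}.
#' @return a \linkS4class{TraitTree}
#' @export
traitTree <- function(x, linkage = "average", weights = "height") {
    if (methods::is(x, "TraitNetwork")) {
        ids <- nodes(x)
        K <- length(ids)
        D <- matrix(1, K, K, dimnames = list(ids, ids))
        e <- edges(x)
        if (nrow(e)) {
            ia <- match(e$a, ids); ib <- match(e$b, ids)
            D[cbind(ia, ib)] <- D[cbind(ib, ia)] <- 1 - e$w
        }
        diag(D) <- 0
    } else {
        M <- .as_matrix_input(x)
        .assert_no_na(M, "trait matrix")
        ids <- colnames(M)
        D <- 1 - abs(stats::cor(M))
        D[D < 0] <- 0
    }
    if (length(ids) < 2) stop("need at least 2 traits")
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    h <- hc$height
    hmax <- max(h)
    if (hmax > 0) h <- pmin(pmax(h / hmax, 0), 1)
    scheme <- if (is.function(weights)) "custom" else match.arg(weights, c("height", "uniform"))
    wfun <- if (is.function(weights)) weights
            else if (scheme == "uniform")
                function(merge, height) list(node = rep(1, nrow(merge)),
                                             leaf = rep(1, nrow(merge) + 1L))
            else .tree_weights_height
    w <- wfun(hc$merge, h)
    new("TraitTree", labels = ids, merge = hc$merge, height = h,
        nodeWeights = w$node, leafWeights = w$leaf, scheme = scheme)
}

#' Penalty groups encoded by a trait tree
#'
#' @param tree a \linkS4class{TraitTree}
#' @param dropZero drop groups with zero weight (default TRUE)
#' @return list of \code{list(cols, weight)}: trait index sets with their
#'   group weights (leaves are singleton groups carrying the L1 part)
#' @export
treeGroups <- function(tree, dropZero = TRUE) {
    nL <- length(tree@labels)
    members <- .tree_members(tree@merge, nL)
    out <- list()
    for (l in seq_len(nL)) {
        if (!dropZero || tree@leafWeights[l] > 0)
            out[[length(out) + 1L]] <- list(cols = l, weight = tree@leafWeights[l])
    }
    for (v in seq_along(members)) {
        if (!dropZero || tree@nodeWeights[v] > 0)
            out[[length(out) + 1L]] <- list(cols = members[[v]],
                                            weight = tree@nodeWeights[v])
    }
    out
}

#' Member trait sets of the internal nodes
#'
#' @param tree a \linkS4class{TraitTree}
#' @return list of character vectors, one per internal node (merge order)
#' @export
treeMembers <- function(tree) {
    lapply(.tree_members(tree@merge, length(tree@labels)),
           function(ix) tree@labels[ix])
}

## ---------------------------------------------------------------------------
## Newick serialization (internal node labels carry the node weights)
## ---------------------------------------------------------------------------

#' Write a trait tree as Newick
#'
#' Internal node labels carry the node weights as \code{w=<value>}; branch
#' lengths encode the (normalized) merge heights. Leaf weights are not
#' stored; \code{\link{readTraitTree}} recomputes them from the heights
#' under the default scheme.
#'
#' @param tree a \linkS4class{TraitTree}
#' @param path output path
#' @export
writeTraitTree <- function(tree, path) {
    nV <- nrow(tree@merge)
    build <- function(node, parentH) {
        if (node < 0) {
            sprintf("%s:%.10g", tree@labels[-node], parentH)
        } else {
            h <- tree@height[node]
            kids <- vapply(tree@merge[node, ], build, "", parentH = h)
            sprintf("(%s,%s)w=%.10g:%.10g", kids[1], kids[2],
                    tree@nodeWeights[node], parentH - h)
        }
    }
    txt <- paste0(sub(":[^:]*$", "", build(nV, tree@height[nV])), ";")
    writeLines(txt, path)
    invisible(path)
}

## minimal recursive-descent Newick parser (binary, labeled internals)
.parse_newick <- function(txt) {
    txt <- gsub("\\s", "", sub(";\\s*$", "", txt))
    pos <- 1L
    nchr <- nchar(txt)
    peek <- function() substr(txt, pos, pos)
    token <- function() {
        start <- pos
        while (pos <= nchr && !peek() %in% c("(", ")", ",", ":")) pos <<- pos + 1L
        substr(txt, start, pos - 1L)
    }
    node <- function() {
        if (peek() == "(") {
            pos <<- pos + 1L
            left <- node()
            stopifnot(peek() == ",")
            pos <<- pos + 1L
            right <- node()
            stopifnot(peek() == ")")
            pos <<- pos + 1L
            lab <- token()
            br <- 0
            if (peek() == ":") { pos <<- pos + 1L; br <- as.numeric(token()) }
            list(children = list(left, right), label = lab, brlen = br)
        } else {
            lab <- token()
            br <- 0
            if (peek() == ":") { pos <<- pos + 1L; br <- as.numeric(token()) }
            list(children = NULL, label = lab, brlen = br)
        }
    }
    node()
}

#' Read a trait tree from Newick
#'
#' @param path file path
#' @param weights weighting scheme used to recompute leaf weights (and node
#'   weights when the file has no \code{w=} labels); see
#'   \code{\link{traitTree}}.
#' @return a \linkS4class{TraitTree}
#' @export
readTraitTree <- function(path, weights = "height") {
    root <- .parse_newick(paste(readLines(path), collapse = ""))
    labels <- character(0)
    rows <- list()   # list of (childA, childB, height, weight)
    depth <- function(nd) {   # height of node above the deepest leaf
        if (is.null(nd$children)) return(0)
        max(vapply(nd$children, function(ch) depth(ch) + ch$brlen, 0))
    }
    walk <- function(nd) {
        ## returns (ref, height): ref < 0 leaf index, > 0 merge row
        if (is.null(nd$children)) {
            labels <<- c(labels, nd$label)
            return(list(ref = -length(labels), height = 0))
        }
        a <- walk(nd$children[[1]])
        b <- walk(nd$children[[2]])
        h <- depth(nd)
        w <- if (grepl("^w=", nd$label)) as.numeric(sub("^w=", "", nd$label)) else NA_real_
        rows[[length(rows) + 1L]] <<- list(a = a$ref, b = b$ref, h = h, w = w)
        list(ref = length(rows), height = h)
    }
    walk(root)
    ## hclust convention: merge rows sorted by height
    ord <- order(vapply(rows, function(r) r$h, 0))
    rank <- match(seq_along(rows), ord)
    merge <- t(vapply(rows[ord], function(r) {
        remap <- function(x) if (x < 0) x else rank[x]
        c(remap(r$a), remap(r$b))
    }, c(0, 0)))
    storage.mode(merge) <- "integer"
    height <- vapply(rows[ord], function(r) r$h, 0)
    hmax <- max(height)
    if (hmax > 0) height <- pmin(height / hmax, 1)
    fileW <- vapply(rows[ord], function(r) r$w, 0)
    scheme <- if (is.function(weights)) "custom" else weights
    wfun <- if (is.function(weights)) weights
            else if (identical(weights, "uniform"))
                function(merge, height) list(node = rep(1, nrow(merge)),
                                             leaf = rep(1, nrow(merge) + 1L))
            else .tree_weights_height
    w <- wfun(merge, height)
    nodeW <- ifelse(is.na(fileW), w$node, fileW)
    new("TraitTree", labels = labels, merge = merge, height = height,
        nodeWeights = nodeW, leafWeights = w$leaf, scheme = scheme)
}
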