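## Gene-module discovery: dynamic programming over tree cuts.
##
## Each internal node of the trait tree is a candidate module with
## connectivity score = (total internal edge weight) / (module size), i.e.
## half the mean internal degree (absent edges count as weight 0). Unlike
## raw edge density, this score grows with size at equal density, so a
## dense module beats its own sub-cliques, while attaching loosely
## connected traits or merging unrelated modules lowers it. A tree DP
## selects up to M disjoint (non-nested) nodes maximizing the total score.

#' Extract the top connected trait modules
#'
#' @param tree a \linkS4class{TraitTree} over the traits.
#' @param net a \linkS4class{TraitNetwork} on the same traits.
#' @param M number of modules requested (default 20).
#' @param minSize minimum module size (default 3).
#' @return a \linkS4class{ModuleSet}; if fewer than M eligible disjoint
#'   subtrees exist, all found are returned with a warning
#' @export
extractModules <- function(tree, net, M = 20, minSize = 3) {
    stopifnot(M >= 1)
    ids <- tree@labels
    K <- length(ids)
    W <- matrix(0, K, K, dimnames = list(ids, ids))
    e <- edges(net)
    if (nrow(e)) {
        ia <- match(e$a, ids); ib <- match(e$b, ids)
        ok <- !is.na(ia) & !is.na(ib)
        W[cbind(ia[ok], ib[ok])] <- W[cbind(ib[ok], ia[ok])] <- e$w[ok]
    }
    members <- .tree_members(tree@merge, K)
    score <- vapply(members, function(m) {
        if (length(m) < 2) return(0)
        sum(W[m, m]) / (2 * length(m))   # internal edge weight per trait
    }, numeric(1))
    eligible <- vapply(members, length, 1L) >= minSize

    nV <- nrow(tree@merge)
    ## DP over the tree: best[[v]][m+1] = best total score using up to m
    ## disjoint eligible nodes inside subtree v; pick[[v]][m+1] the choice.
    best <- vector("list", nV)
    pick <- vector("list", nV)
    childBest <- function(child, m) {
        if (m <= 0 || child < 0) return(0)
        best[[child]][m + 1]
    }
    for (v in seq_len(nV)) {
        b <- numeric(M + 1)
        p <- vector("list", M + 1)
        for (m in 0:M) {
            ## split the budget between the two children
            bm <- -Inf; pm <- NULL
            for (m1 in 0:m) {
                val <- childBest(tree@merge[v, 1], m1) +
                       childBest(tree@merge[v, 2], m - m1)
                if (val > bm) { bm <- val; pm <- c(m1, m - m1) }
            }
            ## or take v itself as a module
            if (m >= 1 && eligible[v] && score[v] > bm) {
                bm <- score[v]; pm <- "self"
            }
            b[m + 1] <- bm
            p[[m + 1]] <- pm
        }
        best[[v]] <- b
        pick[[v]] <- p
    }
    chosen <- integer(0)
    trace <- function(v, m) {
        if (v < 0 || m <= 0) return(invisible())
        pm <- pick[[v]][[m + 1]]
        if (identical(pm, "self")) chosen <<- c(chosen, v)
        else {
            trace(tree@merge[v, 1], pm[1])
            trace(tree@merge[v, 2], pm[2])
        }
        invisible()
    }
    trace(nV, M)
    if (length(chosen) < M)
        warning(sprintf("only %d disjoint modules of size >= %d found (%d requested)",
                        length(chosen), minSize, M))
    ord <- order(score[chosen], decreasing = TRUE)
    chosen <- chosen[ord]
    new("ModuleSet",
        modules = lapply(chosen, function(v) ids[members[[v]]]),
        scores = score[chosen],
        params = list(M = M, minSize = minSize))
}
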