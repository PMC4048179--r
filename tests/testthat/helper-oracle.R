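## Independent convex reference solver (scipy epigraph SLSQP) used to verify
## solver objectives, plus shared objective evaluators written directly from
## the model definitions (independent of the package internals).

oracle_available <- function() nzchar(Sys.which("python"))

oracle_solve <- function(problems) {
    script <- system.file("oracle", "convex_oracle.py", package = "structmap")
    fin <- tempfile(fileext = ".json")
    fout <- tempfile(fileext = ".json")
    jsonlite::write_json(list(problems = problems), fin,
                         auto_unbox = TRUE, digits = NA)
    out <- system2(Sys.which("python"), c(script, fin, fout),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(fout))
        stop("oracle failed: ", paste(out, collapse = "\n"))
    res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)$solutions
    lapply(res, function(s) list(
        obj = s$obj,
        B = do.call(rbind, lapply(s$B, unlist))))
}

## ---- atom builders (0-based indices into vec(B), column-major) ----------

vecix <- function(j, k, J) (k - 1) * J + (j - 1)   # 0-based

atoms_l1 <- function(J, K, w) {
    w <- rep(w, length.out = J)
    out <- list()
    for (k in seq_len(K)) for (j in seq_len(J)) {
        if (w[j] > 0)
            out[[length(out) + 1]] <- list(kind = "abs", w = w[j],
                                           idx = vecix(j, k, J), coef = 1)
    }
    out
}

atoms_row_l2 <- function(J, K, w, cols = NULL) {
    w <- rep(w, length.out = J)
    cols <- cols %||% list(seq_len(K))
    out <- list()
    for (j in seq_len(J)) for (g in cols) {
        if (w[j] > 0)
            out[[length(out) + 1]] <- list(kind = "l2", w = w[j],
                                           idx = vecix(j, g, J))
    }
    out
}

atoms_snp_groups <- function(groups, K, w, J) {
    out <- list()
    for (gi in seq_along(groups)) for (k in seq_len(K)) {
        if (w[gi] > 0)
            out[[length(out) + 1]] <- list(kind = "l2", w = w[gi],
                                           idx = vecix(groups[[gi]], k, J))
    }
    out
}

atoms_col_fusion <- function(edgesDf, J, gamma, signed = FALSE) {
    ## edgesDf: columns ia, ib (1-based column indices), w, r
    out <- list()
    for (e in seq_len(nrow(edgesDf))) {
        s <- if (signed && edgesDf$r[e] < 0) -1 else 1
        we <- gamma * edgesDf$w[e]
        if (we <= 0) next
        for (j in seq_len(J)) {
            out[[length(out) + 1]] <- list(
                kind = "abs", w = we,
                idx = c(vecix(j, edgesDf$ia[e], J), vecix(j, edgesDf$ib[e], J)),
                coef = c(1, -s))
        }
    }
    out
}

atoms_row_fusion <- function(edgesDf, J, K, gamma, signed = FALSE) {
    out <- list()
    for (e in seq_len(nrow(edgesDf))) {
        s <- if (signed && edgesDf$r[e] < 0) -1 else 1
        we <- gamma * edgesDf$w[e]
        if (we <= 0) next
        for (k in seq_len(K)) {
            out[[length(out) + 1]] <- list(
                kind = "abs", w = we,
                idx = c(vecix(edgesDf$ia[e], k, J), vecix(edgesDf$ib[e], k, J)),
                coef = c(1, -s))
        }
    }
    out
}

atoms_tree <- function(tree, lambda, J, trait_ids) {
    colmap <- match(tree@labels, trait_ids)
    out <- list()
    for (g in treeGroups(tree)) {
        w <- lambda * g$weight
        if (w <= 0) next
        cols <- colmap[g$cols]
        for (j in seq_len(J))
            out[[length(out) + 1]] <- list(kind = "l2", w = w,
                                           idx = vecix(j, cols, J))
    }
    out
}

atoms_block <- function(snpGroups, traitGroups, lambda2, W, J) {
    out <- list()
    for (g in seq_along(snpGroups)) for (h in seq_along(traitGroups)) {
        w <- lambda2 * W[g, h]
        if (w <= 0) next
        idx <- as.vector(outer(snpGroups[[g]] - 1,
                               (traitGroups[[h]] - 1) * J, "+"))
        out[[length(out) + 1]] <- list(kind = "l2", w = w, idx = idx)
    }
    out
}

## ---- independent objective evaluator ------------------------------------

eval_objective <- function(X, Y, B, atoms) {
    v <- as.vector(B)   # column-major
    pen <- 0
    for (a in atoms) {
        x <- v[unlist(a$idx) + 1]
        pen <- pen + if (identical(a$kind, "abs"))
            a$w * abs(sum(unlist(a$coef) * x))
        else a$w * sqrt(sum(x^2))
    }
    0.5 * sum((Y - X %*% B)^2) + pen
}

## network edges with 1-based column indices for the atom builders
edge_index_df <- function(net, ids) {
    e <- structmap::edges(net)
    data.frame(ia = match(e$a, ids), ib = match(e$b, ids), w = e$w, r = e$r)
}
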