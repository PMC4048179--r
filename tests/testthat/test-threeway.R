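test_that("triplet assembly is exactly the support product", {
    snps <- paste0("snp", 1:4); genes <- paste0("g", 1:3); traits <- paste0("p", 1:2)
    ## single chain
    B <- matrix(0, 4, 3); B[2, 1] <- 0.5
    A <- matrix(0, 3, 2); A[1, 2] <- -0.3
    tp <- assembleTriplets(.cm(B, snps, genes), .cm(A, genes, traits))
    expect_equal(nrow(tp), 1)
    expect_equal(tp$snp_id, "snp2")
    expect_equal(tp$gene_id, "g1")
    expect_equal(tp$trait_id, "p2")
    ## empty stage-1 support gives no triplets
    expect_equal(nrow(assembleTriplets(.cm(matrix(0, 4, 3), snps, genes),
                                       .cm(A, genes, traits))), 0)
    ## random supports: |triplets| = sum_m |supp(B[, m])| * |supp(A[m, ])|
    set.seed(50)
    for (rep in 1:10) {
        B <- matrix(rbinom(12, 1, 0.4) * rnorm(12), 4, 3)
        A <- matrix(rbinom(6, 1, 0.5) * rnorm(6), 3, 2)
        tp <- assembleTriplets(.cm(B, snps, genes), .cm(A, genes, traits))
        want <- sum(sapply(1:3, function(m) sum(B[, m] != 0) * sum(A[m, ] != 0)))
        expect_equal(nrow(tp), want)
    }
})

test_that("cis/trans classification matches a brute-force distance filter", {
    snps <- paste0("snp", 1:3)
    genes <- paste0("g", 1:3)
    smap <- data.frame(snp_id = snps, chrom = c("chr1", "chr1", "chr2"),
                       pos = c(100L, 5000000L, 100L))
    gmap <- data.frame(trait_id = genes, chrom = c("chr1", "chr2", "chr3"),
                       tx_start = c(10000099L, 100L, 100L))
    B <- matrix(1, 3, 3)
    ct <- classifyCisTrans(.cm(B, snps, genes), smap, gmap)
    ## same chromosome at distance 9,999,999 bp is cis (10 Mb rule)
    r1 <- ct[ct$snp_id == "snp1" & ct$gene_id == "g1", ]
    expect_equal(r1$distance, 9999999)
    expect_equal(r1$label, "cis")
    ## different chromosomes are always trans
    expect_true(all(ct$label[ct$chrom_snp != ct$chrom_gene] == "trans"))
    ## random maps equal an independent oracle
    set.seed(51)
    for (rep in 1:10) {
        J <- sample(5:20, 1); K <- sample(3:8, 1)
        sj <- paste0("s", 1:J); gk <- paste0("g", 1:K)
        sm <- data.frame(snp_id = sj, chrom = sample(paste0("chr", 1:3), J, TRUE),
                         pos = sample.int(3e7, J))
        gm <- data.frame(trait_id = gk, chrom = sample(paste0("chr", 1:3), K, TRUE),
                         tx_start = sample.int(3e7, K))
        B <- matrix(rbinom(J * K, 1, 0.3), J, K)
        ct <- classifyCisTrans(.cm(B, sj, gk), sm, gm)
        for (r in seq_len(nrow(ct))) {
            i <- match(ct$snp_id[r], sj); m <- match(ct$gene_id[r], gk)
            want <- if (sm$chrom[i] == gm$chrom[m] &&
                        abs(sm$pos[i] - gm$tx_start[m]) <= 1e7) "cis" else "trans"
            expect_equal(ct$label[r], want)
        }
    }
    ## unmapped ids labeled unknown with a warning
    expect_warning(
        ct2 <- classifyCisTrans(.cm(B, paste0("s", 1:J), gk),
                                sm[-1, ], gm),
        "unmapped")
    expect_true(any(ct2$label == "unknown"))
})

test_that("SNP merging follows single-linkage chaining within 2 Mb", {
    snps <- paste0("snp", 1:4); genes <- "g1"
    ## two SNPs 1 Mb apart merge into one association
    sm <- data.frame(snp_id = snps, chrom = "chr1",
                     pos = c(1e6L, 2e6L, 10e6L, 13.5e6L))
    B <- matrix(c(0.2, 0.9, 0.4, 0.1), 4, 1)
    mg <- mergeNearbySNPs(.cm(B, snps, genes), sm)
    expect_equal(nrow(mg), 3)   # {snp1,snp2} | {snp3} | {snp4}
    expect_equal(mg$snp_id[mg$n_snps == 2], "snp2")   # strongest |beta|
    ## 3 Mb apart stays two associations
    sm2 <- data.frame(snp_id = snps[1:2], chrom = "chr1", pos = c(1e6L, 4e6L))
    mg2 <- mergeNearbySNPs(.cm(B[1:2, , drop = FALSE], snps[1:2], genes), sm2)
    expect_equal(nrow(mg2), 2)
    ## random clustered positions match a brute-force chaining oracle
    set.seed(52)
    for (rep in 1:10) {
        J <- sample(5:50, 1)
        sj <- paste0("s", 1:J)
        sm <- data.frame(snp_id = sj, chrom = sample(c("chr1", "chr2"), J, TRUE),
                         pos = sample.int(2e7, J))
        B <- matrix(rbinom(J, 1, 0.6) * rnorm(J), J, 1)
        mg <- mergeNearbySNPs(.cm(B, sj, "g1"), sm, window = 2e6)
        ## oracle: count chains per chromosome among supported SNPs
        want <- 0
        for (ch in unique(sm$chrom)) {
            ps <- sort(sm$pos[sm$chrom == ch & B[, 1] != 0])
            if (!length(ps)) next
            want <- want + 1 + sum(diff(ps) > 2e6)
        }
        expect_equal(nrow(mg), want)
    }
})

test_that("hotspot detection counts row support exactly", {
    snps <- paste0("snp", 1:3); genes <- paste0("g", 1:25)
    B <- matrix(0, 3, 25)
    B[1, 1:25] <- 1      # 25 genes -> hotspot at threshold 20
    B[2, 1:20] <- 1      # exactly 20 -> not flagged (strictly more than)
    hs <- detectHotspots(.cm(B, snps, genes), minGenes = 20)
    expect_true(hs$hotspot[hs$snp_id == "snp1"])
    expect_false(hs$hotspot[hs$snp_id == "snp2"])
    expect_equal(hs$n_genes[hs$snp_id == "snp1"], 25)
    ## empty coefficient matrix has no hotspots
    hs0 <- detectHotspots(.cm(matrix(0, 3, 25), snps, genes))
    expect_false(any(hs0$hotspot))
})

test_that("two-stage pipeline recovers a planted chain on small simulated data", {
    cfg <- simConfig(n = 150, J = 30, K = 15, q = 4, nModules = 3,
                     causal = list(list(snp = 1, module = 1, beta = 0.9)),
                     hotspot = FALSE,
                     geneTrait = list(list(genes = 1:5, trait = 1, effect = 0.5)),
                     seed = 99)
    d <- simulateDataset(cfg)
    X <- values(d$genotypes); Y <- values(d$expression); Z <- values(d$traits)
    geneNet <- correlationNetwork(Y, 0.4)
    traitNet <- correlationNetwork(Z, 0.4)
    l1 <- 0.6 * max(abs(crossprod(scale(X), scale(Y))))
    l2 <- 0.45 * max(abs(crossprod(scale(Y), scale(Z))))
    ts <- runTwoStage(X, Y, Z, geneNet, traitNet,
                      list(lambda = l1, gamma = 0.3 * l1, lambda2 = l2,
                           gammaGene = 0.3 * l2, gammaTrait = 0.3 * l2),
                      tol = 1e-6)
    tp <- ts$triplets
    expect_gt(nrow(tp), 0)
    ## the planted chain snp1 -> module-1 gene -> trait p1 is present
    expect_true(any(tp$snp_id == "snp1" & tp$gene_id %in% paste0("g", 1:5) &
                    tp$trait_id == "p1"))
    ## X-chromosome filter utility drops flagged rows
    ct <- classifyCisTrans(ts$stage1, snpMap(d$genotypes),
                           geneMap(d$expression))
    expect_identical(dropChromosome(ct, "chrX"), ct)
})
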