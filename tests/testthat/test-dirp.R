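test_that("pairwise identity counts only mutually ungapped columns", {
    msa <- c(s1 = "ACD-", s2 = "ACE-", s3 = "ACD-", s4 = "A---",
             s5 = "-A--")
    expect_equal(pairwiseIdentity(msa, "s1", "s3"), 100)
    expect_equal(pairwiseIdentity(msa, "s1", "s2"), 100 * 2 / 3,
                 tolerance = 1e-12)
    expect_error(pairwiseIdentity(msa, "s4", "s5"), "ungapped")
    expect_error(pairwiseIdentity(msa, "s1", "zz"), "absent")
})

test_that("closeness threshold is the type-7 (1-alpha) null quantile", {
    expect_equal(closenessThreshold(1:100, alpha = 0.05),
                 unname(quantile(1:100, 0.95, type = 7)))
    expect_equal(closenessThreshold(1:100, alpha = 0), 100)
    expect_error(closenessThreshold(numeric(0)), "empty")

    # cross-check: values above the cutoff are significant at ~alpha
    set.seed(2)
    null <- rnorm(500)
    cut <- closenessThreshold(null, alpha = 0.05)
    p <- empiricalPValue(cut + 1e-9, null, "greater")
    expect_lte(p, 0.05 + 1 / 501)
})

test_that("selection applies identity and closeness thresholds jointly", {
    pairs <- data.frame(
        id_a = c("a", "a", "b", "c"), id_b = c("b", "c", "c", "d"),
        identity_pct = c(30, 50, 30, 30),
        phylo_raw = NA_real_, phylo_norm = c(2.5, 2.5, 2.5, 0.5),
        reachable = c(TRUE, TRUE, TRUE, FALSE),
        similarity = c(0.9, 0.95, 0.1, 0.9),
        net_dist = c(0.1, 0.05, 2.3, 0.1))
    sel <- selectDIRP(pairs, cutoff = 0.5)
    got <- dirpPairs(sel)
    # high-identity pair excluded despite maximal similarity
    expect_false(got$selected[got$id_a == "a" & got$id_b == "c"])
    # unreachable pair excluded
    expect_false(got$selected[got$id_b == "d"])
    expect_equal(sum(got$selected), 1)

    # no pair passing both thresholds is a valid, empty result
    none <- selectDIRP(pairs, cutoff = 2)
    expect_equal(nrow(dirpSelected(none)), 0)

    cnt <- selectionCounts(sel)
    expect_true(cnt$initial >= cnt$divergent & cnt$divergent >= cnt$selected)
})

test_that("selection is monotone in both thresholds", {
    set.seed(9)
    pairs <- data.frame(
        id_a = sprintf("x%02d", 1:40), id_b = sprintf("y%02d", 1:40),
        identity_pct = runif(40, 0, 100), phylo_raw = NA_real_,
        phylo_norm = runif(40, 0, 4), reachable = TRUE,
        similarity = runif(40), net_dist = runif(40))
    base <- sum(dirpPairs(selectDIRP(pairs, cutoff = 0.5))$selected)
    looser_id <- selectDIRP(pairs, cutoff = 0.5,
                            config = pipelineConfig(identityMax = 80))
    lower_cut <- selectDIRP(pairs, cutoff = 0.2)
    expect_gte(sum(dirpPairs(looser_id)$selected), base)
    expect_gte(sum(dirpPairs(lower_cut)$selected), base)
})

test_that("planted pairs are recovered with no decoy excess at alpha", {
    spec <- syntheticSpec(seed = 1)
    res <- runPipeline(spec)
    planted <- pk(res$family$plantedPairs)
    for (kn in c("diffusion", "commute_time")) {
        sel <- pk(dirpSelected(res$dirp[[kn]]))
        expect_true(all(planted %in% sel))
        nDecoy <- nrow(dirpPairs(res$dirp[[kn]])) - length(planted)
        fp <- length(setdiff(sel, planted))
        expect_lte(fp / nDecoy, 0.05)
    }
})

test_that("shared-partner medians separate planted pairs from decoys", {
    spec <- syntheticSpec(seed = 3)
    fam <- synthFamily(spec)
    syn <- synthNetwork(spec, fam$plantedPairs)
    planted <- sharedPartnerStats(syn$network, fam$plantedPairs)
    expect_equal(planted$counts$shared, rep(3L, 5))
    expect_equal(planted$median, 3)

    members <- sort(unique(c(fam$plantedPairs$id_a, fam$plantedPairs$id_b)))
    all_pairs <- as.data.frame(t(combn(sprintf("FAM%02d", 1:16), 2)))
    decoys <- all_pairs[!pk(all_pairs) %in% pk(fam$plantedPairs), ]
    expect_equal(sharedPartnerStats(syn$network, decoys)$median, 0)
})

test_that("bin summaries reduce to the whole-set summary for one bin", {
    set.seed(4)
    pairs <- data.frame(phylo_norm = runif(50, 0, 3),
                        net_dist = runif(50, 0, 2))
    one <- binDistanceSummary(pairs, nBins = 1L)
    expect_equal(one$n, 50L)
    expect_equal(one$median, median(pairs$net_dist))
    expect_equal(c(one$min, one$max), range(pairs$net_dist))

    # positively coupled fixture has increasing bin medians
    coupled <- data.frame(phylo_norm = seq(0, 3, length.out = 60))
    coupled$net_dist <- coupled$phylo_norm + rnorm(60, sd = 0.05)
    bs <- binDistanceSummary(coupled, nBins = 4L)
    expect_true(all(diff(bs$median) > 0))
})

test_that("null networks show no phylogeny-network distance coupling", {
    # on rewired graphs the selection rate stays near alpha and bin medians
    # show no trend: regress bin median on bin index under the null
    spec <- syntheticSpec(seed = 6)
    fam <- synthFamily(spec)
    syn <- synthNetwork(spec, fam$plantedPairs)
    net <- removeHubs(syn$network, 300L)
    rg <- rewirePreservingDegree(net, seed = 11L)
    K <- diffusionKernel(rg)
    tab <- paralogPairTable(K, fam$msa, tree = fam$tree,
                            members = sprintf("FAM%02d", 1:16))
    bs <- binDistanceSummary(tab[tab$reachable, ], nBins = 4L)
    fit <- lm(median ~ bin, data = bs[bs$n > 0, ])
    ci <- confint(fit)["bin", ]
    expect_true(ci[1] <= 0 && ci[2] >= 0)
})
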