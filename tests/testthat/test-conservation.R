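test_that("NCBI-format matrix parsing round-trips BLOSUM45", {
    B <- defaultSubstitutionMatrix()
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# test matrix",
                 paste(c(" ", colnames(B)), collapse = " "),
                 vapply(rownames(B), function(r)
                     paste(c(r, B[r, ]), collapse = " "), character(1))), f)
    got <- readSubstitutionMatrix(f)
    expect_equal(got, B, ignore_attr = FALSE)
    expect_true(isSymmetric(got))
    expect_equal(got["W", "W"], B["W", "W"])

    writeLines(c("  A R", "A 1 2", "R 3 1"), f)
    expect_error(readSubstitutionMatrix(f), "asymmetric")
})

test_that("pair position scores honour gaps and matrix lookups", {
    msa <- c(r1 = "LAC", r2 = "LWC", r3 = "L-C")
    B <- defaultSubstitutionMatrix()
    expect_equal(pairPositionScore(msa, "r1", "r2", 1), B["L", "L"])
    expect_true(is.na(pairPositionScore(msa, "r1", "r3", 2)))
    expect_gt(pairPositionScore(msa, "r1", "r1", 2),   # A vs A
              pairPositionScore(msa, "r1", "r2", 2))   # A vs W
    bad <- c(r1 = "LUC", r2 = "LWC")
    expect_error(pairScoreMatrix(bad, rbind(c("r1", "r2"))), "U")
})

test_that("set conservation equals a brute-force per-column mean", {
    set.seed(21)
    aa <- c("A", "R", "N", "D", "C", "Q")
    msa <- setNames(replicate(6, paste(sample(aa, 10, TRUE), collapse = "")),
                    paste0("s", 1:6))
    pairs <- t(combn(names(msa), 2))
    B <- defaultSubstitutionMatrix()
    got <- setConservation(msa, pairs)
    m <- msaMatrix(msa)
    brute <- vapply(1:10, function(j) {
        mean(apply(pairs, 1, function(p) B[m[p[1], j], m[p[2], j]]))
    }, numeric(1))
    expect_equal(got$mean, brute, tolerance = 1e-12)

    # identical column: mean is that residue's diagonal score
    msa2 <- c(a = "WW", b = "WA", c = "WR")
    sc <- setConservation(msa2, t(combn(c("a", "b", "c"), 2)))
    expect_equal(sc$mean[1], B["W", "W"])
})

test_that("coverage below 50 percent flags a column unscored", {
    msa <- c(a = "A-", b = "A-", c = "AC", d = "AC")
    pairs <- rbind(c("a", "b"), c("c", "d"), c("a", "c"))
    sc <- setConservation(msa, pairs)
    expect_true(is.na(sc$mean[2]))       # only 1 of 3 pairs scorable
    expect_equal(sc$coverage[2], 1 / 3)
})

test_that("reference mapping skips gaps and round-trips all columns", {
    msa <- c(ref = "M-TE", other = "MATE")
    mp <- mapToReference(msa, "ref", 3)
    expect_equal(mp$label, "T2")
    expect_true(is.na(mapToReference(msa, "ref", 2)$label))

    set.seed(13)
    for (i in 1:10) {
        chars <- sample(c("A", "C", "-"), 30, TRUE, prob = c(.4, .4, .2))
        msa <- c(ref = paste(chars, collapse = ""))
        mp <- mapToReference(msa, "ref")
        got <- mp$position[!is.na(mp$position)]
        expect_equal(got, seq_len(sum(chars != "-")))
    }
})

test_that("self-comparison yields a flat differential profile", {
    set.seed(31)
    msa <- setNames(replicate(6, paste(sample(c("A", "R", "N", "D"), 8,
                                              TRUE), collapse = "")),
                    paste0("s", 1:6))
    allp <- t(combn(names(msa), 2))
    rsets <- sampleRandomPairs(allp, size = nrow(allp), nSets = 5, seed = 1)
    prof <- differentialProfile(msa, "s1", allp, rsets)
    expect_equal(profileTable(prof)$delta, rep(0, 8), tolerance = 1e-12)
})

test_that("delta is invariant to a constant shift of the matrix", {
    set.seed(32)
    msa <- setNames(replicate(8, paste(sample(c("A", "R", "N", "D", "C"),
                                              12, TRUE), collapse = "")),
                    paste0("s", 1:8))
    B <- defaultSubstitutionMatrix()
    setp <- rbind(c("s1", "s2"), c("s3", "s4"))
    rsets <- sampleRandomPairs(t(combn(names(msa), 2)), 2, 20, seed = 2)
    p1 <- profileTable(differentialProfile(msa, "s1", setp, rsets, mat = B))
    p2 <- profileTable(differentialProfile(msa, "s1", setp, rsets,
                                           mat = B + 7))
    expect_equal(p1$delta, p2$delta, tolerance = 1e-10)
    expect_equal(p1$c_set + 7, p2$c_set, tolerance = 1e-10)
})

test_that("planted conserved and variable columns are called with direction", {
    spec <- syntheticSpec(seed = 5, nConservedColumns = 3L,
                          nVariableColumns = 1L)
    fam <- synthFamily(spec)
    universe <- t(combn(names(fam$msa), 2))
    rsets <- sampleRandomPairs(universe, nrow(fam$plantedPairs), 100,
                               seed = 77L)
    prof <- differentialProfile(fam$msa, fam$reference, fam$plantedPairs,
                                rsets)
    sig <- significantPositions(prof, alpha = 0.01)
    # every planted conserved column is called, with the right direction
    expect_true(all(fam$conservedColumns$column %in%
                    sig$position[sig$direction == "conserved"]))
    # the planted variable column has a clearly negative delta; with 100
    # random sets the per-position two-sided null leaves roughly one
    # background position per profile at the minimum attainable p, so the
    # called set may carry a small excess beyond the planted columns
    ptv <- profileTable(prof)
    expect_lt(ptv$delta[ptv$column == fam$variableColumns], -2)
    expect_equal(ptv$direction[ptv$column == fam$variableColumns],
                 "variable")
    extra <- setdiff(sig$position,
                     c(fam$conservedColumns$column, fam$variableColumns))
    expect_lte(length(extra), 3)
    # the planted conserved columns carry the largest positive deltas
    pt <- profileTable(prof)
    topk <- pt$position[order(-pt$delta)][seq_len(3)]
    expect_setequal(topk, fam$conservedColumns$column)

    expect_equal(nrow(significantPositions(prof, alpha = 1)),
                 sum(!is.na(profileTable(prof)$p)))
    expect_warning(significantPositions(prof, alpha = 1e-4), "resolution")
})

test_that("planted columns are recovered with high power at 20 pairs", {
    hits <- 0L; total <- 0L
    for (s in 1:8) {
        spec <- syntheticSpec(seed = 200 + s, nFamily = 40L,
                              nPlanted = 20L, nConservedColumns = 8L)
        fam <- synthFamily(spec)
        universe <- t(combn(names(fam$msa), 2))
        rsets <- sampleRandomPairs(universe, nrow(fam$plantedPairs), 100,
                                   seed = 300 + s)
        prof <- differentialProfile(fam$msa, fam$reference,
                                    fam$plantedPairs, rsets)
        sig <- significantPositions(prof, alpha = 0.01)
        hits <- hits + sum(fam$conservedColumns$column %in%
                           sig$position[sig$direction == "conserved"])
        total <- total + nrow(fam$conservedColumns)
    }
    expect_gte(hits / total, 0.9)
})
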