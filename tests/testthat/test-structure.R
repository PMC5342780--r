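test_that("toy complex PDB text round-trips through the parser", {
    toy <- synthComplex(syntheticSpec(seed = 1))
    cx <- toy$structure
    at <- atomTable(cx)
    expect_setequal(unique(at$chain), c("A", "B"))
    expect_equal(sum(at$chain == "A"), 12)
    expect_equal(sum(at$chain == "B"), 3)
    expect_equal(rasChain(cx), "A")
    expect_true(all(at$radius > 0))

    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(toy$pdbText, f)
    expect_error(readComplexStructure(f, rasChain = "Z"), "'Z'")
})

test_that("alternate locations resolve to the highest occupancy", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
"ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
"ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70  0.00           C",
"ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
"END"), f)
    cx <- readComplexStructure(f, rasChain = "A")
    at <- atomTable(cx)
    expect_equal(nrow(at), 2)
    expect_equal(at$x[at$resno == 1], 5.0)   # the 0.70-occupancy copy
})

test_that("SASA matches analytic sphere areas", {
    lone <- data.frame(chain = "A", resno = 1L, resid = "ALA",
                       elety = "CA", element = "C", x = 0, y = 0, z = 0,
                       occupancy = 1, radius = 1.7)
    s <- computeSASA(lone)
    expect_equal(s$perAtom, 4 * pi * 3.1^2, tolerance = 0.01)

    # far apart: both atoms keep the full isolated area
    two <- rbind(lone, transform(lone, resno = 2L, x = 100))
    s2 <- computeSASA(two)
    expect_equal(s2$perAtom, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)

    # small atom buried at the centre of a large sphere
    buried <- rbind(transform(lone, radius = 0.4),
                    transform(lone, resno = 2L, radius = 8))
    expect_equal(computeSASA(buried)$perAtom[1], 0)
})

test_that("SASA agrees with the two-sphere overlap formula within 1%", {
    set.seed(17)
    for (i in 1:20) {
        r1 <- runif(1, 1.2, 2.0); r2 <- runif(1, 1.2, 2.0)
        # distances producing a genuine partial overlap of expanded spheres
        d <- runif(1, abs(r1 - r2) + 0.3, r1 + r2 + 2 * 1.4 - 0.3)
        atoms <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
                            elety = "CA", element = "C",
                            x = c(0, d), y = 0, z = 0, occupancy = 1,
                            radius = c(r1, r2))
        got <- computeSASA(atoms)$perAtom[1]
        want <- twoSphereSASA(r1 + 1.4, r2 + 1.4, d)
        expect_equal(got, want, tolerance = 0.01)
    }
})

test_that("interface residues are exactly the designed contacts", {
    spec <- syntheticSpec(seed = 1)
    toy <- synthComplex(spec)
    iface <- interfaceResidues(toy$structure, deltaThreshold = 1.0)
    expect_equal(interfacePositions(iface), toy$contacts)

    apart <- synthComplex(spec, apart = TRUE)
    expect_length(interfacePositions(interfaceResidues(apart$structure)), 0)

    # the partner chain loses surface too (contact is mutual)
    full <- computeSASA(toy$structure)
    alone <- computeSASA(toy$structure, chains = "B")
    expect_gt(sum(alone$perResidue$sasa) -
              sum(full$perResidue$sasa[full$perResidue$chain == "B"]), 0)

    # the threshold is strict: a residue exactly at it is excluded
    ds <- deltaSASA(iface)
    top <- max(ds)
    at_threshold <- interfaceResidues(toy$structure, deltaThreshold = top)
    expect_false(as.integer(names(which.max(ds))) %in%
                 interfacePositions(at_threshold))
})

test_that("complex clustering groups by superposed C-alpha RMSD", {
    spec <- syntheticSpec(seed = 2)
    a <- synthComplex(spec)$structure

    # a rigidly moved copy superposes to RMSD ~ 0 and joins the group
    b <- a
    th <- 0.7
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
    xyz <- as.matrix(b@atoms[, c("x", "y", "z")]) %*% R
    b@atoms$x <- xyz[, 1] + 11; b@atoms$y <- xyz[, 2] - 4
    b@atoms$z <- xyz[, 3] + 2
    b@atoms$resid[1] <- "GLY"   # break sequence identity so RMSD is used
    b@id <- "COPY"

    # a noisy copy (5 A coordinate noise) lands in its own group
    set.seed(9)
    c3 <- a
    c3@atoms$x <- c3@atoms$x + rnorm(nrow(c3@atoms), sd = 5)
    c3@atoms$resid[2] <- "GLY"   # sequence distinct from both a and b
    c3@id <- "NOISY"

    groups <- clusterComplexes(list(a, b, c3), cutoff = 1.0)
    members <- lapply(groups, function(g) g@members)
    expect_length(groups, 2)
    expect_true(any(vapply(members, function(m)
        setequal(m, c("TOY", "COPY")), logical(1))))
    expect_true(any(vapply(members, function(m)
        identical(m, "NOISY"), logical(1))))

    same <- clusterComplexes(list(a, b), cutoff = 1.0)
    expect_length(same, 1)
    expect_lt(max(same[[1]]@rmsd), 1e-6)
})
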