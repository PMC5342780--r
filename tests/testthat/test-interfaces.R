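# The curated complex interface lists and the 22 differential positions
# exercise the match / flanking / region logic end to end; expected values
# below are frozen under the package's reporting conventions (ratios as
# percentages truncated to one decimal).

test_that("per-complex overlap counts and ratios are reproduced", {
    m <- matchPositions(rasInterfaceTable(), dirpPositions()$label)
    bc <- matchByComplex(m)
    expected <- data.frame(
        id = c("1LFD", "1NVU", "1XD2", "1BKD", "3CF6", "1WQ1", "2UZI",
               "2VH5", "3DDC", "1HE8", "3KUC", "3KUD", "1K8R", "1C1Y",
               "1ZC3", "2A9K", "2C5L", "4DXA", "3T5G", "2BOV", "1UAD"),
        size = c(16L, 36L, 20L, 21L, 22L, 19L, 10L, 11L, 7L, 7L, 8L, 6L,
                 7L, 7L, 11L, 14L, 17L, 9L, 5L, 3L, 5L),
        matches = c(7L, 12L, 7L, 8L, 9L, 7L, 4L, 4L, 2L, 2L, 2L, 0L, 2L,
                    1L, 0L, 4L, 1L, 1L, 0L, 1L, 1L),
        ratio = c(43.7, 33.3, 35.0, 38.0, 40.9, 36.8, 40.0, 36.3, 28.5,
                  28.5, 25.0, 0.0, 28.5, 14.2, 0.0, 28.5, 5.8, 11.1, 0.0,
                  33.3, 20.0))
    got <- bc[match(expected$id, bc$id), ]
    expect_equal(got$interface_size, expected$size)
    expect_equal(got$matches, expected$matches)
    expect_equal(got$ratio_pct, expected$ratio)
})

test_that("per-position match counts rank the effector hot spots", {
    m <- matchPositions(rasInterfaceTable(), dirpPositions()$label)
    bp <- matchByPosition(m)
    counts <- setNames(bp$n_matches, bp$label)
    expect_equal(unname(counts[c("I36", "Y64", "D33", "P34")]),
                 c(14L, 9L, 8L, 8L))
    expect_equal(unname(counts[c("Y32", "A66", "Y71")]), c(5L, 5L, 5L))
    expect_equal(unname(counts[c("D54", "G60")]), c(4L, 4L))
    expect_equal(unname(counts[c("T20", "A59", "Q22")]), c(3L, 3L, 3L))
    expect_equal(unname(counts[c("G12", "V103", "I139")]), c(2L, 1L, 1L))
    expect_equal(unname(counts[c("T35", "R68", "T58", "F28", "G77",
                                 "E153", "C186")]), rep(0L, 7))
    # deterministic ordering: descending matches then position
    expect_equal(bp$label[1], "I36")
    expect_false(is.unsorted(-bp$n_matches))
})

test_that("the two match-table views agree on totals", {
    m <- matchPositions(rasInterfaceTable(), dirpPositions()$label)
    expect_equal(sum(matchByComplex(m)$matches),
                 sum(matchByPosition(m)$n_matches))

    empty <- matchPositions(rasInterfaceTable(), integer(0))
    expect_true(all(matchByComplex(empty)$matches == 0))

    tab <- rasInterfaceTable()[1, ]
    all_in <- matchPositions(tab, strsplit(tab$positions, ",")[[1]])
    expect_equal(matchByComplex(all_in)$ratio_pct, 100)
})

test_that("participation splits into 15 direct, 4 flanked, 3 unmatched", {
    fp <- flankingParticipation(rasInterfaceTable(), dirpPositions()$label)
    expect_equal(unname(table(fp$class)["direct"]), 15L)
    expect_equal(unname(table(fp$class)["flanked"]), 4L)
    expect_equal(unname(table(fp$class)["none"]), 3L)
    expect_equal(sort(fp$label[fp$class == "flanked"]),
                 sort(c("T35", "R68", "T58", "F28")))
    expect_equal(sort(fp$label[fp$class == "none"]),
                 sort(c("G77", "E153", "C186")))
    # shares: 15/22 direct, 19/22 participating
    expect_equal(round(100 * 15 / 22), 68)
    n_part <- sum(fp$class != "none")
    expect_equal(round(100 * n_part / nrow(fp)), 86)
})

test_that("flanking respects sequence bounds and the within-complex flag", {
    iface <- data.frame(id = "X", positions = "2,4")
    fp <- flankingParticipation(iface, c(1L, 3L))
    expect_equal(as.character(fp$class), c("none", "flanked"))
    # terminal residue: no i+1 in any interface, never flanked
    fp2 <- flankingParticipation(data.frame(id = "X", positions = "4"),
                                 c(5L))
    expect_equal(as.character(fp2$class), "none")
    # stricter variant: neighbours must share one complex
    split <- data.frame(id = c("X", "Y"), positions = c("2", "4"))
    fp3 <- flankingParticipation(split, 3L)
    fp4 <- flankingParticipation(split, 3L, withinComplex = TRUE)
    expect_equal(as.character(fp3$class), "flanked")
    expect_equal(as.character(fp4$class), "none")
})

test_that("functional-region assignment reproduces the canonical shares", {
    ra <- regionAssignment(dirpPositions()$label)
    pct <- setNames(ra$pct, ra$region)
    expect_equal(unname(pct["Switch I"]), 23)
    expect_equal(unname(pct["Switch II"]), 23)
    expect_equal(unname(pct["C-terminal HVR"]), 5)
    expect_equal(unname(pct["Nucleotide binding site"]), 27)
    expect_equal(unname(pct["Inert"]), 32)

    members <- setNames(strsplit(ra$members, ","), ra$region)
    expect_true("Y32" %in% members[["Switch I"]])
    expect_true("C186" %in% members[["C-terminal HVR"]])
    # T35 belongs to both Switch I and the nucleotide site
    expect_true("T35" %in% members[["Switch I"]])
    expect_true("T35" %in% members[["Nucleotide binding site"]])
    expect_setequal(members[["Inert"]],
                    c("T20", "Q22", "D54", "G77", "V103", "I139", "E153"))
})
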