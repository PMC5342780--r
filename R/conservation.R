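# Differential position conservation: per-column BLOSUM45 pair scores for a
# pair set, normalized against the whole-alignment background, with an
# empirical null from random pair sets of the same size.

#' Coerce an alignment to a character matrix
#'
#' Accepts a named character vector of equal-length gapped sequences or a
#' \pkg{Biostrings} \code{AAStringSet}/\code{AAMultipleAlignment}; returns a
#' rows-by-columns single-character matrix (uppercase).
#'
#' @param msa the alignment
#' @return character matrix with row names
#' @export
msaMatrix <- function(msa) {
    if (is.matrix(msa) && is.character(msa)) return(msa)
    if (methods::is(msa, "AAMultipleAlignment"))
        msa <- methods::as(msa, "AAStringSet")
    if (methods::is(msa, "XStringSet")) {
        seqs <- as.character(msa)
    } else if (is.character(msa)) {
        seqs <- msa
    } else stop("unsupported alignment representation")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("alignment rows must be named")
    if (length(unique(nchar(seqs))) != 1)
        stop("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
    m
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param file FASTA file of aligned (gapped) amino-acid sequences
#' @return named character vector of equal-length sequences
#' @export
readMSA <- function(file) {
    s <- Biostrings::readAAStringSet(file)
    out <- as.character(s)
    names(out) <- sub("\\s.*$", "", names(s))
    if (length(unique(nchar(out))) != 1)
        stop("sequences are not aligned (unequal lengths)")
    out
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix layout used for the BLOSUM/PAM series
#' ('#' comments, a header row of residue letters, one labelled row per
#' residue).  The matrix must be square and symmetric.
#'
#' @param file path to the matrix file
#' @return symmetric integer matrix with residue dimnames
#' @seealso \code{\link{defaultSubstitutionMatrix}}
#' @export
readSubstitutionMatrix <- function(file) {
    lines <- readLines(file)
    lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    if (length(lines) < 2) stop("not a substitution matrix")
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    labs <- vapply(rows, `[[`, character(1), 1L)
    vals <- lapply(rows, function(r) as.numeric(r[-1]))
    if (any(lengths(vals) != length(header)))
        stop("matrix rows do not match header width")
    M <- do.call(rbind, vals)
    dimnames(M) <- list(labs, header)
    if (!identical(sort(labs), sort(header)))
        stop("row and column residue labels differ")
    M <- M[header, header, drop = FALSE]
    if (any(M != t(M))) {
        bad <- which(M != t(M), arr.ind = TRUE)[1, ]
        stop(sprintf("matrix is asymmetric at (%s, %s)",
                     header[bad[1]], header[bad[2]]))
    }
    M
}

#' The BLOSUM45 substitution matrix
#'
#' BLOSUM45 scores substitutions between sequences of up to ~45 percent
#' identity and is therefore matched to the divergence regime of the
#' selected pairs.  Taken from \pkg{Biostrings}' shipped copy of the
#' canonical NCBI matrix.
#'
#' @return symmetric integer matrix
#' @export
defaultSubstitutionMatrix <- function() {
    e <- new.env()
    utils::data("BLOSUM45", package = "Biostrings", envir = e)
    e$BLOSUM45
}

# Validate that every non-gap symbol of the alignment is scorable.
checkAlphabet <- function(m, mat) {
    symbols <- setdiff(unique(as.vector(m)), "-")
    unknown <- setdiff(symbols, rownames(mat))
    if (length(unknown))
        stop("residue(s) absent from substitution matrix: ",
             paste(unknown, collapse = ", "))
}

#' Substitution score of one pair at one column
#'
#' Returns the matrix score of the two residues, or \code{NA} (not
#' scorable) when either sequence has a gap at that column.
#'
#' @param msa the alignment (see \code{\link{msaMatrix}})
#' @param a,b row identifiers
#' @param column column index
#' @param mat substitution matrix (default BLOSUM45)
#' @return numeric score or \code{NA}
#' @export
pairPositionScore <- function(msa, a, b, column,
                              mat = defaultSubstitutionMatrix()) {
    m <- msaMatrix(msa)
    ra <- m[a, column]; rb <- m[b, column]
    if (ra == "-" || rb == "-") return(NA_real_)
    for (r in c(ra, rb))
        if (!r %in% rownames(mat))
            stop(sprintf("residue '%s' absent from substitution matrix", r))
    mat[ra, rb]
}

#' Pair-by-column substitution score matrix
#'
#' The workhorse behind all conservation summaries: one row per pair, one
#' column per alignment column, \code{NA} where either member is gapped.
#' Computing it once lets every random pair set be scored by row subsetting.
#'
#' @param msa the alignment
#' @param pairs two-column matrix/data.frame of row identifiers
#' @param mat substitution matrix
#' @return numeric matrix (pairs x columns), rows named by pair key
#' @export
pairScoreMatrix <- function(msa, pairs, mat = defaultSubstitutionMatrix()) {
    m <- msaMatrix(msa)
    checkAlphabet(m, mat)
    pairs <- as.matrix(pairs)
    lut <- mat
    out <- matrix(NA_real_, nrow(pairs), ncol(m))
    for (i in seq_len(nrow(pairs))) {
        ra <- m[pairs[i, 1], ]; rb <- m[pairs[i, 2], ]
        ok <- ra != "-" & rb != "-"
        if (any(ok)) out[i, ok] <- lut[cbind(ra[ok], rb[ok])]
    }
    rownames(out) <- pairKey(pairs[, 1], pairs[, 2])
    out
}

#' Mean per-column conservation of a pair set
#'
#' Column means of the pair scores over the scorable (mutually ungapped)
#' pairs.  Columns where fewer than \code{minCoverage} of the pairs are
#' scorable are flagged unscored (\code{NA}).
#'
#' @param msa the alignment
#' @param pairs two-column matrix/data.frame of row identifiers
#' @param mat substitution matrix
#' @param minCoverage minimum scorable fraction (default 0.5)
#' @return data.frame (column, mean, coverage)
#' @export
setConservation <- function(msa, pairs, mat = defaultSubstitutionMatrix(),
                            minCoverage = 0.5) {
    if (NROW(pairs) == 0) stop("pair set is empty")
    S <- pairScoreMatrix(msa, pairs, mat)
    columnConservation(S, minCoverage)
}

# Column means + coverage from a precomputed pair-score matrix.
columnConservation <- function(S, minCoverage = 0.5) {
    cov <- colMeans(!is.na(S))
    mu <- suppressWarnings(colMeans(S, na.rm = TRUE))
    mu[cov < minCoverage | !is.finite(mu)] <- NA_real_
    data.frame(column = seq_len(ncol(S)), mean = mu, coverage = cov,
               row.names = NULL)
}

#' Map alignment columns to reference numbering
#'
#' Residue label of the reference (template) row at given columns, numbered
#' by counting only the reference's ungapped characters (e.g. \code{"Y32"}).
#' Columns where the reference is gapped are not mappable (\code{NA}).
#'
#' @param msa the alignment
#' @param reference identifier of the reference row
#' @param columns column indices (default: all)
#' @return data.frame (column, position, label)
#' @export
mapToReference <- function(msa, reference, columns = NULL) {
    m <- msaMatrix(msa)
    if (!reference %in% rownames(m))
        stop(sprintf("reference '%s' absent from alignment", reference))
    ref <- m[reference, ]
    if (is.null(columns)) columns <- seq_along(ref)
    pos <- cumsum(ref != "-")
    gap <- ref[columns] == "-"
    data.frame(
        column = columns,
        position = ifelse(gap, NA_integer_, pos[columns]),
        label = ifelse(gap, NA_character_,
                       paste0(ref[columns], pos[columns])),
        row.names = NULL)
}

#' Differential conservation profile
#'
#' For every column where the reference row is ungapped, computes the mean
#' pair score within the analysed set (C_set), the mean over all alignment
#' pairs (C_bg), their difference delta = C_set - C_bg, and a two-sided
#' empirical p-value of delta against the deltas of random pair sets of the
#' same size.  Positive delta marks positions specifically conserved in the
#' set; negative delta marks specifically variable ones.
#'
#' @param msa the alignment
#' @param reference identifier of the template row used for numbering
#' @param setPairs two-column matrix/data.frame: the pair set under test
#' @param randomSets list of pair sets from \code{\link{sampleRandomPairs}},
#'   each of the same size as \code{setPairs}
#' @param mat substitution matrix (default BLOSUM45)
#' @param minCoverage minimum scorable-pair fraction per column (default 0.5)
#' @param pooledNull use one pooled null across positions instead of the
#'   per-position null (default FALSE)
#' @return a \linkS4class{ConservationProfile}
#' @export
differentialProfile <- function(msa, reference, setPairs, randomSets,
                                mat = defaultSubstitutionMatrix(),
                                minCoverage = 0.5, pooledNull = FALSE) {
    m <- msaMatrix(msa)
    if (NROW(setPairs) == 0) stop("pair set is empty")
    if (length(randomSets) == 0) stop("no random sets supplied")
    ids <- rownames(m)
    allPairs <- t(utils::combn(ids, 2))
    S <- pairScoreMatrix(m, allPairs, mat)

    pick <- function(pairs) {
        key <- pairKey(as.character(pairs[[1]]), as.character(pairs[[2]]))
        miss <- setdiff(key, rownames(S))
        if (length(miss))
            stop("pair(s) not in alignment universe: ",
                 paste(miss, collapse = ", "))
        S[key, , drop = FALSE]
    }
    bg <- columnConservation(S, minCoverage = 0)
    setC <- columnConservation(pick(as.data.frame(setPairs)), minCoverage)
    delta <- setC$mean - bg$mean
    nullDelta <- do.call(rbind, lapply(randomSets, function(ps)
        columnConservation(pick(as.data.frame(ps)), minCoverage)$mean -
            bg$mean))

    map <- mapToReference(m, reference)
    keep <- which(!is.na(map$position))
    pvals <- vapply(keep, function(j) {
        if (is.na(delta[j])) return(NA_real_)
        nd <- if (pooledNull) as.vector(nullDelta) else nullDelta[, j]
        nd <- nd[is.finite(nd)]
        if (length(nd) == 0) return(NA_real_)
        (sum(abs(nd) >= abs(delta[j])) + 1) / (length(nd) + 1)
    }, numeric(1))

    prof <- data.frame(
        column = keep,
        position = map$position[keep],
        label = map$label[keep],
        c_set = setC$mean[keep],
        c_bg = bg$mean[keep],
        delta = delta[keep],
        p = pvals,
        direction = ifelse(is.na(delta[keep]), NA_character_,
                           ifelse(delta[keep] >= 0, "conserved", "variable")),
        coverage = setC$coverage[keep],
        row.names = NULL)
    new("ConservationProfile", profile = prof, reference = reference,
        nRandomSets = as.integer(length(randomSets)))
}

#' Significantly differential positions
#'
#' Positions with empirical p below \code{alpha}, in reference numbering,
#' with their conservation direction.  Warns when \code{alpha} is below the
#' resolution attainable with the number of random sets used
#' (min p = 1 / (nSets + 1)).
#'
#' @param profile a \linkS4class{ConservationProfile}
#' @param alpha per-position significance level (default 0.01)
#' @param adjust optional multiple-testing correction method passed to
#'   \code{p.adjust} (default \code{"none"}, mirroring per-position
#'   thresholds)
#' @return data.frame (position, label, delta, p, direction), ordered by
#'   position
#' @export
significantPositions <- function(profile, alpha = 0.01, adjust = "none") {
    stopifnot(is(profile, "ConservationProfile"))
    minp <- 1 / (profile@nRandomSets + 1)
    if (alpha < minp)
        warning(sprintf(
            "alpha = %g is below the attainable resolution (min p = %g)",
            alpha, minp))
    p <- profile@profile
    pv <- if (adjust == "none") p$p else stats::p.adjust(p$p, method = adjust)
    sel <- !is.na(pv) & (pv < alpha | alpha >= 1)  # alpha = 1: all scored
    out <- p[sel, c("position", "label", "delta", "p", "direction")]
    out <- out[order(out$position), ]
    rownames(out) <- NULL
    out
}

#' @rdname ConservationProfile-class
#' @export
setMethod("profileTable", "ConservationProfile", function(x) x@profile)

setMethod("show", "ConservationProfile", function(object) {
    p <- object@profile
    cat(sprintf(paste0("ConservationProfile: %d reference positions ",
                       "(reference %s, %d random sets)\n"),
                nrow(p), object@reference, object@nRandomSets))
})
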