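#' Pipeline configuration constructor
#'
#' @param identityMax maximum pairwise sequence identity (percent) for a
#'   divergent pair (default 45)
#' @param phyloNormMin optional normalized phylogenetic distance gate
#'   (default 1.7); only applied when \code{usePhyloGate = TRUE}, since the
#'   identity threshold is the operative divergence filter and the 1.7 value
#'   is its correlated distance-scale counterpart
#' @param closenessAlpha significance level of the network-closeness
#'   threshold (default 0.05)
#' @param conservationAlpha significance level for differential position
#'   conservation (default 0.01)
#' @param hubCutoff hub degree cutoff (default 300)
#' @param beta diffusion-kernel bandwidth (default 1)
#' @param lambda exponent of the phylogenetic normalization (default 1)
#' @param deltaSASAThreshold per-residue SASA-loss threshold in Angstrom^2
#'   defining interface membership (default 1)
#' @param nullReplicates rewired-network replicates (default 100)
#' @param nRandomSets random pair sets for the conservation null
#'   (default 100)
#' @param usePhyloGate also require phylo_norm >= phyloNormMin (default
#'   FALSE)
#' @return a \linkS4class{PipelineConfig}
#' @export
pipelineConfig <- function(identityMax = 45, phyloNormMin = 1.7,
                           closenessAlpha = 0.05, conservationAlpha = 0.01,
                           hubCutoff = 300L, beta = 1, lambda = 1,
                           deltaSASAThreshold = 1.0, nullReplicates = 100L,
                           nRandomSets = 100L, usePhyloGate = FALSE) {
    new("PipelineConfig", identityMax = identityMax,
        phyloNormMin = phyloNormMin, closenessAlpha = closenessAlpha,
        conservationAlpha = conservationAlpha,
        hubCutoff = as.integer(hubCutoff), beta = beta, lambda = lambda,
        deltaSASAThreshold = deltaSASAThreshold,
        nullReplicates = as.integer(nullReplicates),
        nRandomSets = as.integer(nRandomSets), usePhyloGate = usePhyloGate)
}

#' Pairwise sequence identity in an alignment
#'
#' 100 x (identical residues) / (columns where both rows are ungapped).
#'
#' @param msa named character vector of equal-length gapped sequences (or an
#'   \code{AAStringSet})
#' @param a,b row identifiers
#' @return identity percentage in [0, 100]
#' @export
pairwiseIdentity <- function(msa, a, b) {
    m <- msaMatrix(msa)
    if (!all(c(a, b) %in% rownames(m)))
        stop("sequence(s) absent from alignment")
    ra <- m[a, ]; rb <- m[b, ]
    both <- ra != "-" & rb != "-"
    if (!any(both))
        stop(sprintf("no mutually ungapped columns between %s and %s", a, b))
    100 * sum(ra[both] == rb[both]) / sum(both)
}

#' Candidate paralog-pair table
#'
#' Assembles, for every pair of alignment rows present in the analysis, the
#' quantities the selection operates on: pairwise identity, raw and
#' normalized phylogenetic distance (when a tree is given), kernel
#' similarity, network distance -ln(p), and reachability within the kernel's
#' connected component.
#'
#' @param K a \linkS4class{KernelMatrix} computed on the (hub-filtered)
#'   network
#' @param msa alignment of the family (named character vector or
#'   \code{AAStringSet})
#' @param tree optional \code{phylo} tree with the family members as leaves
#' @param lambda exponent for \code{\link{normalizePhylo}}
#' @param members identifiers to pair up (default: alignment rows)
#' @return data.frame with one row per unordered pair
#' @export
paralogPairTable <- function(K, msa, tree = NULL, lambda = 1,
                             members = NULL) {
    stopifnot(is(K, "KernelMatrix"))
    m <- msaMatrix(msa)
    if (is.null(members)) members <- rownames(m)
    members <- sort(members)
    if (length(members) < 2) stop("need at least two members")
    pn <- if (!is.null(tree))
        normalizePhylo(patristicDistances(tree), lambda = lambda)
    idx <- utils::combn(members, 2)
    dist <- kernelToDistance(K)
    out <- data.frame(id_a = idx[1, ], id_b = idx[2, ])
    out$identity_pct <- vapply(seq_len(ncol(idx)), function(i)
        pairwiseIdentity(msa, idx[1, i], idx[2, i]), numeric(1))
    if (!is.null(tree)) {
        out$phylo_raw <- phyloRaw(pn)[cbind(out$id_a, out$id_b)]
        out$phylo_norm <- phyloNorm(pn)[cbind(out$id_a, out$id_b)]
    } else {
        out$phylo_raw <- NA_real_
        out$phylo_norm <- NA_real_
    }
    Kv <- K@values
    reach <- out$id_a %in% rownames(Kv) & out$id_b %in% rownames(Kv)
    out$reachable <- reach
    out$similarity <- NA_real_
    out$net_dist <- NA_real_
    if (any(reach)) {
        ij <- cbind(out$id_a[reach], out$id_b[reach])
        out$similarity[reach] <- Kv[ij]
        out$net_dist[reach] <- networkDistance(dist)[ij]
    }
    out
}

#' Network-closeness similarity cutoff
#'
#' The (1 - alpha) empirical quantile (type-7, linear interpolation) of the
#' null similarity distribution from rewired networks.  Pairs whose observed
#' kernel similarity is at or above this cutoff are significantly closer in
#' the network than expected under the degree-preserving null.
#'
#' @param null a \linkS4class{NullEnsemble} or numeric vector
#' @param alpha significance level (default 0.05); \code{alpha = 0} gives
#'   the null maximum
#' @return the similarity cutoff
#' @export
closenessThreshold <- function(null, alpha = 0.05) {
    vals <- if (is(null, "NullEnsemble")) null@values else as.numeric(null)
    if (length(vals) == 0) stop("null ensemble is empty")
    stats::quantile(vals, probs = 1 - alpha, type = 7, names = FALSE)
}

#' Select divergent-but-interacting pairs
#'
#' A pair is selected iff its identity is at or below
#' \code{identityMax}, it is reachable in the kernel's component, and its
#' kernel similarity is at or above the closeness cutoff (the test is on the
#' similarity scale, not on -ln(p)).  With \code{usePhyloGate = TRUE} the
#' normalized phylogenetic distance must additionally reach
#' \code{phyloNormMin}.
#'
#' @param pairs data.frame from \code{\link{paralogPairTable}}
#' @param cutoff similarity cutoff from \code{\link{closenessThreshold}}
#' @param config a \linkS4class{PipelineConfig}
#' @param kernel,network provenance labels stored in the result
#' @return a \linkS4class{DIRPSet}
#' @export
selectDIRP <- function(pairs, cutoff, config = pipelineConfig(),
                       kernel = "diffusion", network = "network") {
    need <- c("id_a", "id_b", "identity_pct", "similarity", "reachable")
    if (!all(need %in% names(pairs)))
        stop("pair table must contain: ", paste(need, collapse = ", "))
    if (all(is.na(pairs$similarity)))
        stop("pair table carries no similarity values")
    sel <- pairs$identity_pct <= config@identityMax &
        pairs$reachable &
        !is.na(pairs$similarity) & pairs$similarity >= cutoff
    if (config@usePhyloGate)
        sel <- sel & !is.na(pairs$phylo_norm) &
            pairs$phylo_norm >= config@phyloNormMin
    pairs$selected <- sel
    new("DIRPSet", pairs = pairs, config = config, cutoff = cutoff,
        kernel = kernel, network = network)
}

#' @rdname DIRPSet-class
#' @export
setMethod("dirpPairs", "DIRPSet", function(x) x@pairs)

#' @rdname DIRPSet-class
#' @export
setMethod("dirpSelected", "DIRPSet", function(x)
    x@pairs[x@pairs$selected, c("id_a", "id_b")])

setMethod("show", "DIRPSet", function(object) {
    p <- object@pairs
    cat(sprintf(paste0("DIRPSet (%s kernel, %s): %d candidate pairs, ",
                       "%d divergent, %d selected\n"),
                object@kernel, object@network, nrow(p),
                sum(p$identity_pct <= object@config@identityMax),
                sum(p$selected)))
})

#' Selection accounting
#'
#' The pair-count bookkeeping of the selection: initial pairs, pairs past
#' the divergence boundary, selected pairs, and the percentage of selected
#' pairs relative to the initial count.
#'
#' @param x a \linkS4class{DIRPSet}
#' @param denominator \code{"initial"} (default) or \code{"divergent"}
#' @return one-row data.frame
#' @export
selectionCounts <- function(x, denominator = c("initial", "divergent")) {
    stopifnot(is(x, "DIRPSet"))
    denominator <- match.arg(denominator)
    p <- x@pairs
    ini <- nrow(p)
    div <- sum(p$identity_pct <= x@config@identityMax)
    sel <- sum(p$selected)
    den <- if (denominator == "initial") ini else div
    data.frame(initial = ini, divergent = div, selected = sel,
               pct = round(100 * sel / den))
}

#' Network-distance distributions by phylogenetic bin
#'
#' Cuts pairs into \code{nBins} equal-width bins of normalized phylogenetic
#' distance and returns the five-number summary of the network distance in
#' each bin (empty bins are flagged).
#'
#' @param pairs data.frame with \code{phylo_norm} and \code{net_dist}
#' @param nBins number of bins
#' @return data.frame (bin, lo, hi, n, min, q1, median, q3, max)
#' @export
binDistanceSummary <- function(pairs, nBins = 5L) {
    ok <- is.finite(pairs$phylo_norm) & is.finite(pairs$net_dist)
    x <- pairs$phylo_norm[ok]; y <- pairs$net_dist[ok]
    if (length(x) == 0) stop("no finite pairs to bin")
    br <- seq(min(x), max(x), length.out = nBins + 1)
    bin <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
    do.call(rbind, lapply(seq_len(nBins), function(b) {
        yy <- y[bin == b]
        if (length(yy) == 0)
            return(data.frame(bin = b, lo = br[b], hi = br[b + 1], n = 0L,
                              min = NA_real_, q1 = NA_real_,
                              median = NA_real_, q3 = NA_real_,
                              max = NA_real_))
        fv <- stats::fivenum(yy)
        data.frame(bin = b, lo = br[b], hi = br[b + 1], n = length(yy),
                   min = fv[1], q1 = fv[2], median = fv[3], q3 = fv[4],
                   max = fv[5])
    }))
}
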