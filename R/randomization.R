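# Null models: degree-preserving rewiring, random pair sets, empirical
# p-values.  All stochastic entry points take explicit seeds; replicate
# seeds are derived as seed + replicate index.

#' Degree-preserving network rewiring
#'
#' Randomly permutes the partners of each node while keeping every node's
#' degree, via double-edge swaps with rejection of swaps that would create
#' self-loops or duplicate edges (\code{igraph::keeping_degseq}).  The
#' default attempts 10 x |E| swaps.
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @param nSwaps number of attempted swaps (default \code{10 * ecount})
#' @param seed integer seed (mandatory for reproducibility)
#' @return a rewired \linkS4class{InteractionNetwork} with the same degree
#'   sequence
#' @export
rewirePreservingDegree <- function(net, nSwaps = NULL, seed = 1L) {
    stopifnot(is(net, "InteractionNetwork"))
    m <- igraph::ecount(net@graph)
    if (is.null(nSwaps)) nSwaps <- 10L * m
    if (nSwaps < 0) stop("nSwaps must be >= 0")
    if (m < 2 || nSwaps == 0) return(net)
    g <- withLocalSeed(seed, igraph::rewire(
        net@graph,
        igraph::keeping_degseq(loops = FALSE, niter = nSwaps)))
    new("InteractionNetwork", graph = g)
}

#' Empirical p-value against a null ensemble
#'
#' Permutation-standard add-one estimator p = (r + 1) / (n + 1), where r is
#' the number of null values at least as extreme as the observation (ties
#' count as extreme).  For \code{tail = "two_sided"} extremeness is the
#' absolute deviation from the null mean.
#'
#' @param observed a finite numeric value
#' @param null a \linkS4class{NullEnsemble} or numeric vector of null values
#' @param tail one of \code{"greater"}, \code{"less"}, \code{"two_sided"}
#' @return the empirical p-value in (0, 1]
#' @examples
#' empiricalPValue(101, 1:100, "greater")   # 1/101
#' @export
empiricalPValue <- function(observed, null,
                            tail = c("greater", "less", "two_sided")) {
    tail <- match.arg(tail)
    if (!is.finite(observed)) stop("observed value must be finite")
    vals <- if (is(null, "NullEnsemble")) null@values else as.numeric(null)
    if (length(vals) == 0) stop("null ensemble is empty")
    r <- switch(tail,
        greater = sum(vals >= observed),
        less = sum(vals <= observed),
        two_sided = {
            ctr <- mean(vals)
            sum(abs(vals - ctr) >= abs(observed - ctr))
        })
    (r + 1) / (length(vals) + 1)
}

#' Random sets of aligned pairs
#'
#' Draws \code{nSets} sets of exactly \code{size} distinct pairs from the
#' universe of aligned pairs, without replacement within each set (sets are
#' independent of one another).  Set k is drawn under seed \code{seed + k},
#' so individual sets are reproducible.
#'
#' @param universe two-column matrix/data.frame, one row per aligned pair
#' @param size pairs per set; must not exceed \code{nrow(universe)}
#' @param nSets number of sets
#' @param seed integer base seed
#' @return list of \code{nSets} data.frames with columns \code{id_a},
#'   \code{id_b}
#' @export
sampleRandomPairs <- function(universe, size, nSets = 100L, seed = 1L) {
    universe <- as.data.frame(universe)
    if (size > nrow(universe))
        stop("size exceeds the number of available pairs")
    lapply(seq_len(nSets), function(k) {
        idx <- withLocalSeed(seed + k,
                             sample.int(nrow(universe), size))
        out <- universe[idx, 1:2]
        names(out) <- c("id_a", "id_b")
        rownames(out) <- NULL
        out
    })
}

#' Null ensemble of kernel similarities on rewired networks
#'
#' Builds \code{nReplicates} degree-preserving rewirings of the network,
#' recomputes the requested kernel on each, and pools the similarity values
#' of the candidate pairs (pairs unreachable in a replicate are skipped).
#' This is the null distribution behind the network-closeness threshold.
#'
#' @param net an \linkS4class{InteractionNetwork} (post hub removal)
#' @param pairs two-column matrix/data.frame of candidate identifier pairs
#' @param kernel \code{"diffusion"} or \code{"commute_time"}
#' @param beta diffusion bandwidth (ignored for the commute-time kernel)
#' @param nReplicates number of rewired replicates (default 100)
#' @param seed integer base seed; replicate k uses \code{seed + k}
#' @return a \linkS4class{NullEnsemble} of pooled similarity values
#' @export
nullSimilarityEnsemble <- function(net, pairs,
                                   kernel = c("diffusion", "commute_time"),
                                   beta = 1, nReplicates = 100L, seed = 1L) {
    kernel <- match.arg(kernel)
    pairs <- as.matrix(pairs)
    vals <- unlist(lapply(seq_len(nReplicates), function(k) {
        rg <- rewirePreservingDegree(net, seed = seed + k)
        K <- if (kernel == "diffusion") diffusionKernel(rg, beta = beta)
             else commuteTimeKernel(rg)
        extractPairValues(K@values, pairs)
    }))
    new("NullEnsemble", values = as.numeric(vals),
        replicates = as.integer(nReplicates), seed = as.integer(seed))
}

# Values of a symmetric node matrix at given identifier pairs; pairs with a
# member absent from the matrix yield no value.
extractPairValues <- function(M, pairs) {
    ok <- pairs[, 1] %in% rownames(M) & pairs[, 2] %in% rownames(M)
    if (!any(ok)) return(numeric(0))
    M[cbind(pairs[ok, 1], pairs[ok, 2])]
}

#' @rdname NullEnsemble-class
#' @export
setMethod("nullValues", "NullEnsemble", function(x) x@values)

setMethod("show", "NullEnsemble", function(object) {
    cat(sprintf("NullEnsemble: %d values from %d replicates (seed %d)\n",
                length(object@values), object@replicates, object@seed))
})
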