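#' Run the full analysis end-to-end on a synthetic universe
#'
#' Orchestrates every stage in order — family simulation, interactome
#' simulation, hub removal, diffusion and commute-time kernels, rewired-
#' network null ensembles, divergent-but-interacting pair selection per
#' kernel, shared-partner statistics, differential conservation with random
#' pair sets, significant-position calling, and the toy-complex interface
#' stage — and returns all stage outputs plus a manifest of counts and
#' seeds.  Identical \code{spec}/\code{config}/\code{seed} give identical
#' outputs.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param config a \linkS4class{PipelineConfig}
#' @param seed overrides the spec seed when given
#' @return list with elements \code{family}, \code{network}, \code{kernels},
#'   \code{nulls}, \code{cutoffs}, \code{dirp} (per-kernel
#'   \linkS4class{DIRPSet}), \code{sharedPartners}, \code{profile},
#'   \code{significant}, \code{interface}, \code{manifest}
#' @export
runPipeline <- function(spec = syntheticSpec(), config = pipelineConfig(),
                        seed = NULL) {
    if (!is.null(seed)) spec@seed <- as.integer(seed)
    t0 <- Sys.time()

    fam <- synthFamily(spec)
    syn <- synthNetwork(spec, fam$plantedPairs)
    net <- removeHubs(syn$network, config@hubCutoff)

    kernels <- list(
        diffusion = diffusionKernel(net, beta = config@beta),
        commute_time = commuteTimeKernel(net))

    members <- familyIds(spec)
    memberPairs <- t(utils::combn(members, 2))
    nulls <- lapply(names(kernels), function(kn)
        nullSimilarityEnsemble(net, memberPairs, kernel = kn,
                               beta = config@beta,
                               nReplicates = config@nullReplicates,
                               seed = spec@seed + 3000L))
    names(nulls) <- names(kernels)
    cutoffs <- vapply(nulls, closenessThreshold,
                      alpha = config@closenessAlpha, numeric(1))

    dirp <- lapply(names(kernels), function(kn) {
        tab <- paralogPairTable(kernels[[kn]], fam$msa, tree = fam$tree,
                                lambda = config@lambda, members = members)
        selectDIRP(tab, cutoffs[[kn]], config, kernel = kn,
                   network = "synthetic")
    })
    names(dirp) <- names(kernels)

    sel <- dirpSelected(dirp$diffusion)
    shared <- if (nrow(sel) > 0) sharedPartnerStats(syn$network, sel)
              else list(counts = NULL, median = NA_real_)

    profile <- NULL
    signif <- NULL
    if (nrow(sel) > 0) {
        rsets <- sampleRandomPairs(as.data.frame(memberPairs),
                                   size = nrow(sel),
                                   nSets = config@nRandomSets,
                                   seed = spec@seed + 4000L)
        profile <- differentialProfile(fam$msa, fam$reference, sel, rsets)
        signif <- significantPositions(profile,
                                       alpha = config@conservationAlpha)
    }

    toy <- synthComplex(spec)
    iface <- interfaceResidues(toy$structure,
                               deltaThreshold = config@deltaSASAThreshold)

    manifest <- list(
        seed = spec@seed,
        stages = c("family", "network", "kernels", "null", "dirp",
                   "conservation", "interface"),
        counts = list(
            familyMembers = spec@nFamily,
            candidatePairs = nrow(memberPairs),
            plantedPairs = nrow(fam$plantedPairs),
            selectedDiffusion = sum(dirp$diffusion@pairs$selected),
            selectedCommute = sum(dirp$commute_time@pairs$selected),
            significantPositions = if (is.null(signif)) 0L
                                   else nrow(signif)),
        cutoffs = cutoffs,
        elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    list(family = fam, network = syn, kernels = kernels, nulls = nulls,
         cutoffs = cutoffs, dirp = dirp, sharedPartners = shared,
         profile = profile, significant = signif,
         interface = iface, toyComplex = toy, manifest = manifest)
}
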