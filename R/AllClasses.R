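#' @import methods
NULL

setOldClass("igraph")
setOldClass("phylo")

#' Undirected protein-protein interaction network
#'
#' Thin S4 wrapper around a simple undirected \pkg{igraph} graph whose
#' vertices are protein identifiers.  Validity enforces the invariants the
#' downstream kernels rely on: no self-loops, no duplicated edges, undirected.
#'
#' @slot graph an \pkg{igraph} object (simple, undirected, named vertices)
#' @exportClass InteractionNetwork
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    if (igraph::is_directed(g))
        return("graph must be undirected")
    if (!igraph::is_simple(g))
        return("graph must be simple (no self-loops or duplicate edges)")
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
        return("vertices must be named with protein identifiers")
    TRUE
})

#' Node-similarity kernel over the largest connected component
#'
#' Symmetric positive semi-definite similarity matrix from either the
#' Laplacian exponential diffusion kernel exp(-beta * L) or the commute-time
#' kernel (Moore-Penrose pseudo-inverse of L).  Rows/columns are ordered by
#' sorted identifier; nodes outside the largest connected component are kept
#' in \code{unreachable}.
#'
#' @slot values symmetric numeric matrix with identifier dimnames
#' @slot kernel \code{"diffusion"} or \code{"commute_time"}
#' @slot beta diffusion bandwidth (NA for the commute-time kernel)
#' @slot nEdges number of edges in the component the kernel was computed on
#' @slot unreachable identifiers outside the largest connected component
#' @exportClass KernelMatrix
setClass("KernelMatrix", representation(
    values = "matrix", kernel = "character", beta = "numeric",
    nEdges = "integer", unreachable = "character"))

setValidity("KernelMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("kernel matrix must be square")
    if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-8)
        return("kernel matrix must be symmetric")
    if (!object@kernel %in% c("diffusion", "commute_time"))
        return("kernel must be 'diffusion' or 'commute_time'")
    TRUE
})

#' Normalized association probabilities and -ln(p) network distances
#'
#' @slot p matrix of normalized association probabilities in (0, 1]
#' @slot d matrix of distances d = -ln(p), zero diagonal
#' @slot unreachable identifiers excluded from the component
#' @exportClass NetworkDistanceMatrix
setClass("NetworkDistanceMatrix", representation(
    p = "matrix", d = "matrix", unreachable = "character"))

setValidity("NetworkDistanceMatrix", function(object) {
    if (!identical(dim(object@p), dim(object@d)))
        return("p and d must have identical dimensions")
    if (nrow(object@p) > 0) {
        if (any(object@p <= 0) || any(object@p > 1 + 1e-9))
            return("p values must lie in (0, 1]")
        if (any(abs(diag(object@d)) > 1e-9))
            return("distance diagonal must be zero")
    }
    TRUE
})

#' Patristic (and exponentially normalized) phylogenetic distances
#'
#' @slot raw symmetric matrix of patristic distances (sum of branch lengths
#'   along the leaf-to-leaf path)
#' @slot norm normalized distances d' = exp(lambda * d) - 1 (empty until
#'   \code{normalizePhylo} is called)
#' @slot lambda scaling exponent used for \code{norm} (NA before normalization)
#' @exportClass PhyloDistanceMatrix
setClass("PhyloDistanceMatrix", representation(
    raw = "matrix", norm = "matrix", lambda = "numeric"))

#' Null ensemble of a statistic under a randomization model
#'
#' @slot values per-replicate (possibly pooled) statistic values
#' @slot replicates number of randomized replicates
#' @slot seed base seed the replicates were derived from
#' @exportClass NullEnsemble
setClass("NullEnsemble", representation(
    values = "numeric", replicates = "integer", seed = "integer"))

setValidity("NullEnsemble", function(object) {
    if (length(object@values) < 1) return("null ensemble must be non-empty")
    if (any(!is.finite(object@values))) return("null values must be finite")
    TRUE
})

#' Pipeline thresholds
#'
#' Holds the filtering constants of the divergent-but-interacting pair
#' analysis: the maximum pairwise sequence identity (45 percent), the optional
#' normalized phylogenetic distance gate (1.7), the network-closeness
#' significance level (0.05), the conservation significance level (0.01) and
#' the hub degree cutoff (300).
#'
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    identityMax = "numeric", phyloNormMin = "numeric",
    closenessAlpha = "numeric", conservationAlpha = "numeric",
    hubCutoff = "integer", beta = "numeric", lambda = "numeric",
    deltaSASAThreshold = "numeric", nullReplicates = "integer",
    nRandomSets = "integer", usePhyloGate = "logical"))

setValidity("PipelineConfig", function(object) {
    if (object@identityMax < 0 || object@identityMax > 100)
        return("identityMax must be a percentage in [0, 100]")
    if (object@closenessAlpha <= 0 || object@closenessAlpha > 1)
        return("closenessAlpha must lie in (0, 1]")
    if (object@conservationAlpha <= 0 || object@conservationAlpha > 1)
        return("conservationAlpha must lie in (0, 1]")
    if (object@hubCutoff < 1L) return("hubCutoff must be >= 1")
    if (object@beta < 0) return("beta must be >= 0")
    if (object@lambda <= 0) return("lambda must be > 0")
    TRUE
})

#' Selected set of divergent-but-interacting paralog pairs
#'
#' @slot pairs data.frame with one row per candidate pair (identity,
#'   phylogenetic distance, kernel similarity, network distance, reachability,
#'   selection flag)
#' @slot config the \linkS4class{PipelineConfig} used
#' @slot cutoff the similarity cutoff applied (1 - alpha null quantile)
#' @slot kernel which kernel the selection used
#' @slot network free-text provenance label of the network
#' @exportClass DIRPSet
setClass("DIRPSet", representation(
    pairs = "data.frame", config = "PipelineConfig", cutoff = "numeric",
    kernel = "character", network = "character"))

#' Per-position differential conservation profile
#'
#' One row per alignment column where the reference row is ungapped:
#' set mean BLOSUM score, background mean, their difference, empirical
#' p-value and direction.
#'
#' @slot profile data.frame (column, position, label, c_set, c_bg, delta,
#'   p, direction, coverage)
#' @slot reference identifier of the reference (template) row
#' @slot nRandomSets number of random pair sets behind the null
#' @exportClass ConservationProfile
setClass("ConservationProfile", representation(
    profile = "data.frame", reference = "character", nRandomSets = "integer"))

#' Protein complex structure (atom table view)
#'
#' @slot id complex identifier (e.g. a PDB code)
#' @slot atoms data.frame with columns chain, resno, resid, elety, element,
#'   x, y, z, occupancy, radius (van der Waals, Angstrom)
#' @slot rasChain chain identifier of the Ras-family chain
#' @exportClass ComplexStructure
setClass("ComplexStructure", representation(
    id = "character", atoms = "data.frame", rasChain = "character"))

setValidity("ComplexStructure", function(object) {
    need <- c("chain", "resno", "resid", "elety", "element",
              "x", "y", "z", "occupancy", "radius")
    if (!all(need %in% names(object@atoms)))
        return(paste("atom table must contain columns:",
                     paste(need, collapse = ", ")))
    if (nrow(object@atoms) > 0) {
        if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
            return("coordinates must be finite")
        if (any(object@atoms$radius <= 0)) return("radii must be > 0")
        if (!object@rasChain %in% object@atoms$chain)
            return(sprintf("ras chain '%s' absent from structure",
                           object@rasChain))
    }
    TRUE
})

#' Structural group of complexes (RMSD clustering)
#'
#' @slot members complex identifiers in the group
#' @slot representative identifier of the representative member
#' @slot rmsd within-group pairwise C-alpha RMSD matrix (Angstrom)
#' @exportClass FunctionalGroup
setClass("FunctionalGroup", representation(
    members = "character", representative = "character", rmsd = "matrix"))

#' Binding interface of the Ras chain in one complex
#'
#' Residues whose solvent-accessible surface area drops by more than the
#' threshold between the unbound chain and the full complex.
#'
#' @slot id complex/group identifier
#' @slot positions residue numbers in the interface (reference numbering)
#' @slot deltaSASA named per-residue SASA loss (Angstrom^2) for all residues
#' @slot threshold the SASA-loss threshold applied (strict >)
#' @exportClass InterfaceRegion
setClass("InterfaceRegion", representation(
    id = "character", positions = "integer", deltaSASA = "numeric",
    threshold = "numeric"))

#' Overlap of query positions with complex interfaces
#'
#' The machine twin of the per-complex / per-position binding-site overlap
#' tables: one view per complex (matches among its interface residues, ratio)
#' and one per query position (how many complexes include it).
#'
#' @slot byComplex data.frame (id, interface_size, matches, ratio_pct,
#'   matched)
#' @slot byPosition data.frame (label, position, n_matches, complexes)
#' @exportClass MatchTable
setClass("MatchTable", representation(
    byComplex = "data.frame", byPosition = "data.frame"))

setValidity("MatchTable", function(object) {
    if (nrow(object@byComplex) > 0 &&
        sum(object@byComplex$matches) != sum(object@byPosition$n_matches))
        return("per-complex and per-position match totals disagree")
    TRUE
})

#' Specification for the synthetic test universe
#'
#' Describes the generated interactome (preferential-attachment background
#' with planted shared-partner paralog pairs), the simulated family
#' alignment/tree (planted columns conserved only within the planted pairs),
#' and the toy two-chain complex geometry.
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec", representation(
    seed = "integer", nBackground = "integer", paPower = "numeric",
    paEdges = "integer", nFamily = "integer", nPlanted = "integer",
    nSharedPartners = "integer", privatePartners = "integer",
    msaLength = "integer", nConservedColumns = "integer",
    nVariableColumns = "integer", noiseRate = "numeric",
    peptideLength = "integer", contactResidues = "integer",
    contactDistance = "numeric"))

setValidity("SyntheticSpec", function(object) {
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed is mandatory")
    if (2L * object@nPlanted > object@nFamily)
        return("planted pairs must be disjoint: need nFamily >= 2 * nPlanted")
    if (object@nConservedColumns + object@nVariableColumns > object@msaLength)
        return("planted columns exceed alignment length")
    if (any(object@contactResidues < 1L) ||
        any(object@contactResidues > object@peptideLength))
        return("contact residues must lie within the peptide")
    if (object@noiseRate < 0) return("noiseRate must be >= 0")
    TRUE
})
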