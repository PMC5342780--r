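#' Parse a Newick tree
#'
#' Wraps \code{ape::read.tree} with the validation the distance pipeline
#' needs: every branch must carry a length, branch lengths must be
#' non-negative (zero is allowed) and leaf labels must be unique.
#'
#' @param x a file path or a Newick string
#' @return an \pkg{ape} \code{phylo} object
#' @examples
#' tr <- readPhyloTree("(A:1,B:2);")
#' @export
readPhyloTree <- function(x) {
    tree <- tryCatch({
        if (length(x) == 1 && file.exists(x)) ape::read.tree(x)
        else ape::read.tree(text = x)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tree) || !inherits(tree, "phylo"))
        stop("not a valid Newick tree")
    if (is.null(tree$edge.length) || anyNA(tree$edge.length))
        stop("tree is missing branch lengths")
    if (any(tree$edge.length < 0))
        stop("negative branch lengths are not allowed")
    if (anyDuplicated(tree$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    tree
}

#' Patristic distance matrix
#'
#' Pairwise leaf-to-leaf distances as the sum of branch lengths along the
#' unique path in the tree, ordered by sorted leaf label.
#'
#' @param tree a \code{phylo} object (see \code{\link{readPhyloTree}})
#' @return a \linkS4class{PhyloDistanceMatrix} with the raw distances filled
#' @export
patristicDistances <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    d <- stats::cophenetic(tree)
    ord <- order(rownames(d))
    d <- d[ord, ord, drop = FALSE]
    new("PhyloDistanceMatrix", raw = d,
        norm = matrix(numeric(0), 0, 0), lambda = NA_real_)
}

#' Exponential normalization of phylogenetic distances
#'
#' Applies d' = exp(lambda * d) - 1, the strictly increasing rescaling used
#' to bring tree distances onto a scale comparable with -ln(p) network
#' distances (d = 0 maps to d' = 0).
#'
#' @param dm a \linkS4class{PhyloDistanceMatrix}
#' @param lambda positive scaling exponent (default 1)
#' @return the input object with the \code{norm} slot filled
#' @export
normalizePhylo <- function(dm, lambda = 1) {
    stopifnot(is(dm, "PhyloDistanceMatrix"))
    if (lambda <= 0) stop("lambda must be > 0")
    norm <- exp(lambda * dm@raw) - 1
    diag(norm) <- 0
    new("PhyloDistanceMatrix", raw = dm@raw, norm = norm, lambda = lambda)
}

#' @rdname PhyloDistanceMatrix-class
#' @export
setMethod("phyloRaw", "PhyloDistanceMatrix", function(x) x@raw)

#' @rdname PhyloDistanceMatrix-class
#' @export
setMethod("phyloNorm", "PhyloDistanceMatrix", function(x) {
    if (length(x@norm) == 0)
        stop("distances have not been normalized; call normalizePhylo()")
    x@norm
})

setMethod("show", "PhyloDistanceMatrix", function(object) {
    cat(sprintf("PhyloDistanceMatrix: %d leaves%s\n", nrow(object@raw),
                if (length(object@norm))
                    sprintf(", normalized (lambda = %g)", object@lambda)
                else ""))
})
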