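# Graph kernels on the largest connected component.
#
# Both kernels are computed from the spectral decomposition of the dense
# combinatorial Laplacian L = D - A, which keeps K exactly symmetric and
# positive semi-definite at the scales this package targets.  Node order is
# fixed (lexicographic) before any linear algebra for bit-stable output.

# Laplacian of the largest component, nodes sorted lexicographically.
componentLaplacian <- function(net) {
    nodes <- largestComponentNodes(net)
    if (length(nodes) == 0) stop("network is empty")
    sub <- igraph::induced_subgraph(net@graph, nodes)
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    A <- A[nodes, nodes, drop = FALSE]
    L <- diag(rowSums(A), nrow = length(nodes)) - A
    dimnames(L) <- list(nodes, nodes)
    list(L = L, nodes = nodes,
         nEdges = igraph::ecount(sub),
         unreachable = setdiff(networkNodes(net), nodes))
}

#' Laplacian exponential diffusion kernel
#'
#' Computes K = exp(-beta * L) on the largest connected component of the
#' network, where L = D - A is the combinatorial Laplacian.  K_ij measures
#' how much "heat" injected at node i reaches node j; beta sets the
#' diffusion bandwidth (beta = 0 yields the identity, large beta the flat
#' component average).
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @param beta non-negative diffusion bandwidth (default 1)
#' @return a \linkS4class{KernelMatrix}
#' @examples
#' net <- interactionNetwork(rbind(c("a", "b")))
#' kernelValues(diffusionKernel(net, beta = 1))
#' @export
diffusionKernel <- function(net, beta = 1) {
    stopifnot(is(net, "InteractionNetwork"), beta >= 0)
    cl <- componentLaplacian(net)
    e <- eigen(cl$L, symmetric = TRUE)
    K <- e$vectors %*% (exp(-beta * e$values) * t(e$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(cl$nodes, cl$nodes)
    new("KernelMatrix", values = K, kernel = "diffusion", beta = beta,
        nEdges = as.integer(cl$nEdges), unreachable = cl$unreachable)
}

#' Commute-time kernel
#'
#' The Moore-Penrose pseudo-inverse L+ of the Laplacian, computed on the
#' largest connected component.  L+ is the Gram matrix of a Euclidean
#' embedding of the graph whose squared distances are proportional to
#' random-walk commute times: C(i, j) = 2m (L+_ii + L+_jj - 2 L+_ij), with m
#' the edge count (see \code{\link{commuteTimes}}).
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @return a \linkS4class{KernelMatrix}
#' @export
commuteTimeKernel <- function(net) {
    stopifnot(is(net, "InteractionNetwork"))
    cl <- componentLaplacian(net)
    if (cl$nEdges == 0) stop("kernel undefined: graph has no edges")
    e <- eigen(cl$L, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-10
    inv <- ifelse(e$values > tol, 1 / e$values, 0)
    K <- e$vectors %*% (inv * t(e$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(cl$nodes, cl$nodes)
    new("KernelMatrix", values = K, kernel = "commute_time", beta = NA_real_,
        nEdges = as.integer(cl$nEdges), unreachable = cl$unreachable)
}

#' Commute times from a commute-time kernel
#'
#' C(i, j) = 2m (L+_ii + L+_jj - 2 L+_ij): the expected number of steps of a
#' random walk from i to j and back.  C / 2m is the effective resistance.
#'
#' @param K a commute-time \linkS4class{KernelMatrix}
#' @return symmetric matrix of commute times
#' @export
commuteTimes <- function(K) {
    stopifnot(is(K, "KernelMatrix"))
    if (K@kernel != "commute_time")
        stop("commute times are defined for the commute-time kernel only")
    v <- K@values
    d <- diag(v)
    C <- 2 * K@nEdges * (outer(d, rep(1, length(d))) +
                         outer(rep(1, length(d)), d) - 2 * v)
    C[C < 0] <- 0  # clip numerical negatives on the diagonal scale
    dimnames(C) <- dimnames(v)
    C
}

#' Convert kernel similarities to network distances
#'
#' Normalizes kernel values to association probabilities with the cosine
#' form p_ij = K_ij / sqrt(K_ii K_jj) (guaranteeing p in (0, 1] for a PSD
#' kernel with positive diagonal, and p_ii = 1), then transforms them to
#' distances d = -ln(p).  Non-positive kernel entries, possible for the
#' pseudo-inverse kernel, are floored at \code{eps} before the logarithm and
#' are therefore effectively infinitely distant.
#'
#' @param K a \linkS4class{KernelMatrix}
#' @param eps floor applied to p before the logarithm (default 1e-12)
#' @return a \linkS4class{NetworkDistanceMatrix}
#' @export
kernelToDistance <- function(K, eps = 1e-12) {
    stopifnot(is(K, "KernelMatrix"))
    v <- K@values
    dg <- diag(v)
    if (any(dg <= 0))
        stop("kernel diagonal must be strictly positive")
    p <- v / sqrt(outer(dg, dg))
    p <- pmin(p, 1)       # guard against roundoff above Cauchy-Schwarz
    p[p < eps] <- eps
    d <- -log(p)
    diag(p) <- 1
    diag(d) <- 0
    new("NetworkDistanceMatrix", p = p, d = d, unreachable = K@unreachable)
}

#' @rdname KernelMatrix-class
#' @export
setMethod("kernelValues", "KernelMatrix", function(x) x@values)

#' @rdname KernelMatrix-class
#' @export
setMethod("kernelType", "KernelMatrix", function(x) x@kernel)

#' @rdname KernelMatrix-class
#' @export
setMethod("unreachableNodes", "KernelMatrix", function(x) x@unreachable)

#' @rdname NetworkDistanceMatrix-class
#' @export
setMethod("associationProb", "NetworkDistanceMatrix", function(x) x@p)

#' @rdname NetworkDistanceMatrix-class
#' @export
setMethod("networkDistance", "NetworkDistanceMatrix", function(x) x@d)

#' @rdname NetworkDistanceMatrix-class
#' @export
setMethod("unreachableNodes", "NetworkDistanceMatrix",
          function(x) x@unreachable)

setMethod("show", "KernelMatrix", function(object) {
    cat(sprintf("KernelMatrix (%s%s): %d x %d nodes, %d unreachable\n",
                object@kernel,
                if (object@kernel == "diffusion")
                    sprintf(", beta = %g", object@beta) else "",
                nrow(object@values), ncol(object@values),
                length(object@unreachable)))
})
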