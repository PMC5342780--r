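#' Build an interaction network from an edge table
#'
#' Constructs a simple undirected \linkS4class{InteractionNetwork} from a
#' two-column table of protein identifier pairs.  Self-loops are dropped with
#' a warning and duplicate edges (in either orientation) are collapsed.
#'
#' @param edges two-column character matrix or data.frame of identifier pairs
#' @return an \linkS4class{InteractionNetwork}
#' @examples
#' net <- interactionNetwork(rbind(c("A", "B"), c("B", "C"), c("A", "B")))
#' networkNodes(net)
#' @export
interactionNetwork <- function(edges) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2)
        stop("edge table must have at least two columns")
    a <- as.character(edges[, 1])
    b <- as.character(edges[, 2])
    if (any(!nzchar(a)) || any(!nzchar(b)))
        stop("identifiers must be non-empty")
    loops <- a == b
    if (any(loops)) {
        warning(sprintf("dropping %d self-loop(s)", sum(loops)))
        a <- a[!loops]; b <- b[!loops]
    }
    keep <- !duplicated(pairKey(a, b))
    g <- igraph::graph_from_data_frame(
        data.frame(from = a[keep], to = b[keep]), directed = FALSE)
    new("InteractionNetwork", graph = g)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a tab-separated edge list (two identifier columns, optional third
#' evidence-type column).  When \code{evidenceFilter} is given, only rows
#' whose evidence column matches the pattern (e.g. \code{"physical"}) are
#' kept, as when restricting MITAB-like exports to direct physical
#' interactions.
#'
#' @param file path to a TSV edge list
#' @param evidenceFilter optional regular expression applied to column 3
#' @param comment.char lines starting with this character are skipped
#' @return an \linkS4class{InteractionNetwork}
#' @export
readInteractionNetwork <- function(file, evidenceFilter = NULL,
                                   comment.char = "#") {
    lines <- readLines(file)
    keep <- nzchar(trimws(lines)) &
        !startsWith(trimws(lines), comment.char)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    bad <- vapply(fields, function(f) length(f) < 2 ||
                      !nzchar(f[[1]]) || !nzchar(f[[2]]), logical(1))
    if (any(bad))
        stop(sprintf("malformed edge record at line %d of '%s'",
                     lineno[which(bad)[1]], file))
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
    if (!is.null(evidenceFilter)) {
        ev <- vapply(fields, function(f)
            if (length(f) >= 3) f[[3]] else "", character(1))
        sel <- grepl(evidenceFilter, ev)
        a <- a[sel]; b <- b[sel]
    }
    interactionNetwork(cbind(a, b))
}

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x)
    sort(igraph::V(x@graph)$name))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) {
    e <- igraph::as_edgelist(x@graph)
    colnames(e) <- c("a", "b")
    e
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("nodeDegree", "InteractionNetwork", function(x) {
    d <- igraph::degree(x@graph)
    d[order(names(d))]
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
                igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

#' Extract the underlying igraph object
#' @param x an \linkS4class{InteractionNetwork}
#' @return an \pkg{igraph} graph
#' @export
asIgraph <- function(x) {
    stopifnot(is(x, "InteractionNetwork"))
    x@graph
}

#' Remove network hubs
#'
#' Deletes, in a single pass on the input degrees, every node whose degree is
#' greater than or equal to \code{cutoff} (default 300), together with its
#' incident edges.  Highly connected hubs introduce nonspecific shortcuts
#' that distort kernel-based distances.
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @param cutoff integer degree threshold; nodes with degree >= cutoff are
#'   removed
#' @return the filtered \linkS4class{InteractionNetwork}
#' @export
removeHubs <- function(net, cutoff = 300L) {
    stopifnot(is(net, "InteractionNetwork"), cutoff >= 1)
    d <- igraph::degree(net@graph)
    hubs <- names(d)[d >= cutoff]
    new("InteractionNetwork",
        graph = igraph::delete_vertices(net@graph, hubs))
}

# Largest connected component as a sorted identifier vector (deterministic:
# ties broken toward the component containing the smallest identifier).
largestComponentNodes <- function(net) {
    g <- net@graph
    if (igraph::vcount(g) == 0) return(character(0))
    comp <- igraph::components(g)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1) {
        firsts <- vapply(best, function(k)
            min(igraph::V(g)$name[comp$membership == k]), character(1))
        best <- best[order(firsts)][1]
    }
    sort(igraph::V(g)$name[comp$membership == best[1]])
}

#' Shared interaction partners of node pairs
#'
#' For each pair (a, b) counts the common neighbors |N(a) n N(b)|, excluding
#' a and b themselves, and reports the set-level median.  Divergent pairs
#' that remain close in the interactome tend to share partners, unlike
#' matched control pairs.
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @param pairs two-column matrix/data.frame of identifier pairs
#' @return list with \code{counts} (per-pair data.frame) and \code{median}
#' @export
sharedPartnerStats <- function(net, pairs) {
    stopifnot(is(net, "InteractionNetwork"))
    pairs <- as.matrix(pairs)
    g <- net@graph
    ids <- igraph::V(g)$name
    missing <- setdiff(unique(c(pairs[, 1], pairs[, 2])), ids)
    if (length(missing))
        stop("node(s) absent from network: ", paste(missing, collapse = ", "))
    n <- vapply(seq_len(nrow(pairs)), function(i) {
        a <- pairs[i, 1]; b <- pairs[i, 2]
        na <- igraph::neighbors(g, a)$name
        nb <- igraph::neighbors(g, b)$name
        length(setdiff(intersect(na, nb), c(a, b)))
    }, integer(1))
    list(counts = data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                             shared = n, row.names = NULL),
         median = stats::median(n))
}
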