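# Independent oracles and fixture builders used across the suite.  These
# deliberately avoid the code paths they check (e.g. the walk simulator
# never touches the Laplacian pseudo-inverse).

# Monte-Carlo commute time: mean round-trip step count of a simple random
# walk i -> j -> i.  Returns the estimate and its standard error.
walkCommuteTime <- function(adjList, i, j, nWalks = 1500) {
    times <- vapply(seq_len(nWalks), function(w) {
        steps <- 0L
        cur <- i
        target <- j
        repeat {
            nb <- adjList[[cur]]
            cur <- nb[sample.int(length(nb), 1L)]
            steps <- steps + 1L
            if (cur == target) {
                if (target == i) break
                target <- i
            }
        }
        steps
    }, numeric(1))
    list(mean = mean(times), se = stats::sd(times) / sqrt(nWalks))
}

adjacencyList <- function(edgeMat, nodes) {
    lapply(nodes, function(v) {
        nb <- c(edgeMat[edgeMat[, 1] == v, 2], edgeMat[edgeMat[, 2] == v, 1])
        match(nb, nodes)
    })
}

# Patristic oracle independent of ape's cophenetic: walk the tree as a
# weighted graph and sum branch lengths along shortest paths.
patristicByGraph <- function(tree) {
    n <- length(tree$tip.label)
    edges <- tree$edge
    g <- igraph::make_graph(t(edges), directed = FALSE)
    igraph::E(g)$weight <- tree$edge.length
    d <- igraph::distances(g)[seq_len(n), seq_len(n)]
    dimnames(d) <- list(tree$tip.label, tree$tip.label)
    ord <- order(rownames(d))
    d[ord, ord]
}

# Analytic SASA of a sphere of expanded radius r occluded by one neighbour
# sphere of expanded radius rb at centre distance d (spherical-cap formula).
twoSphereSASA <- function(r, rb, d) {
    if (d >= r + rb) return(4 * pi * r^2)
    if (d + r <= rb) return(0)
    a <- (d^2 + r^2 - rb^2) / (2 * d)
    h <- r - a
    4 * pi * r^2 - 2 * pi * r * h
}

# Random connected simple graph with n nodes (named letters).
randomConnectedGraph <- function(n, p = 0.5) {
    repeat {
        g <- igraph::sample_gnp(n, p)
        if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    interactionNetwork(igraph::as_edgelist(g))
}

# A small null family alignment (no planted columns) for calibration runs.
nullFamilySpec <- function(seed) {
    syntheticSpec(seed = seed, nFamily = 12L, nPlanted = 2L,
                  msaLength = 40L, nConservedColumns = 0L,
                  nVariableColumns = 0L)
}

pk <- function(d) dirpscan:::pairKey(as.character(d[[1]]),
                                     as.character(d[[2]]))
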