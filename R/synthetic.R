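# Synthetic test universe with known ground truth: a scale-free-ish
# interactome with planted shared-partner paralog pairs, a simulated family
# alignment/tree with planted conserved columns, and toy two-chain
# complexes with geometrically known contact residues.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a synthetic-data specification
#'
#' The defaults define the study conditions of the simulation suite: a
#' 300-node preferential-attachment background interactome; a 16-member
#' duplicated family in which 5 disjoint, phylogenetically distant pairs are
#' planted with 3 dedicated shared partners each (every member also gets 3
#' private partners); a 180-column gapless alignment evolved down a random
#' tree under a per-site uniform substitution process at rate 0.5
#' substitutions per unit branch length, with 8 planted columns conserved
#' within each planted pair (pairs match internally but differ from one
#' another, so the alignment background stays variable) and 1
#' background-conserved column made discordant within the planted pairs;
#' and a 12-residue peptide probed by a partner peptide contacting residues
#' 5-7 at 5.5 Angstrom.
#'
#' @param seed mandatory integer seed
#' @param nBackground background interactome size
#' @param paPower,paEdges preferential-attachment exponent and edges per
#'   added node
#' @param nFamily number of family members
#' @param nPlanted number of planted divergent-but-interacting pairs
#' @param nSharedPartners dedicated shared partners per planted pair
#' @param privatePartners private background partners per family member
#' @param msaLength alignment length (columns)
#' @param nConservedColumns planted pair-specific conserved columns
#' @param nVariableColumns planted pair-specific variable columns
#' @param noiseRate substitutions per site per unit branch length
#' @param peptideLength toy-complex Ras-like peptide length
#' @param contactResidues designed contact residues of the toy complex
#' @param contactDistance inter-chain contact distance (Angstrom)
#' @return a \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(seed = 1L, nBackground = 300L, paPower = 1,
                          paEdges = 2L, nFamily = 16L, nPlanted = 5L,
                          nSharedPartners = 3L, privatePartners = 3L,
                          msaLength = 180L, nConservedColumns = 8L,
                          nVariableColumns = 1L, noiseRate = 0.5,
                          peptideLength = 12L, contactResidues = 5:7,
                          contactDistance = 5.5) {
    new("SyntheticSpec", seed = as.integer(seed),
        nBackground = as.integer(nBackground), paPower = paPower,
        paEdges = as.integer(paEdges), nFamily = as.integer(nFamily),
        nPlanted = as.integer(nPlanted),
        nSharedPartners = as.integer(nSharedPartners),
        privatePartners = as.integer(privatePartners),
        msaLength = as.integer(msaLength),
        nConservedColumns = as.integer(nConservedColumns),
        nVariableColumns = as.integer(nVariableColumns),
        noiseRate = noiseRate, peptideLength = as.integer(peptideLength),
        contactResidues = as.integer(contactResidues),
        contactDistance = contactDistance)
}

familyIds <- function(spec) sprintf("FAM%02d", seq_len(spec@nFamily))

#' Simulate the family alignment and tree
#'
#' Draws a random tree over the family, evolves a root sequence down it
#' under a per-site uniform substitution process (substitution probability
#' 1 - exp(-rate * branch length) per site per branch), then plants the
#' ground truth: disjoint maximally divergent pairs; conserved columns
#' where every planted pair is internally invariant (each pair carries its
#' own residue, so the column stays variable across the family); and
#' background-conserved columns where the two members of each planted pair
#' are set to a strongly mismatching residue pair (specifically variable in
#' the planted set).  Pairwise identity decreases with patristic distance
#' by construction.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @return list with \code{msa} (named character), \code{tree}
#'   (\code{phylo}), \code{reference} (template row id),
#'   \code{plantedPairs} (data.frame id_a, id_b),
#'   \code{conservedColumns} (data.frame column, residues; one residue per
#'   planted pair, slash-separated), \code{variableColumns} (integer
#'   vector)
#' @export
synthFamily <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    withLocalSeed(spec@seed + 1000L, {
        ids <- familyIds(spec)
        tree <- ape::rtree(spec@nFamily, tip.label = ids)

        # evolve sequences down the tree
        L <- spec@msaLength
        nNode <- ape::Nnode(tree) + spec@nFamily
        seqs <- vector("list", nNode)
        root <- spec@nFamily + 1L
        seqs[[root]] <- sample(.AA20, L, replace = TRUE)
        ord <- ape::reorder.phylo(tree, "cladewise")
        for (k in seq_len(nrow(ord$edge))) {
            par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
            s <- seqs[[par]]
            psub <- 1 - exp(-spec@noiseRate * ord$edge.length[k])
            hit <- stats::runif(L) < psub
            if (any(hit))
                s[hit] <- vapply(s[hit], function(a)
                    sample(setdiff(.AA20, a), 1), character(1))
            seqs[[child]] <- s
        }
        msaM <- do.call(rbind, seqs[seq_len(spec@nFamily)])
        rownames(msaM) <- tree$tip.label
        msaM <- msaM[ids, , drop = FALSE]

        # planted pairs: greedily take disjoint pairs, most divergent first
        pd <- phyloRaw(patristicDistances(tree))
        cmb <- utils::combn(ids, 2)
        dd <- pd[cbind(cmb[1, ], cmb[2, ])]
        used <- character(0); planted <- NULL
        for (i in order(dd, decreasing = TRUE)) {
            a <- cmb[1, i]; b <- cmb[2, i]
            if (a %in% used || b %in% used) next
            planted <- rbind(planted, data.frame(id_a = a, id_b = b))
            used <- c(used, a, b)
            if (nrow(planted) == spec@nPlanted) break
        }
        members <- used

        cols <- sample.int(L, spec@nConservedColumns + spec@nVariableColumns)
        consCols <- cols[seq_len(spec@nConservedColumns)]
        varCols <- setdiff(cols, consCols)
        # each planted pair gets its own residue per conserved column, so
        # the pair is invariant there while the column stays variable
        # family-wide (pair-specific conservation, not family conservation);
        # residues come from the high self-score half of the matrix so the
        # planted effect size is well above one matrix-score unit
        blos <- defaultSubstitutionMatrix()[.AA20, .AA20]
        hiDiag <- .AA20[diag(blos) >= stats::median(diag(blos))]
        consRes <- character(0)
        for (cc in consCols) {
            res <- sample(hiDiag, nrow(planted),
                          replace = nrow(planted) > length(hiDiag))
            for (i in seq_len(nrow(planted)))
                msaM[c(planted$id_a[i], planted$id_b[i]), cc] <- res[i]
            consRes <- c(consRes, paste(res, collapse = "/"))
        }
        # variable columns: a background-conserved residue family-wide, but
        # one member of each planted pair carries a strongly mismatching
        # residue, so the pair scores fall well below the column mean
        for (cc in varCols) {
            bgRes <- sample(hiDiag, 1)
            msaM[, cc] <- bgRes
            lowVs <- .AA20[blos[.AA20, bgRes] <= -2]
            if (length(lowVs) == 0)
                lowVs <- .AA20[order(blos[.AA20, bgRes])][1:3]
            msaM[planted$id_a, cc] <- sample(lowVs, nrow(planted),
                                             replace = TRUE)
        }

        msa <- apply(msaM, 1, paste, collapse = "")
        list(msa = msa, tree = tree, reference = ids[1],
             plantedPairs = planted,
             conservedColumns = data.frame(column = consCols,
                                           residues = consRes),
             variableColumns = as.integer(varCols))
    })
}

#' Simulate the interactome with planted shared-partner pairs
#'
#' Generates an undirected preferential-attachment background, wires each
#' family member to a few private background partners, and gives every
#' planted pair a dedicated set of partners shared by both members (so the
#' pair is close under diffusion/commute-time kernels while non-planted
#' family pairs share about nothing).
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param plantedPairs data.frame (id_a, id_b), typically from
#'   \code{\link{synthFamily}}; by default members are paired consecutively
#' @return list with \code{network} (\linkS4class{InteractionNetwork}) and
#'   \code{truth} (planted pairs with their shared-partner identifiers)
#' @export
synthNetwork <- function(spec, plantedPairs = NULL) {
    stopifnot(is(spec, "SyntheticSpec"))
    ids <- familyIds(spec)
    if (is.null(plantedPairs)) {
        k <- spec@nPlanted
        plantedPairs <- data.frame(id_a = ids[seq_len(k) * 2 - 1],
                                   id_b = ids[seq_len(k) * 2])
    }
    withLocalSeed(spec@seed + 2000L, {
        bg <- igraph::sample_pa(spec@nBackground, power = spec@paPower,
                                m = spec@paEdges, directed = FALSE)
        igraph::V(bg)$name <- sprintf("BG%03d", seq_len(spec@nBackground))
        edges <- igraph::as_edgelist(bg)

        bgIds <- igraph::V(bg)$name
        need <- length(ids) * spec@privatePartners +
            nrow(plantedPairs) * spec@nSharedPartners
        if (need > length(bgIds))
            stop("background too small for the requested wiring")
        # one global permutation, sliced into disjoint private and shared
        # partner sets, so no family pair shares a partner by accident
        pool <- sample(bgIds)
        ptr <- 1L
        for (f in ids) {
            part <- pool[ptr:(ptr + spec@privatePartners - 1L)]
            ptr <- ptr + spec@privatePartners
            edges <- rbind(edges, cbind(f, part))
        }
        sharedNodes <- list()
        for (i in seq_len(nrow(plantedPairs))) {
            sh <- pool[ptr:(ptr + spec@nSharedPartners - 1L)]
            ptr <- ptr + spec@nSharedPartners
            sharedNodes[[pairKey(plantedPairs$id_a[i],
                                 plantedPairs$id_b[i])]] <- sh
            edges <- rbind(edges,
                           cbind(plantedPairs$id_a[i], sh),
                           cbind(plantedPairs$id_b[i], sh))
        }
        net <- suppressWarnings(interactionNetwork(edges))
        list(network = net,
             truth = list(plantedPairs = plantedPairs,
                          sharedNodes = sharedNodes))
    })
}

#' Build a toy two-chain complex with known contacts
#'
#' Writes a minimal, parseable PDB of two C-alpha-only poly-alanine chains:
#' chain A extended along the x axis (3.8 Angstrom spacing) and chain B
#' placed directly above the designated contact residues at
#' \code{contactDistance}.  At the default 5.5 Angstrom exactly the
#' designed residues lose solvent accessibility upon complexation, so the
#' true interface is known by construction.
#'
#' @param spec a \linkS4class{SyntheticSpec} (peptide length, contacts,
#'   distance), or NULL when the explicit arguments are given
#' @param file optional path to write the PDB text to
#' @param apart place chain B 100 Angstrom away instead (no contacts)
#' @return list with \code{structure} (\linkS4class{ComplexStructure}),
#'   \code{pdbText}, and \code{contacts} (the designed residues)
#' @export
synthComplex <- function(spec = syntheticSpec(), file = NULL,
                         apart = FALSE) {
    stopifnot(is(spec, "SyntheticSpec"))
    spacing <- 3.8
    contacts <- spec@contactResidues
    y <- if (apart) 100 else spec@contactDistance
    lines <- character(0)
    serial <- 0L
    addAtom <- function(chain, resno, x, y, z) {
        serial <<- serial + 1L
        lines <<- c(lines, sprintf(
            "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, chain, resno, x, y, z, 1.0, 0.0, "C"))
    }
    for (i in seq_len(spec@peptideLength))
        addAtom("A", i, spacing * (i - 1), 0, 0)
    for (j in seq_along(contacts))
        addAtom("B", j, spacing * (contacts[j] - 1), y, 0)
    lines <- c(lines, "END")
    if (!is.null(file)) writeLines(lines, file)
    tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
    if (is.null(file)) { writeLines(lines, tmp); on.exit(unlink(tmp)) }
    structure <- readComplexStructure(tmp, rasChain = "A", id = "TOY")
    list(structure = structure, pdbText = lines, contacts = contacts)
}
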