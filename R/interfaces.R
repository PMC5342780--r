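# Overlap of conserved positions with complex binding interfaces:
# per-complex and per-position tabulation, flanking participation, and
# assignment to named functional regions.

#' Parse residue position labels
#'
#' Accepts labels such as \code{"Y32"} (one-letter residue + number) or bare
#' integers; returns a data.frame with the numeric position and the label.
#'
#' @param x character or integer vector
#' @return data.frame (label, position)
#' @export
parsePositionLabels <- function(x) {
    if (is.numeric(x))
        return(data.frame(label = as.character(x), position = as.integer(x)))
    pos <- suppressWarnings(as.integer(gsub("[^0-9]", "", x)))
    if (anyNA(pos)) stop("unparseable position label(s): ",
                         paste(x[is.na(pos)], collapse = ", "))
    data.frame(label = x, position = pos)
}

# Normalize interface input (list of InterfaceRegion, or data.frame with
# columns id + positions comma string) to a named list of integer vectors.
.interfaceList <- function(interfaces) {
    if (is.data.frame(interfaces)) {
        stopifnot(all(c("id", "positions") %in% names(interfaces)))
        out <- lapply(strsplit(interfaces$positions, ","), function(p)
            parsePositionLabels(trimws(p))$position)
        names(out) <- interfaces$id
        return(out)
    }
    out <- lapply(interfaces, function(i) {
        stopifnot(is(i, "InterfaceRegion"))
        i@positions
    })
    names(out) <- vapply(interfaces, function(i) i@id, character(1))
    out
}

#' Tabulate query positions against complex interfaces
#'
#' Builds the two consistent views of the overlap between a set of
#' reference-numbered positions and a collection of binding interfaces:
#' per complex, how many query positions fall inside its interface (with
#' the ratio to the interface size, as a percentage truncated to one
#' decimal); and per position, how many complexes include it (ordered by
#' descending match count, then position).
#'
#' @param interfaces list of \linkS4class{InterfaceRegion} objects, or a
#'   data.frame with columns \code{id} and comma-separated \code{positions}
#'   (e.g. \code{\link{rasInterfaceTable}})
#' @param positions query positions: labels like \code{"Y32"} or integers
#' @return a \linkS4class{MatchTable}
#' @export
matchPositions <- function(interfaces, positions) {
    iface <- .interfaceList(interfaces)
    q <- parsePositionLabels(positions)
    byComplex <- do.call(rbind, lapply(names(iface), function(id) {
        ip <- iface[[id]]
        hit <- q$position %in% ip
        data.frame(id = id, interface_size = length(ip),
                   matches = sum(hit),
                   ratio_pct = if (length(ip))
                       truncPct1(100 * sum(hit) / length(ip)) else NA_real_,
                   matched = paste(q$label[hit], collapse = ","))
    }))
    byPosition <- if (nrow(q) == 0)
        data.frame(label = character(0), position = integer(0),
                   n_matches = integer(0), complexes = character(0))
    else do.call(rbind, lapply(seq_len(nrow(q)), function(i) {
        inb <- vapply(iface, function(ip) q$position[i] %in% ip, logical(1))
        data.frame(label = q$label[i], position = q$position[i],
                   n_matches = sum(inb),
                   complexes = paste(names(iface)[inb], collapse = ","))
    }))
    byPosition <- byPosition[order(-byPosition$n_matches,
                                   byPosition$position), ]
    rownames(byComplex) <- rownames(byPosition) <- NULL
    new("MatchTable", byComplex = byComplex, byPosition = byPosition)
}

#' @rdname MatchTable-class
#' @export
setMethod("matchByComplex", "MatchTable", function(x) x@byComplex)

#' @rdname MatchTable-class
#' @export
setMethod("matchByPosition", "MatchTable", function(x) x@byPosition)

setMethod("show", "MatchTable", function(object) {
    cat(sprintf("MatchTable: %d complexes x %d positions, %d total matches\n",
                nrow(object@byComplex), nrow(object@byPosition),
                sum(object@byComplex$matches)))
})

#' Interface participation classes
#'
#' Classifies each query position as \code{direct} (inside at least one
#' interface), \code{flanked} (not direct, but both sequence neighbours
#' i - 1 and i + 1 are interface residues), or \code{none}.  By default the
#' two neighbours may come from different complexes' interfaces; with
#' \code{withinComplex = TRUE} both must belong to the same complex.
#'
#' @param interfaces as in \code{\link{matchPositions}}
#' @param positions query positions (labels or integers)
#' @param withinComplex require both flanking residues in one complex's
#'   interface (default FALSE)
#' @return data.frame (label, position, class)
#' @export
flankingParticipation <- function(interfaces, positions,
                                  withinComplex = FALSE) {
    iface <- .interfaceList(interfaces)
    q <- parsePositionLabels(positions)
    pooled <- sort(unique(unlist(iface)))
    cls <- vapply(q$position, function(p) {
        direct <- any(vapply(iface, function(ip) p %in% ip, logical(1)))
        if (direct) return("direct")
        flanked <- if (withinComplex)
            any(vapply(iface, function(ip)
                (p - 1) %in% ip && (p + 1) %in% ip, logical(1)))
        else (p - 1) %in% pooled && (p + 1) %in% pooled
        if (flanked) "flanked" else "none"
    }, character(1))
    data.frame(label = q$label, position = q$position,
               class = factor(cls, levels = c("direct", "flanked", "none")))
}

#' Assign positions to named functional regions
#'
#' Positions may belong to several regions; positions matching none are
#' collected under \code{"Inert"}.  Percentages are rounded to integers
#' relative to the total number of query positions.
#'
#' @param positions query positions (labels or integers)
#' @param regionMap named list of integer vectors (default
#'   \code{\link{rasRegionMap}()})
#' @return data.frame (region, members, n, pct)
#' @export
regionAssignment <- function(positions, regionMap = rasRegionMap()) {
    q <- parsePositionLabels(positions)
    rows <- lapply(names(regionMap), function(rn) {
        hit <- q$position %in% regionMap[[rn]]
        data.frame(region = rn, members = paste(q$label[hit], collapse = ","),
                   n = sum(hit), pct = round(100 * sum(hit) / nrow(q)))
    })
    inAny <- Reduce(`|`, lapply(regionMap, function(rr) q$position %in% rr))
    rows <- c(rows, list(data.frame(
        region = "Inert", members = paste(q$label[!inAny], collapse = ","),
        n = sum(!inAny), pct = round(100 * sum(!inAny) / nrow(q)))))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Canonical Ras functional regions
#'
#' Residue ranges of the conformationally mobile switch regions, the
#' C-terminal hyper-variable region and the nucleotide (GDP/GTP) binding
#' site, in HRas numbering.  Residue 35 belongs to both Switch I and the
#' nucleotide site; multi-membership is intended.
#'
#' @return named list of integer vectors
#' @export
rasRegionMap <- function() {
    list(
        `Switch I` = 30:38,
        `Switch II` = 60:76,
        `C-terminal HVR` = 166:189,
        `Nucleotide binding site` = c(10:17, 28L, 35L, 57:60, 116:120,
                                      145:147))
}

#' Curated Ras complex binding-site residue lists
#'
#' Published binding-site residue lists (HRas reference numbering) for 21
#' structural groups of human Ras-family complexes from the Protein Data
#' Bank (28 structures; sequence-identical entries share a row), spanning
#' GEF, GAP, antibody, Ras-binding-domain and other partner classes.  Used
#' as the reference input for \code{\link{matchPositions}},
#' \code{\link{flankingParticipation}} and \code{\link{regionAssignment}}.
#'
#' @return data.frame (group, id, members, description, positions)
#' @export
rasInterfaceTable <- function() {
    f <- system.file("extdata", "ras_complex_interfaces.tsv",
                     package = "dirpscan", mustWork = TRUE)
    utils::read.delim(f, stringsAsFactors = FALSE)
}

#' The 22 differentially conserved Ras positions
#'
#' Positions specifically conserved (21) or specifically variable (1, at
#' residue 139) in divergent-but-interacting Ras pairs, in HRas reference
#' numbering.  (Published sources label the variable position variably as
#' R139 or I139; the residue-139 identity used here follows the tabulated
#' form, I139.)
#'
#' @return data.frame (label, direction)
#' @export
dirpPositions <- function() {
    f <- system.file("extdata", "dirp_positions.tsv",
                     package = "dirpscan", mustWork = TRUE)
    utils::read.delim(f, stringsAsFactors = FALSE)
}
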