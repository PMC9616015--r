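#' Fourfold connection-strength coding
#'
#' Bins the fraction of realized ties between (or within) sectors into the
#' fourfold scheme: under 20\% of possible ties is coded 0 (no relation),
#' 20-40\% is 1 (weak), 40-60\% is 2 (average) and at least 60\% is 3
#' (strong).  Boundary fractions take the higher code (intervals are
#' half-open below: 0.20 -> 1, 0.40 -> 2, 0.60 -> 3).
#'
#' @param fraction numeric vector of fractions in [0, 1].
#' @return integer codes in 0..3.
#' @export
codeStrength <- function(fraction) {
  if (any(is.na(fraction) | fraction < 0 | fraction > 1))
    stop("fractions must lie in [0, 1]")
  ifelse(fraction >= 0.6, 3L,
         ifelse(fraction >= 0.4, 2L, ifelse(fraction >= 0.2, 1L, 0L)))
}

#' Aggregate an organization adjacency to the sector level
#'
#' For every unordered pair of distinct sectors, counts the possible
#' (|A| x |B|) and present inter-sector organization ties, their fraction
#' and the fourfold strength code; within-sector fractions (over
#' |A|(|A|-1)/2 pairs) are computed the same way and held in a separate
#' table.  Sectors with no organizations in the network do not appear.
#'
#' @param adj an \linkS4class{Adjacency}.
#' @param roster the matching \linkS4class{Roster} (every organization must
#'   carry a known sector).
#' @return a \linkS4class{SectorGraph}.
#' @export
aggregateToSectors <- function(adj, roster) {
  m <- adjMatrix(adj)
  sec <- orgSectors(roster)[rownames(m)]
  if (any(is.na(sec)))
    stop("organization(s) without a sector: ",
         paste(rownames(m)[is.na(sec)], collapse = ", "))
  sectors <- sort(unique(unname(sec)))
  if (length(sectors) < 2)
    stop("sector aggregation needs at least 2 sectors")
  sizes <- table(sec)

  combs <- utils::combn(sectors, 2)
  pairs <- data.frame(sector_a = combs[1, ], sector_b = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$possible <- as.integer(sizes[pairs$sector_a] * sizes[pairs$sector_b])
  pairs$present <- vapply(seq_len(nrow(pairs)), function(r) {
    block <- m[sec == pairs$sector_a[r], sec == pairs$sector_b[r],
               drop = FALSE]
    as.integer(sum(block))
  }, 1L)
  pairs$fraction <- pairs$present / pairs$possible
  pairs$strength <- codeStrength(pairs$fraction)

  within <- data.frame(sector = sectors, stringsAsFactors = FALSE)
  within$possible <- as.integer(sizes[sectors] * (sizes[sectors] - 1) / 2)
  within$present <- vapply(sectors, function(s) {
    block <- m[sec == s, sec == s, drop = FALSE]
    as.integer(sum(block) / 2)
  }, 1L, USE.NAMES = FALSE)
  within$fraction <- ifelse(within$possible > 0,
                            within$present / within$possible, 0)
  within$strength <- codeStrength(within$fraction)

  new("SectorGraph", pairs = pairs, within = within,
      layer = layerLabel(adj))
}

setMethod("show", "SectorGraph", function(object) {
  cat("SectorGraph (", object@layer, "): ", nrow(object@within),
      " sectors, ", sum(object@pairs$strength > 0),
      " connected sector pairs of ", nrow(object@pairs), "\n", sep = "")
  print(object@pairs[object@pairs$strength > 0,
                     c("sector_a", "sector_b", "fraction", "strength")],
        row.names = FALSE, digits = 3)
})

#' @rdname aggregateToSectors
#' @param x a \linkS4class{SectorGraph}.
#' @param includeWithin also bind the within-sector rows (with
#'   \code{sector_b == sector_a})?
#' @return \code{sectorPairs} returns the pair table as a data.frame.
#' @export
sectorPairs <- function(x, includeWithin = FALSE) {
  out <- x@pairs
  if (includeWithin) {
    w <- x@within
    out <- rbind(out, data.frame(sector_a = w$sector, sector_b = w$sector,
                                 possible = w$possible, present = w$present,
                                 fraction = w$fraction, strength = w$strength,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Write a sector graph
#'
#' \code{writeSectorGraph} writes the CSV interchange form (between-sector
#' pairs plus within-sector rows); \code{writeSectorDOT} writes a Graphviz
#' DOT rendering in which edge width and darkness encode the strength code,
#' omitting pairs coded 0 and (by default) within-sector loops.
#'
#' @param x a \linkS4class{SectorGraph}.
#' @param path output file path.
#' @export
writeSectorGraph <- function(x, path) {
  utils::write.csv(sectorPairs(x, includeWithin = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSectorGraph
#' @param includeWithin draw within-sector loops as well?
#' @export
writeSectorDOT <- function(x, path, includeWithin = FALSE) {
  df <- sectorPairs(x, includeWithin)
  df <- df[df$strength > 0, , drop = FALSE]
  shade <- c("grey80", "grey55", "grey20")
  lines <- c("graph sectors {", "  node [shape=box, fontsize=10];",
             sprintf('  "%s";', x@within$sector),
             sprintf('  "%s" -- "%s" [penwidth=%d, color=%s];',
                     df$sector_a, df$sector_b, df$strength,
                     shade[df$strength]),
             "}")
  writeLines(lines, path)
  invisible(path)
}
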