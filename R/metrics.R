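## Integration metrics, implemented directly from their definitions on the
## 0/1 matrix.  Tie counting uses the ordered-pair convention throughout
## (ties = 2 x undirected edges), which is the convention under which the
## standard whole-network tables are internally consistent
## (ties / n = average degree, ties / (n(n-1)) = density).

.adj_mat <- function(adj) if (is.matrix(adj)) adj else adjMatrix(adj)

#' Number of ties (ordered-pair convention)
#'
#' Counts ordered pairs (i, j), i != j, with a tie -- twice the number of
#' undirected edges of a symmetric adjacency.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return integer count.
#' @export
countTies <- function(adj) {
  m <- .adj_mat(adj)
  as.integer(sum(m))
}

#' Network density
#'
#' Ties present divided by the maximum possible:
#' \code{ties / (n (n - 1))} under the ordered-pair convention.  Reported to
#' 3 decimals in tables but returned at full precision.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return fraction in [0, 1].
#' @export
tieDensity <- function(adj) {
  m <- .adj_mat(adj)
  n <- nrow(m)
  if (n < 2) stop("density is undefined for fewer than 2 organizations")
  sum(m) / (n * (n - 1))
}

#' Average degree centrality
#'
#' Mean number of connections per organization: \code{ties / n}, i.e. the
#' mean undirected degree.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return nonnegative number.
#' @export
averageDegree <- function(adj) {
  m <- .adj_mat(adj)
  sum(m) / nrow(m)
}

#' Isolates and active organizations
#'
#' Isolates are organizations with no tie to any other organization; active
#' organizations are the rest.  The percentage is rounded to an integer, as
#' in the standard table format.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return list with \code{isolates}, \code{active}, \code{active_pct}.
#' @export
isolateSummary <- function(adj) {
  m <- .adj_mat(adj)
  deg <- rowSums(m)
  iso <- sum(deg == 0)
  n <- nrow(m)
  list(isolates = as.integer(iso), active = as.integer(n - iso),
       active_pct = as.integer(round(100 * (n - iso) / n)))
}

#' Per-organization degree centrality
#'
#' Degree (number of other organizations an organization is connected to)
#' and normalized degree (degree / (n - 1), isolates included in n), ordered
#' by decreasing degree with ties broken by org_id.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return data.frame (\code{org_id}, \code{degree},
#'   \code{normalized_degree}).
#' @export
degreeCentrality <- function(adj) {
  m <- .adj_mat(adj)
  n <- nrow(m)
  if (n < 2) stop("degree centrality needs at least 2 organizations")
  deg <- as.integer(rowSums(m))
  out <- data.frame(org_id = rownames(m), degree = deg,
                    normalized_degree = deg / (n - 1),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$org_id), , drop = FALSE]
}

#' Freeman degree centralization
#'
#' How concentrated ties are around the most-connected organization:
#' \deqn{C = \sum_i (d_{max} - d_i) / ((n-1)(n-2))}
#' for an undirected graph, 0 for regular graphs and 1 for a star.  Isolates
#' are included in n.
#'
#' @param adj an \linkS4class{Adjacency} (or symmetric 0/1 matrix).
#' @return fraction in [0, 1].
#' @export
degreeCentralization <- function(adj) {
  m <- .adj_mat(adj)
  n <- nrow(m)
  if (n < 3) stop("degree centralization is undefined for fewer than 3 organizations")
  deg <- rowSums(m)
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Ranked table of the most central organizations
#'
#' The k organizations with highest normalized degree, annotated with sector
#' and tasks and flagged when they hold the gatekeeper task; ties are broken
#' deterministically by org_id.
#'
#' @param adj an \linkS4class{Adjacency}.
#' @param roster the matching \linkS4class{Roster}.
#' @param k number of organizations to return (<= n).
#' @return data.frame (\code{rank}, \code{org_id}, \code{name},
#'   \code{sector}, \code{tasks}, \code{gatekeeper}, \code{degree},
#'   \code{normalized_degree}).
#' @export
topCentral <- function(adj, roster, k = 10L) {
  dc <- degreeCentrality(adj)
  k <- min(k, nrow(dc))
  dc <- dc[seq_len(k), , drop = FALSE]
  ord <- match(dc$org_id, orgIds(roster))
  tk <- roster@orgs$tasks[ord]
  data.frame(rank = seq_len(k), org_id = dc$org_id,
             name = roster@orgs$name[ord],
             sector = roster@orgs$sector[ord], tasks = tk,
             gatekeeper = vapply(strsplit(tk, ";", fixed = TRUE),
                                 function(v) "gatekeeper" %in% v, TRUE),
             degree = dc$degree, normalized_degree = dc$normalized_degree,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the integration metric panel
#'
#' The per-network-per-layer comparison row set: organizations, sectors,
#' active organizations (with percentage), isolates, ordered tie count,
#' density, average degree and Freeman degree centralization.
#'
#' @param adj an \linkS4class{Adjacency}.
#' @param roster optional \linkS4class{Roster} (supplies the sector count).
#' @param network network label carried into reports.
#' @return a \linkS4class{MetricsPanel}.
#' @export
metricsPanel <- function(adj, roster = NULL, network = "network") {
  m <- .adj_mat(adj)
  n <- nrow(m)
  iso <- isolateSummary(adj)
  nsec <- if (is.null(roster)) NA_integer_ else
    length(unique(orgSectors(roster)[rownames(m)]))
  new("MetricsPanel",
      n_orgs = as.integer(n), n_sectors = nsec,
      active_orgs = iso$active, active_pct = iso$active_pct,
      isolates = iso$isolates, ties_ordered = countTies(adj),
      density = tieDensity(adj), avg_degree = averageDegree(adj),
      centralization = if (n >= 3) degreeCentralization(adj) else NA_real_,
      layer = if (is.matrix(adj)) "contact" else layerLabel(adj),
      network = network)
}

#' @rdname metricsPanel
#' @param x a \linkS4class{MetricsPanel}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.MetricsPanel <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(network = x@network, layer = x@layer, n_orgs = x@n_orgs,
             n_sectors = x@n_sectors, active_orgs = x@active_orgs,
             active_pct = x@active_pct, isolates = x@isolates,
             ties_ordered = x@ties_ordered, density = x@density,
             avg_degree = x@avg_degree, centralization = x@centralization,
             stringsAsFactors = FALSE)
}

setMethod("show", "MetricsPanel", function(object) {
  cat("MetricsPanel [", object@network, ", ", object@layer, "]\n", sep = "")
  cat(sprintf("  Number of sectors        %s\n",
              ifelse(is.na(object@n_sectors), "-", object@n_sectors)))
  cat(sprintf("  Number of organizations  %d\n", object@n_orgs))
  cat(sprintf("  Active organizations     %d (%d%%)\n",
              object@active_orgs, object@active_pct))
  cat(sprintf("  Isolates                 %d\n", object@isolates))
  cat(sprintf("  Number of ties           %d\n", object@ties_ordered))
  cat(sprintf("  Density                  %.3f\n", object@density))
  cat(sprintf("  Average degree           %.2f\n", object@avg_degree))
  cat(sprintf("  Degree centralization    %s\n",
              ifelse(is.na(object@centralization), "-",
                     sprintf("%.3f", object@centralization))))
})
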