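#' Labeled reconstruction of nonrespondent rows
#'
#' Survey nonresponse handling for sociometric data: the outgoing-tie row of
#' every nonresponding organization is replaced by the transpose of its
#' column restricted to responding reporters -- i.e. what responding
#' organizations said about it is entered as a reciprocal relationship.
#' Reports between two nonresponding organizations are unrecoverable and
#' stay 0.  Responding rows are returned unchanged; every imputed cell is
#' flagged in the \code{reconstructed} layer.
#'
#' @param report a \linkS4class{ReportMatrix}.
#' @return a \linkS4class{ReportMatrix} with missing rows filled in.
#' @export
labeledReconstruction <- function(report) {
  m <- report@mat
  rec <- report@reconstructed
  resp <- report@responded
  for (i in which(!resp)) {
    m[i, ] <- ifelse(resp, m[, i], 0L)
    rec[i, ] <- TRUE
  }
  diag(m) <- 0L
  new("ReportMatrix", mat = m, responded = resp, reconstructed = rec,
      layer = report@layer)
}

#' Any-link union symmetrization
#'
#' Codes an undirected tie as present if at least one of the two
#' organizations (i.e. any of their boundary spanners) reported it:
#' \code{adj[i,j] = max(report[i,j], report[j,i])}.  Unconfirmed
#' (unidirectional) reports therefore count as ties.  Cell provenance is
#' "observed" when at least one endpoint responded, "reconstructed" when
#' neither did.
#'
#' @param report a \linkS4class{ReportMatrix} (normally after
#'   \code{\link{labeledReconstruction}}; for this union rule the two orders
#'   coincide).
#' @return an \linkS4class{Adjacency}.
#' @export
symmetrizeUnion <- function(report) {
  m <- report@mat
  if (!all(m %in% c(0L, 1L))) stop("report matrix must be binary")
  sym <- pmax(m, t(m))
  storage.mode(sym) <- "integer"
  diag(sym) <- 0L
  resp <- report@responded
  either <- outer(resp, resp, "|")
  prov <- matrix(ifelse(either, "observed", "reconstructed"),
                 nrow(m), dimnames = dimnames(m))
  new("Adjacency", mat = sym, layer = report@layer, provenance = prov,
      responded = resp)
}

#' Wrap a plain symmetric 0/1 matrix as an Adjacency
#'
#' For externally supplied square adjacency matrices (all cells are treated
#' as observed).
#'
#' @param mat square symmetric 0/1 matrix with org_id dimnames.
#' @param layer "contact" or "referral".
#' @return an \linkS4class{Adjacency}.
#' @export
adjacencyFromMatrix <- function(mat, layer = "contact") {
  storage.mode(mat) <- "integer"
  diag(mat) <- 0L
  ids <- rownames(mat)
  new("Adjacency", mat = mat, layer = layer,
      provenance = matrix("observed", nrow(mat), ncol(mat),
                          dimnames = dimnames(mat)),
      responded = stats::setNames(rep(TRUE, nrow(mat)), ids))
}

#' @rdname adjMatrix
#' @export
setMethod("adjMatrix", "Adjacency", function(x, ...) x@mat)

#' @rdname responded
#' @export
setMethod("responded", "Adjacency", function(x) x@responded)

#' @rdname layerLabel
#' @export
setMethod("layerLabel", "Adjacency", function(x) x@layer)

#' Share of reconstructed dyads
#'
#' Fraction of off-diagonal unordered organization pairs whose tie value
#' could only be imputed (neither endpoint responded); reported in pipeline
#' logs as a data-quality figure.
#'
#' @param adj an \linkS4class{Adjacency}.
#' @return fraction in [0, 1].
#' @export
reconstructedShare <- function(adj) {
  n <- nrow(adj@mat)
  if (n < 2) return(0)
  ut <- upper.tri(adj@provenance)
  mean(adj@provenance[ut] == "reconstructed")
}

setMethod("show", "Adjacency", function(object) {
  cat("Adjacency (", object@layer, "): ", nrow(object@mat),
      " organizations, ", sum(object@mat) / 2, " undirected ties, ",
      round(100 * reconstructedShare(object), 1),
      "% of dyads reconstructed-only\n", sep = "")
})

#' Read / write a square adjacency CSV
#'
#' Interchange format: a square CSV whose first column and header row carry
#' the org_ids.
#'
#' @param path file path.
#' @param layer layer label attached on read.
#' @return \code{readAdjacencyCSV} returns an \linkS4class{Adjacency}.
#' @export
readAdjacencyCSV <- function(path, layer = "contact") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  if (!identical(rownames(m), colnames(m)))
    stop("adjacency CSV must have identical row and column org_ids")
  adjacencyFromMatrix(m, layer)
}

#' @rdname readAdjacencyCSV
#' @param x an \linkS4class{Adjacency}, \linkS4class{ReportMatrix} or plain
#'   matrix to write.
#' @export
writeAdjacencyCSV <- function(x, path) {
  m <- if (is.matrix(x)) x else adjMatrix(x)
  utils::write.csv(m, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Undirected edge list of an adjacency
#'
#' @param adj an \linkS4class{Adjacency}.
#' @return data.frame (\code{from}, \code{to}), each unordered tie once.
#' @export
edgeList <- function(adj) {
  m <- adj@mat
  idx <- which(upper.tri(m) & m == 1L, arr.ind = TRUE)
  data.frame(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname edgeList
#' @param path file path for the edge-list CSV.
#' @export
writeEdgeList <- function(adj, path) {
  utils::write.csv(edgeList(adj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert to an igraph object (for export and plotting)
#'
#' Builds an undirected igraph graph carrying sector and task node
#' attributes; used for GraphML export to external network viewers.  All
#' metric computations in this package are formula-based and do not go
#' through this representation.
#'
#' @param adj an \linkS4class{Adjacency}.
#' @param roster optional \linkS4class{Roster} supplying node attributes.
#' @return an \code{igraph} graph.
#' @export
asIgraph <- function(adj, roster = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj@mat, mode = "undirected")
  if (!is.null(roster)) {
    ord <- match(rownames(adj@mat), orgIds(roster))
    igraph::V(g)$sector <- roster@orgs$sector[ord]
    igraph::V(g)$tasks <- roster@orgs$tasks[ord]
    igraph::V(g)$name_full <- roster@orgs$name[ord]
  }
  g
}

#' @rdname asIgraph
#' @param path file path for the GraphML export.
#' @export
writeGraphML <- function(adj, path, roster = NULL) {
  igraph::write_graph(asIgraph(adj, roster), path, format = "graphml")
  invisible(path)
}
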