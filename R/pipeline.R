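#' Integer response percentage
#'
#' Table-style arithmetic: \code{round(100 * responding / invited)}.
#'
#' @param responding number of responding network members.
#' @param invited number of invited network members.
#' @return integer percentage.
#' @export
responsePercentage <- function(responding, invited) {
  as.integer(round(100 * responding / invited))
}

#' Assemble a pipeline configuration
#'
#' @param networks named list, one entry per network.  Each entry is either
#'   \code{list(synthetic = <SyntheticConfig>)} or
#'   \code{list(roster = path, reports = path, responses = path)} (the
#'   responses path is optional).
#' @param layers relational layers to analyze (subset of contact/referral).
#' @param threshold optional boundary filter,
#'   \code{list(attribute =, minimum =, sectors =)}, applied to every
#'   network's roster before analysis.
#' @param outdir optional output directory; when set, every run writes CSV,
#'   JSON, GraphML/DOT artifacts and a run manifest there.
#' @param seed integer master seed; synthetic networks are re-seeded
#'   deterministically from it (seed + 1000 * network index).
#' @param k_top how many organizations the centrality ranking keeps.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(networks, layers = c("contact", "referral"),
                           threshold = NULL, outdir = NULL, seed = 1L,
                           k_top = 10L) {
  if (length(networks) == 0) stop("at least one network is required")
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("networks must be a named list")
  if (!all(layers %in% .LAYERS))
    stop("layers must be a subset of: ", paste(.LAYERS, collapse = ", "))
  for (nm in names(networks)) {
    nw <- networks[[nm]]
    if (!is.null(nw$synthetic)) {
      if (!methods::is(nw$synthetic, "SyntheticConfig"))
        stop("network '", nm, "': synthetic entry must be a SyntheticConfig")
    } else {
      for (p in c(nw$roster, nw$reports, nw$responses))
        if (!file.exists(p))
          stop("network '", nm, "': input file not found: ", p)
    }
  }
  list(networks = networks, layers = layers, threshold = threshold,
       outdir = outdir, seed = as.integer(seed), k_top = as.integer(k_top))
}

#' Analyze one network
#'
#' Runs the per-network stages: optional boundary threshold filter, report
#' filtering, respondent collapse per layer, labeled reconstruction, union
#' symmetrization, metric panel, centrality ranking and sector aggregation.
#' Every stage is logged with row/tie counts.
#'
#' @param roster a \linkS4class{Roster}.
#' @param reports a \linkS4class{TieReportSet}.
#' @param responses optional responses data.frame (\code{respondent_id},
#'   \code{responded}).
#' @param layers layers to analyze.
#' @param threshold optional \code{list(attribute, minimum, sectors)}.
#' @param network network label.
#' @param k_top size of the centrality ranking.
#' @param verbose log stages via \code{message()}?
#' @return list with \code{roster} (post-filter), \code{differentiation},
#'   \code{layers} (per layer: \code{adjacency}, \code{panel},
#'   \code{top_central}, \code{sectors}) and \code{log}.
#' @export
analyzeNetwork <- function(roster, reports, responses = NULL,
                           layers = c("contact", "referral"),
                           threshold = NULL, network = "network",
                           k_top = 10L, verbose = TRUE) {
  say <- function(...) if (verbose) message("[", network, "] ", ...)
  log <- list(network = network, invited_orgs = nOrgs(roster))
  if (!is.null(threshold)) {
    before <- nOrgs(roster)
    roster <- applyThresholdFilter(roster, threshold$attribute,
                                   threshold$minimum, threshold$sectors)
    reports <- filterReports(reports, roster)
    if (!is.null(responses))
      responses <- responses[responses$respondent_id %in%
                               rosterRespondents(roster)$respondent_id, ,
                             drop = FALSE]
    say("threshold filter (", threshold$attribute, " >= ",
        threshold$minimum, "): ", before, " -> ", nOrgs(roster),
        " organizations")
    log$invited_orgs <- nOrgs(roster)
  }
  out_layers <- list()
  for (layer in layers) {
    rm <- collapseRespondents(roster, reports, layer, responses)
    nresp <- sum(responded(rm))
    rec <- labeledReconstruction(rm)
    adj <- symmetrizeUnion(rec)
    panel <- metricsPanel(adj, roster, network)
    say(layer, ": ", nresp, " responding organizations (",
        responsePercentage(nresp, nOrgs(roster)), "%), ",
        countTies(adj) / 2, " undirected ties, ",
        round(100 * reconstructedShare(adj), 1), "% dyads reconstructed-only")
    sectors <- if (length(unique(orgSectors(roster))) >= 2)
      aggregateToSectors(adj, roster) else NULL
    out_layers[[layer]] <- list(
      adjacency = adj, panel = panel,
      top_central = topCentral(adj, roster, k_top),
      sectors = sectors,
      responding_orgs = nresp,
      response_pct = responsePercentage(nresp, nOrgs(roster)),
      reconstructed_share = reconstructedShare(adj))
  }
  log$responding_orgs <- out_layers[[1]]$responding_orgs
  log$response_pct <- out_layers[[1]]$response_pct
  list(roster = roster, differentiation = summarizeDifferentiation(roster),
       layers = out_layers, log = log)
}

#' Run the full comparison pipeline
#'
#' For every configured network (synthetic or file-based) and every layer:
#' ingest, boundary filter, respondent collapse, labeled reconstruction,
#' union symmetrization, metric panel, centrality ranking and sector
#' aggregation; then a cross-network comparison table per layer.  When the
#' configuration names an output directory, all artifacts and a run manifest
#' are written there.
#'
#' @param config a configuration from \code{\link{pipelineConfig}}.
#' @param verbose log progress to stderr?
#' @return a \linkS4class{ComparisonReport}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  results <- list()
  idx <- 0L
  for (nm in names(config$networks)) {
    idx <- idx + 1L
    nw <- config$networks[[nm]]
    res <- try({
      if (!is.null(nw$synthetic)) {
        scfg <- nw$synthetic
        scfg@seed <- config$seed + 1000L * idx
        sv <- generateSurvey(scfg)
        roster <- sv$roster; reports <- sv$reports; responses <- sv$responses
      } else {
        roster <- readRoster(nw$roster)
        reports <- readTieReports(nw$reports, roster)
        responses <- if (!is.null(nw$responses)) readResponses(nw$responses)
      }
      analyzeNetwork(roster, reports, responses, config$layers,
                     config$threshold, nm, config$k_top, verbose)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("network '", nm, "' aborted: ",
              conditionMessage(attr(res, "condition")))
      next
    }
    results[[nm]] <- res
  }
  tables <- lapply(stats::setNames(config$layers, config$layers),
                   function(layer) {
    panels <- lapply(results, function(r) r$layers[[layer]]$panel)
    .comparison_table(panels)
  })
  report <- new("ComparisonReport", networks = results, tables = tables,
                seed = config$seed)
  if (!is.null(config$outdir)) writeReport(report, config$outdir)
  report
}

## one column per network, the standard comparison row set
.comparison_table <- function(panels) {
  rows <- c("Number of sectors", "Number of organizations",
            "Active organizations (%)", "Isolates", "Number of ties",
            "Density", "Average degree centrality", "Degree centralization")
  cols <- lapply(panels, function(p) c(
    ifelse(is.na(p@n_sectors), "-", as.character(p@n_sectors)),
    as.character(p@n_orgs),
    sprintf("%d (%d%%)", p@active_orgs, p@active_pct),
    as.character(p@isolates),
    as.character(p@ties_ordered),
    sprintf("%.3f", p@density),
    sprintf("%.2f", p@avg_degree),
    ifelse(is.na(p@centralization), "-", sprintf("%.3f", p@centralization))))
  out <- data.frame(metric = rows, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  out
}

#' @rdname runPipeline
#' @param report a \linkS4class{ComparisonReport}.
#' @param layer which layer's cross-network table to return.
#' @export
comparisonTable <- function(report, layer = "contact") {
  report@tables[[layer]]
}

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", length(object@networks), "network(s),",
      "seed", object@seed, "\n")
  for (layer in names(object@tables)) {
    cat("\n--", layer, "layer --\n")
    print(object@tables[[layer]], row.names = FALSE)
  }
})

#' Write all pipeline artifacts
#'
#' Per network and layer: adjacency CSV, undirected edge list, metric panel
#' (CSV + JSON), centrality ranking CSV, sector graph CSV and DOT, GraphML
#' export; per layer a cross-network comparison CSV; plus a run manifest
#' JSON recording the seed and per-stage counts.
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeReport <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = report@seed, networks = list())
  for (nm in names(report@networks)) {
    res <- report@networks[[nm]]
    nd <- file.path(outdir, nm)
    dir.create(nd, recursive = TRUE, showWarnings = FALSE)
    writeRoster(res$roster, file.path(nd, "roster.csv"))
    mlog <- res$log
    for (layer in names(res$layers)) {
      ly <- res$layers[[layer]]
      pre <- file.path(nd, layer)
      writeAdjacencyCSV(ly$adjacency, paste0(pre, "_adjacency.csv"))
      writeEdgeList(ly$adjacency, paste0(pre, "_edges.csv"))
      writeGraphML(ly$adjacency, paste0(pre, "_graph.graphml"), res$roster)
      pan <- as.data.frame(ly$panel)
      utils::write.csv(pan, paste0(pre, "_metrics.csv"), row.names = FALSE)
      jsonlite::write_json(as.list(pan), paste0(pre, "_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(ly$top_central, paste0(pre, "_top_central.csv"),
                       row.names = FALSE)
      if (!is.null(ly$sectors)) {
        writeSectorGraph(ly$sectors, paste0(pre, "_sectors.csv"))
        writeSectorDOT(ly$sectors, paste0(pre, "_sectors.dot"))
      }
      mlog[[paste0(layer, "_ties")]] <- ly$panel@ties_ordered
      mlog[[paste0(layer, "_reconstructed_share")]] <- ly$reconstructed_share
    }
    manifest$networks[[nm]] <- mlog
  }
  for (layer in names(report@tables))
    utils::write.csv(report@tables[[layer]],
                     file.path(outdir, paste0("comparison_", layer, ".csv")),
                     row.names = FALSE)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
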