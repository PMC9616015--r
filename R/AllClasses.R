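#' @import methods
NULL

## Closed vocabularies shared across the package.  Layers are the two
## relational questions of the survey; tasks are the Table-2 style division
## of labor within a child service delivery network.
.LAYERS <- c("contact", "referral")
.TASKS  <- c("gatekeeper", "signaling", "providing_services")

#' Organization roster
#'
#' The node set of a whole-network study: one row per organization with its
#' sector, its tasks within the network (gatekeeper, signaling, providing
#' services), optional numeric attributes (e.g. clients in treatment), and
#' the boundary-spanner respondents invited for that organization.
#'
#' @slot orgs data.frame with character columns \code{org_id} (unique),
#'   \code{name}, \code{sector}, \code{tasks} (";"-separated subset of
#'   gatekeeper/signaling/providing_services), \code{respondent_ids}
#'   (";"-separated, unique across the roster), plus any number of numeric
#'   attribute columns.
#' @export
setClass("Roster", representation(orgs = "data.frame"))

setValidity("Roster", function(object) {
  df <- object@orgs
  need <- c("org_id", "name", "sector", "tasks", "respondent_ids")
  if (!all(need %in% names(df)))
    return(paste("roster must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$org_id))
    return("org_id values must be unique")
  if (any(is.na(df$sector) | !nzchar(df$sector)))
    return("every organization must have a nonempty sector")
  tk <- unlist(strsplit(df$tasks[nzchar(df$tasks)], ";", fixed = TRUE))
  if (length(tk) && !all(tk %in% .TASKS))
    return(paste("unknown task label(s):",
                 paste(unique(setdiff(tk, .TASKS)), collapse = ", ")))
  rid <- unlist(strsplit(df$respondent_ids[nzchar(df$respondent_ids)],
                         ";", fixed = TRUE))
  if (anyDuplicated(rid))
    return("respondent ids must be unique across the roster")
  TRUE
})

#' Respondent-level tie reports
#'
#' Raw survey claims, one row per (respondent, named organization, layer):
#' the respondent's organization reports a contact or client-referral tie to
#' the target organization.  Directed (reporter to target); validated against
#' a roster at construction.
#'
#' @slot records data.frame with character columns \code{respondent_id},
#'   \code{reporter_org}, \code{target_org}, \code{layer} (one of
#'   \code{"contact"}, \code{"referral"}).
#' @export
setClass("TieReportSet", representation(records = "data.frame"))

setValidity("TieReportSet", function(object) {
  df <- object@records
  need <- c("respondent_id", "reporter_org", "target_org", "layer")
  if (!all(need %in% names(df)))
    return(paste("reports must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (!all(df$layer %in% .LAYERS))
    return(paste("unknown layer label(s):",
                 paste(unique(setdiff(df$layer, .LAYERS)), collapse = ", ")))
  if (any(df$reporter_org == df$target_org))
    return("self-reports (reporter_org == target_org) are not allowed")
  TRUE
})

#' Organization-level directed report matrix
#'
#' The respondent reports of one layer collapsed to the organization level:
#' cell (i, j) = 1 iff at least one respondent of organization i reported a
#' tie to organization j.  The \code{responded} mask records which rows come
#' from at least one responding boundary spanner, so an all-negative response
#' is distinguishable from nonresponse.  After labeled reconstruction,
#' imputed cells are flagged in \code{reconstructed}.
#'
#' @slot mat square integer 0/1 matrix, org_id dimnames, zero diagonal.
#' @slot responded named logical vector, one entry per organization.
#' @slot reconstructed logical matrix of the same shape flagging cells filled
#'   in by labeled reconstruction (all FALSE straight after collapsing).
#' @slot layer "contact" or "referral".
#' @export
setClass("ReportMatrix",
         representation(mat = "matrix", responded = "logical",
                        reconstructed = "matrix", layer = "character"))

setValidity("ReportMatrix", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must carry identical org_id row and column names")
  if (!all(m %in% c(0L, 1L))) return("entries must be 0/1")
  if (any(diag(m) != 0)) return("diagonal must be zero")
  if (length(object@responded) != nrow(m) ||
      !identical(names(object@responded), rownames(m)))
    return("responded mask must be named per organization")
  if (!identical(dim(object@reconstructed), dim(m)))
    return("reconstructed flags must match the matrix shape")
  if (!identical(object@layer, "contact") &&
      !identical(object@layer, "referral"))
    return("layer must be 'contact' or 'referral'")
  ## a nonresponding row may only carry values put there by reconstruction
  bad <- !object@responded & (rowSums(m * !object@reconstructed) > 0)
  if (any(bad))
    return(paste("nonresponding row(s) with unreconstructed entries:",
                 paste(rownames(m)[bad], collapse = ", ")))
  TRUE
})

#' Analysis-ready symmetric adjacency
#'
#' The undirected organization network of one layer, after labeled
#' reconstruction and any-link union symmetrization.  Cell provenance is
#' "observed" when at least one endpoint organization responded and
#' "reconstructed" when neither did (such dyads are unrecoverable and fixed
#' at 0).
#'
#' @slot mat square symmetric integer 0/1 matrix, zero diagonal, org_id
#'   dimnames.
#' @slot layer "contact" or "referral".
#' @slot provenance character matrix, entries "observed"/"reconstructed".
#' @slot responded named logical vector carried through from the reports.
#' @export
setClass("Adjacency",
         representation(mat = "matrix", layer = "character",
                        provenance = "matrix", responded = "logical"))

setValidity("Adjacency", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must carry identical org_id row and column names")
  if (!all(m %in% c(0L, 1L))) return("entries must be 0/1")
  if (any(diag(m) != 0)) return("diagonal must be zero")
  if (!identical(m, t(m))) return("adjacency must be symmetric")
  if (!identical(dim(object@provenance), dim(m)))
    return("provenance must match the matrix shape")
  if (!all(object@provenance %in% c("observed", "reconstructed")))
    return("provenance entries must be 'observed' or 'reconstructed'")
  TRUE
})

#' Integration metric panel
#'
#' The per-network-per-layer quantity set used to compare network
#' integration: counts of organizations, sectors, active organizations and
#' isolates, the ordered-pair tie count, density, average degree and Freeman
#' degree centralization.
#'
#' @slot n_orgs,n_sectors,active_orgs,isolates,ties_ordered integer counts
#'   (\code{n_sectors} is NA when no roster was supplied).
#' @slot active_pct integer percentage of active organizations.
#' @slot density,avg_degree,centralization numeric; centralization is NA for
#'   n < 3.
#' @slot layer,network character labels.
#' @export
setClass("MetricsPanel",
         representation(n_orgs = "integer", n_sectors = "integer",
                        active_orgs = "integer", active_pct = "integer",
                        isolates = "integer", ties_ordered = "integer",
                        density = "numeric", avg_degree = "numeric",
                        centralization = "numeric",
                        layer = "character", network = "character"))

setValidity("MetricsPanel", function(object) {
  if (object@active_orgs + object@isolates != object@n_orgs)
    return("active_orgs + isolates must equal n_orgs")
  if (object@ties_ordered %% 2L != 0L)
    return("ordered tie count must be even")
  if (!is.na(object@centralization) &&
      (object@centralization < 0 || object@centralization > 1))
    return("centralization must lie in [0, 1]")
  TRUE
})

#' Sector-level graph with strength coding
#'
#' An organization adjacency aggregated to the sector level: for each
#' unordered sector pair the number of possible and present inter-sector
#' ties, the realized fraction, and its fourfold strength code (0 none,
#' 1 weak, 2 average, 3 strong).  Within-sector fractions are computed and
#' held separately.
#'
#' @slot pairs data.frame: sector_a, sector_b, possible, present, fraction,
#'   strength (between-sector, sector_a < sector_b).
#' @slot within data.frame: sector, possible, present, fraction, strength.
#' @slot layer character layer label.
#' @export
setClass("SectorGraph",
         representation(pairs = "data.frame", within = "data.frame",
                        layer = "character"))

setValidity("SectorGraph", function(object) {
  for (df in list(object@pairs, object@within)) {
    if (nrow(df) == 0) next
    if (any(df$present > df$possible))
      return("present ties cannot exceed possible ties")
    if (any(df$fraction < 0 | df$fraction > 1))
      return("fractions must lie in [0, 1]")
    if (!all(df$strength %in% 0:3))
      return("strength codes must be 0, 1, 2 or 3")
  }
  TRUE
})

#' Synthetic survey configuration
#'
#' Parameters of the synthetic roster/survey generator: network size, sector
#' composition and task scheme, survey response rate, the core-periphery
#' block-model tie probabilities, the probability that a contact tie also
#' carries client referral, which sectors get multiple boundary spanners,
#' and the RNG seed.
#'
#' @slot n_orgs integer >= 2.
#' @slot sector_weights named numeric, probabilities summing to 1.
#' @slot task_assignment named list: sector -> character vector of tasks.
#' @slot response_rate,hub_fraction,p_core_core,p_core_periphery,p_periphery_periphery,referral_retention,extra_obs_prob,report_noise
#'   probabilities in [0, 1].
#' @slot multi_respondent_sectors character vector of sector labels that
#'   receive 2-5 boundary spanners.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
         representation(n_orgs = "integer", sector_weights = "numeric",
                        task_assignment = "list", response_rate = "numeric",
                        hub_fraction = "numeric", p_core_core = "numeric",
                        p_core_periphery = "numeric",
                        p_periphery_periphery = "numeric",
                        referral_retention = "numeric",
                        extra_obs_prob = "numeric", report_noise = "numeric",
                        multi_respondent_sectors = "character",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@n_orgs < 2L) return("n_orgs must be at least 2")
  w <- object@sector_weights
  if (length(w) == 0 || is.null(names(w)) || any(!nzchar(names(w))))
    return("sector_weights must be a nonempty named vector")
  if (any(w < 0)) return("sector weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) return("sector weights must sum to 1")
  if (!all(names(w) %in% names(object@task_assignment)))
    return("every sector needs a task assignment")
  probs <- c(object@response_rate, object@hub_fraction, object@p_core_core,
             object@p_core_periphery, object@p_periphery_periphery,
             object@referral_retention, object@extra_obs_prob,
             object@report_noise)
  if (any(is.na(probs) | probs < 0 | probs > 1))
    return("all probabilities must lie in [0, 1]")
  TRUE
})

#' Ground-truth networks behind a synthetic survey
#'
#' The latent undirected networks a synthetic survey reports on: one
#' symmetric 0/1 matrix per layer (referral an entrywise subset of contact)
#' and the core/periphery flag per organization.
#'
#' @slot contact,referral square symmetric integer 0/1 matrices, zero
#'   diagonal, org_id dimnames.
#' @slot core named logical: TRUE for core (hub-block) organizations.
#' @export
setClass("GroundTruth",
         representation(contact = "matrix", referral = "matrix",
                        core = "logical"))

setValidity("GroundTruth", function(object) {
  for (m in list(object@contact, object@referral)) {
    if (!identical(m, t(m))) return("layers must be symmetric")
    if (any(diag(m) != 0)) return("diagonals must be zero")
    if (!all(m %in% c(0L, 1L))) return("entries must be 0/1")
  }
  if (any(object@referral > object@contact))
    return("referral layer must be an entrywise subset of the contact layer")
  if (!identical(names(object@core), rownames(object@contact)))
    return("core flags must be named per organization")
  TRUE
})

#' Cross-network comparison report
#'
#' The end product of the pipeline: per network and layer a
#' \linkS4class{MetricsPanel}, a ranked centrality table and a
#' \linkS4class{SectorGraph}, plus a cross-network table (columns = networks,
#' rows = metrics) mirroring the usual side-by-side presentation.
#'
#' @slot networks named list, one entry per network with elements
#'   \code{roster}, \code{layers} (named list of per-layer results) and
#'   \code{log}.
#' @slot tables named list of cross-network data.frames, one per layer.
#' @slot seed integer seed the run used.
#' @export
setClass("ComparisonReport",
         representation(networks = "list", tables = "list", seed = "integer"))
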