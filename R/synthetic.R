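#' Default sector scheme of a child service delivery network
#'
#' The eleven-sector composition and task division typical of Dutch child
#' and youth service delivery networks, with a skewed weight vector in which
#' specialized youth care providers dominate the roster (as they do
#' empirically) while gatekeeping front-office sectors are small.
#'
#' @return data.frame with columns \code{sector}, \code{weight},
#'   \code{tasks} (";"-separated).
#' @export
defaultSectorTable <- function() {
  data.frame(
    sector = c("center_for_youth_and_family", "municipality",
               "basic_social_organization", "education",
               "general_practitioners", "health_and_prevention",
               "childcare_and_nursery", "specialized_youth_care",
               "protection_and_social_rehabilitation", "safety",
               "volunteer_organization"),
    weight = c(0.02, 0.05, 0.07, 0.12, 0.10, 0.03, 0.08, 0.40, 0.05, 0.06,
               0.02),
    tasks = c("gatekeeper", "signaling", "signaling;providing_services",
              "signaling", "gatekeeper", "signaling;gatekeeper",
              "signaling;providing_services", "providing_services",
              "providing_services", "signaling;providing_services",
              "signaling;providing_services"),
    stringsAsFactors = FALSE)
}

#' Configure the synthetic survey generator
#'
#' The generator emulates a whole-network survey of an interorganizational
#' service delivery system: a roster of 65-135 organizations across up to 11
#' sectors, a latent core-periphery contact network, a referral layer that is
#' a subset of the contact layer, partial survey response, and
#' multi-respondent organizations whose boundary spanners each see only part
#' of their organization's ties.
#'
#' @param n_orgs number of organizations (>= 2).
#' @param sector_weights named probability vector over sector labels (sums
#'   to 1); defaults to \code{defaultSectorTable()}.
#' @param task_assignment named list sector -> character vector of tasks.
#' @param response_rate probability that an invited boundary spanner
#'   responds; default 0.57, the midpoint of typical 52-68\% response.
#' @param hub_fraction fraction of organizations placed in the core block.
#' @param p_core_core,p_core_periphery,p_periphery_periphery Bernoulli tie
#'   probabilities of the two-block contact model.
#' @param referral_retention probability that a contact tie also carries
#'   client referral.
#' @param extra_obs_prob probability that a non-primary boundary spanner of a
#'   multi-respondent organization observes any given incident tie (the
#'   primary respondent always sees the full row, so OR-aggregation is
#'   exercised without losing ties).
#' @param report_noise probability of a false-positive contact claim per
#'   respondent and non-adjacent organization (default 0: respondents report
#'   only true ties).
#' @param multi_respondent_sectors sectors whose members have limited working
#'   areas and therefore get 2-5 boundary spanners each.
#' @param seed integer RNG seed; every generator call is deterministic given
#'   the seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_orgs = 100L,
                            sector_weights = NULL,
                            task_assignment = NULL,
                            response_rate = 0.57,
                            hub_fraction = 0.10,
                            p_core_core = 0.90,
                            p_core_periphery = 0.50,
                            p_periphery_periphery = 0.08,
                            referral_retention = 0.65,
                            extra_obs_prob = 0.8,
                            report_noise = 0,
                            multi_respondent_sectors = c(
                              "general_practitioners", "education",
                              "childcare_and_nursery", "municipality"),
                            seed = 1L) {
  tab <- defaultSectorTable()
  if (is.null(sector_weights))
    sector_weights <- stats::setNames(tab$weight, tab$sector)
  if (is.null(task_assignment))
    task_assignment <- stats::setNames(
      strsplit(tab$tasks, ";", fixed = TRUE), tab$sector)
  new("SyntheticConfig",
      n_orgs = as.integer(n_orgs), sector_weights = sector_weights,
      task_assignment = task_assignment, response_rate = response_rate,
      hub_fraction = hub_fraction, p_core_core = p_core_core,
      p_core_periphery = p_core_periphery,
      p_periphery_periphery = p_periphery_periphery,
      referral_retention = referral_retention,
      extra_obs_prob = extra_obs_prob, report_noise = report_noise,
      multi_respondent_sectors = multi_respondent_sectors,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: n_orgs=", object@n_orgs, ", ",
      length(object@sector_weights), " sectors, response_rate=",
      object@response_rate, ", blocks (", object@p_core_core, "/",
      object@p_core_periphery, "/", object@p_periphery_periphery,
      "), referral_retention=", object@referral_retention,
      ", seed=", object@seed, "\n", sep = "")
})

## Largest-remainder apportionment of n organizations over sector weights:
## the sector mix is the design composition of the network, so it is fixed
## given the weights rather than redrawn per seed.
.apportion <- function(weights, n) {
  quota <- weights * n
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic organization roster
#'
#' Sector counts are apportioned deterministically from the configured
#' weights; tasks follow the sector task scheme; sectors listed in
#' \code{multi_respondent_sectors} receive 2-5 boundary spanners, the rest
#' exactly one; a skewed clients-in-treatment attribute is attached for
#' boundary-threshold exercises.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{Roster}.
#' @export
generateRoster <- function(config) {
  validObject(config)
  set.seed(config@seed)
  w <- config@sector_weights
  counts <- .apportion(w, config@n_orgs)
  sector <- rep(names(w), counts)
  n <- length(sector)
  org_id <- sprintf("org%03d", seq_len(n))
  name <- paste0(sector, "_", stats::ave(seq_len(n), sector, FUN = seq_along))
  tasks <- vapply(config@task_assignment[sector],
                  function(v) paste(v, collapse = ";"), "")
  nresp <- ifelse(sector %in% config@multi_respondent_sectors,
                  sample(2:5, n, replace = TRUE), 1L)
  respondent_ids <- vapply(seq_len(n), function(i)
    paste(sprintf("%s_r%d", org_id[i], seq_len(nresp[i])), collapse = ";"),
    "")
  clients <- 1L + stats::rnbinom(n, size = 1, mu = 30)
  Roster(org_id = org_id, name = name, sector = sector, tasks = tasks,
         respondent_ids = respondent_ids,
         attributes = data.frame(clients_2017 = clients))
}

## Core designation: gatekeeper-task organizations first (front-office
## sectors are the empirical hubs), then roster order, until the configured
## core size is reached.
.core_flags <- function(roster, config) {
  ids <- orgIds(roster)
  k <- max(1L, round(config@hub_fraction * length(ids)))
  gk <- vapply(orgTasks(roster), function(v) "gatekeeper" %in% v, TRUE)
  pick <- ids[order(!gk)][seq_len(min(k, length(ids)))]
  stats::setNames(ids %in% pick, ids)
}

#' Generate ground-truth contact and referral networks
#'
#' The contact layer is a two-block (core/periphery) Bernoulli graph with
#' the configured block probabilities; the referral layer retains each
#' contact tie independently with probability \code{referral_retention}.
#' Both layers are symmetric with zero diagonal, and referral is an
#' entrywise subset of contact by construction.
#'
#' @param roster the \linkS4class{Roster} the networks live on.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{GroundTruth}.
#' @export
generateTruth <- function(roster, config) {
  validObject(config)
  stopifnot(nOrgs(roster) > 0)
  set.seed(config@seed + 1L)
  ids <- orgIds(roster)
  n <- length(ids)
  core <- .core_flags(roster, config)
  contact <- matrix(0L, n, n, dimnames = list(ids, ids))
  referral <- contact
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- if (core[i] && core[j]) config@p_core_core
           else if (core[i] || core[j]) config@p_core_periphery
           else config@p_periphery_periphery
      if (stats::runif(1) < p) {
        contact[i, j] <- contact[j, i] <- 1L
        if (stats::runif(1) < config@referral_retention)
          referral[i, j] <- referral[j, i] <- 1L
      }
    }
  }
  new("GroundTruth", contact = contact, referral = referral, core = core)
}

#' @rdname adjMatrix
#' @param layer for \linkS4class{GroundTruth}: "contact" or "referral".
#' @export
setMethod("adjMatrix", "GroundTruth", function(x, layer = "contact", ...) {
  slot(x, match.arg(layer, .LAYERS))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth on", nrow(object@contact), "organizations:",
      sum(object@contact) / 2, "contact edges,",
      sum(object@referral) / 2, "referral edges,",
      sum(object@core), "core\n")
})

#' Expected contact density of the block model
#'
#' Closed-form expectation of the contact-layer density under the
#' core-periphery Bernoulli model, from the block sizes and probabilities.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param n optionally override the number of organizations.
#' @return expected density (ordered-pair convention, identical to the
#'   undirected one).
#' @export
expectedContactDensity <- function(config, n = config@n_orgs) {
  k <- max(1L, round(config@hub_fraction * n))
  ncc <- k * (k - 1)
  ncp <- 2 * k * (n - k)
  npp <- (n - k) * (n - k - 1)
  (ncc * config@p_core_core + ncp * config@p_core_periphery +
     npp * config@p_periphery_periphery) / (n * (n - 1))
}

#' Simulate the survey reports over a ground truth
#'
#' Each boundary spanner responds independently with probability
#' \code{response_rate}.  A responding primary respondent reports every true
#' tie incident to their organization; additional respondents of
#' multi-respondent organizations observe each incident tie with probability
#' \code{extra_obs_prob}.  An observed tie is reported in the contact layer
#' and, if the ground truth carries referral on it, in the referral layer as
#' well.  With \code{report_noise > 0}, false-positive contact claims are
#' added at that rate.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param roster the matching \linkS4class{Roster}.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{reports} (a \linkS4class{TieReportSet}) and
#'   \code{responses} (data.frame \code{respondent_id}, \code{responded}),
#'   the separate response register that distinguishes an all-negative
#'   response from nonresponse.
#' @export
generateReports <- function(truth, roster, config) {
  validObject(config)
  stopifnot(identical(rownames(truth@contact), orgIds(roster)))
  set.seed(config@seed + 2L)
  rr <- rosterRespondents(roster)
  rr$responded <- as.integer(stats::runif(nrow(rr)) < config@response_rate)
  first_of_org <- !duplicated(rr$org_id)

  recs <- vector("list", nrow(rr))
  ids <- orgIds(roster)
  for (i in seq_len(nrow(rr))) {
    if (!rr$responded[i]) next
    org <- rr$org_id[i]
    targets <- ids[truth@contact[org, ] == 1L]
    if (!first_of_org[i] && length(targets))
      targets <- targets[stats::runif(length(targets)) < config@extra_obs_prob]
    if (config@report_noise > 0) {
      non <- setdiff(ids[truth@contact[org, ] == 0L], org)
      noise <- non[stats::runif(length(non)) < config@report_noise]
    } else noise <- character()
    if (!length(targets) && !length(noise)) next
    layer <- c(ifelse(truth@referral[org, targets] == 1L, "both", "contact"),
               rep("contact", length(noise)))
    tg <- c(targets, noise)
    both <- layer == "both"
    recs[[i]] <- data.frame(
      respondent_id = rr$respondent_id[i],
      reporter_org = org,
      target_org = c(tg, tg[both]),
      layer = c(rep("contact", length(tg)), rep("referral", sum(both))),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(records))
    records <- data.frame(respondent_id = character(),
                          reporter_org = character(),
                          target_org = character(), layer = character(),
                          stringsAsFactors = FALSE)
  list(reports = TieReportSet(records, roster),
       responses = rr[, c("respondent_id", "responded")])
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper chaining \code{\link{generateRoster}},
#' \code{\link{generateTruth}} and \code{\link{generateReports}}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{roster}, \code{truth}, \code{reports},
#'   \code{responses}.
#' @export
generateSurvey <- function(config) {
  roster <- generateRoster(config)
  truth <- generateTruth(roster, config)
  rep <- generateReports(truth, roster, config)
  list(roster = roster, truth = truth, reports = rep$reports,
       responses = rep$responses)
}
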