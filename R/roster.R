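.collapse_multi <- function(x) {
  if (is.list(x)) vapply(x, function(v) paste(v, collapse = ";"), "") else x
}

#' Build an organization roster
#'
#' @param org_id character vector of unique organization ids.
#' @param name organization display names (defaults to the ids).
#' @param sector sector label per organization.
#' @param tasks per-organization tasks: a list of character vectors or a
#'   character vector of ";"-separated labels drawn from
#'   \code{gatekeeper}, \code{signaling}, \code{providing_services}.
#' @param respondent_ids per-organization boundary-spanner ids: a list of
#'   character vectors or a ";"-separated character vector; must be unique
#'   across the whole roster.
#' @param attributes optional data.frame of numeric organization attributes
#'   (e.g. \code{clients_2017}), one row per organization.
#' @return a \linkS4class{Roster}.
#' @examples
#' Roster(org_id = c("a", "b"), sector = c("education", "education"),
#'        tasks = c("signaling", "signaling"),
#'        respondent_ids = c("r1", "r2"))
#' @export
Roster <- function(org_id, name = org_id, sector, tasks = "",
                   respondent_ids = "", attributes = NULL) {
  df <- data.frame(org_id = as.character(org_id),
                   name = as.character(name),
                   sector = as.character(sector),
                   tasks = .collapse_multi(tasks),
                   respondent_ids = .collapse_multi(respondent_ids),
                   stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    stopifnot(nrow(attributes) == nrow(df))
    df <- cbind(df, as.data.frame(attributes))
  }
  new("Roster", orgs = df)
}

#' @rdname Roster-class
#' @export
setMethod("nOrgs", "Roster", function(x) nrow(x@orgs))

#' @rdname Roster-class
#' @export
setMethod("orgIds", "Roster", function(x) x@orgs$org_id)

#' @rdname Roster-class
#' @export
setMethod("orgSectors", "Roster",
          function(x) stats::setNames(x@orgs$sector, x@orgs$org_id))

#' @rdname Roster-class
#' @export
setMethod("orgTasks", "Roster", function(x) {
  stats::setNames(strsplit(x@orgs$tasks, ";", fixed = TRUE), x@orgs$org_id)
})

#' @rdname Roster-class
#' @export
setMethod("rosterRespondents", "Roster", function(x) {
  per <- strsplit(x@orgs$respondent_ids, ";", fixed = TRUE)
  per <- lapply(per, function(v) v[nzchar(v)])
  data.frame(respondent_id = unlist(per),
             org_id = rep(x@orgs$org_id, lengths(per)),
             stringsAsFactors = FALSE)
})

#' Numeric attribute of every organization
#'
#' @param roster a \linkS4class{Roster}.
#' @param attribute attribute (column) name.
#' @return named numeric vector (NA where the attribute is absent).
#' @export
orgAttribute <- function(roster, attribute) {
  df <- roster@orgs
  if (!attribute %in% names(df))
    return(stats::setNames(rep(NA_real_, nrow(df)), df$org_id))
  stats::setNames(as.numeric(df[[attribute]]), df$org_id)
}

setMethod("show", "Roster", function(object) {
  df <- object@orgs
  cat("Roster of", nrow(df), "organizations across",
      length(unique(df$sector)), "sectors;",
      nrow(rosterRespondents(object)), "boundary-spanner respondents\n")
  tab <- sort(table(df$sector), decreasing = TRUE)
  cat("  sectors:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
})

#' Drop small organizations of targeted sectors
#'
#' Boundary-specification filter: within the targeted sectors, organizations
#' whose numeric attribute falls below the minimum are removed from the
#' roster (the classic case being specialized-care providers with only a
#' handful of clients in treatment in a year).  Organizations outside the
#' targeted sectors are untouched.
#'
#' @param roster a \linkS4class{Roster}.
#' @param attribute name of the numeric attribute to threshold on.
#' @param minimum organizations with \code{attribute < minimum} are dropped.
#' @param sectors character vector of sector labels to filter; sectors not
#'   listed are exempt.  An empty vector leaves the roster unchanged.
#' @return the filtered \linkS4class{Roster}.
#' @export
applyThresholdFilter <- function(roster, attribute, minimum, sectors) {
  df <- roster@orgs
  if (length(sectors) == 0 || minimum <= 0) return(roster)
  target <- df$sector %in% sectors
  vals <- orgAttribute(roster, attribute)
  miss <- target & is.na(vals)
  if (any(miss))
    stop("attribute '", attribute, "' missing for targeted organization(s): ",
         paste(df$org_id[miss], collapse = ", "))
  keep <- !target | vals >= minimum
  new("Roster", orgs = df[keep, , drop = FALSE])
}

#' Differentiation summary of a roster
#'
#' Counts of organizations per sector and per task, and the number of
#' sectors present -- the composition side of a network comparison.
#'
#' @param roster a \linkS4class{Roster}.
#' @return list with \code{n_orgs}, \code{n_sectors}, \code{by_sector}
#'   (data.frame sector/n) and \code{by_task} (data.frame task/n; an
#'   organization with several tasks counts once per task).
#' @export
summarizeDifferentiation <- function(roster) {
  stopifnot(nOrgs(roster) > 0)
  sec <- table(roster@orgs$sector)
  tk <- unlist(orgTasks(roster))
  tk <- tk[nzchar(tk)]
  list(n_orgs = nOrgs(roster),
       n_sectors = length(sec),
       by_sector = data.frame(sector = names(sec), n = as.integer(sec),
                              stringsAsFactors = FALSE),
       by_task = data.frame(task = names(table(tk)),
                            n = as.integer(table(tk)),
                            stringsAsFactors = FALSE))
}

#' Read / write a roster CSV
#'
#' The roster interchange format is a UTF-8 CSV with mandatory header and
#' columns \code{org_id,name,sector,tasks,respondent_ids} (multi-valued
#' fields ";"-separated) plus any numeric attribute columns.
#'
#' @param path file path.
#' @return \code{readRoster} returns a \linkS4class{Roster}.
#' @export
readRoster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  need <- c("org_id", "name", "sector", "tasks", "respondent_ids")
  if (!all(need %in% names(df)))
    stop("roster CSV must have columns: ", paste(need, collapse = ", "))
  for (col in need) df[[col]] <- as.character(df[[col]])
  df$tasks[is.na(df$tasks)] <- ""
  df$respondent_ids[is.na(df$respondent_ids)] <- ""
  new("Roster", orgs = df)
}

#' @rdname readRoster
#' @param roster a \linkS4class{Roster} to write.
#' @export
writeRoster <- function(roster, path) {
  utils::write.csv(roster@orgs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
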