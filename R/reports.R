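#' Build a validated tie-report set
#'
#' Wraps respondent-level survey claims and validates them against the
#' roster: both organizations must be on the roster, the respondent must be a
#' boundary spanner of the reporting organization, self-reports are rejected,
#' and layer labels must come from the closed set \{contact, referral\}.
#'
#' @param records data.frame with columns \code{respondent_id},
#'   \code{reporter_org}, \code{target_org}, \code{layer}.
#' @param roster the \linkS4class{Roster} the reports refer to.
#' @return a \linkS4class{TieReportSet}.
#' @export
TieReportSet <- function(records, roster) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    records <- data.frame(respondent_id = character(),
                          reporter_org = character(),
                          target_org = character(),
                          layer = character(), stringsAsFactors = FALSE)
    return(new("TieReportSet", records = records))
  }
  for (col in c("respondent_id", "reporter_org", "target_org", "layer"))
    records[[col]] <- as.character(records[[col]])
  ids <- orgIds(roster)
  bad <- setdiff(unique(c(records$reporter_org, records$target_org)), ids)
  if (length(bad))
    stop("report(s) name organization(s) absent from the roster: ",
         paste(bad, collapse = ", "))
  rr <- rosterRespondents(roster)
  owner <- stats::setNames(rr$org_id, rr$respondent_id)
  unknown <- setdiff(unique(records$respondent_id), names(owner))
  if (length(unknown))
    stop("unknown respondent id(s): ", paste(unknown, collapse = ", "))
  wrong <- owner[records$respondent_id] != records$reporter_org
  if (any(wrong))
    stop("respondent(s) reporting for an organization that is not theirs: ",
         paste(unique(records$respondent_id[wrong]), collapse = ", "))
  new("TieReportSet", records = records)
}

#' @rdname TieReportSet
#' @param x a \linkS4class{TieReportSet}.
#' @return \code{tieRecords} returns the records data.frame.
#' @export
tieRecords <- function(x) x@records

setMethod("show", "TieReportSet", function(object) {
  df <- object@records
  cat("TieReportSet:", nrow(df), "directed claims from",
      length(unique(df$respondent_id)), "respondents (",
      sum(df$layer == "contact"), "contact /",
      sum(df$layer == "referral"), "referral )\n")
})

#' Drop reports that reference organizations no longer on the roster
#'
#' Used after boundary filtering: claims by or about removed organizations,
#' and claims by respondents of removed organizations, are discarded.
#'
#' @param reports a \linkS4class{TieReportSet}.
#' @param roster the (possibly filtered) \linkS4class{Roster}.
#' @return a re-validated \linkS4class{TieReportSet}.
#' @export
filterReports <- function(reports, roster) {
  df <- reports@records
  ids <- orgIds(roster)
  keep <- df$reporter_org %in% ids & df$target_org %in% ids
  TieReportSet(df[keep, , drop = FALSE], roster)
}

#' Collapse respondents to the organization level
#'
#' Applies the aggregation rule for multi-respondent organizations: the
#' directed organization-level report cell (i, j) is 1 iff at least one
#' boundary spanner of organization i reported a tie of the given layer to
#' organization j (logical OR across respondents).  An organization counts
#' as responded iff at least one of its respondents responded to the
#' questionnaire at all; the \code{responses} table makes an all-negative
#' response distinguishable from nonresponse.
#'
#' @param roster a \linkS4class{Roster}.
#' @param reports a \linkS4class{TieReportSet} validated against the roster.
#' @param layer "contact" or "referral".
#' @param responses optional data.frame (\code{respondent_id},
#'   \code{responded} 0/1).  When omitted, a respondent is taken to have
#'   responded iff they submitted at least one tie record in any layer.
#' @return a \linkS4class{ReportMatrix}.
#' @export
collapseRespondents <- function(roster, reports, layer, responses = NULL) {
  if (!layer %in% .LAYERS)
    stop("unknown layer '", layer, "'; must be one of: ",
         paste(.LAYERS, collapse = ", "))
  ids <- orgIds(roster)
  df <- reports@records
  rr <- rosterRespondents(roster)

  if (is.null(responses)) {
    resp_ids <- unique(df$respondent_id)
  } else {
    responses$respondent_id <- as.character(responses$respondent_id)
    unknown <- setdiff(responses$respondent_id, rr$respondent_id)
    if (length(unknown))
      stop("responses table names unknown respondent(s): ",
           paste(unknown, collapse = ", "))
    resp_ids <- responses$respondent_id[responses$responded != 0]
    ghost <- setdiff(unique(df$respondent_id), resp_ids)
    if (length(ghost))
      stop("tie records from respondent(s) marked as nonresponding: ",
           paste(ghost, collapse = ", "))
  }
  responded <- stats::setNames(ids %in% rr$org_id[rr$respondent_id %in% resp_ids],
                               ids)

  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  sel <- df[df$layer == layer, , drop = FALSE]
  if (nrow(sel))
    m[cbind(sel$reporter_org, sel$target_org)] <- 1L
  diag(m) <- 0L
  new("ReportMatrix", mat = m, responded = responded,
      reconstructed = matrix(FALSE, length(ids), length(ids),
                             dimnames = list(ids, ids)),
      layer = layer)
}

#' @describeIn collapseRespondents accessor for the directed 0/1 matrix.
#' @param x a \linkS4class{ReportMatrix}.
#' @param ... unused.
#' @export
setMethod("adjMatrix", "ReportMatrix", function(x, ...) x@mat)

#' @rdname responded
#' @export
setMethod("responded", "ReportMatrix", function(x) x@responded)

#' @rdname layerLabel
#' @export
setMethod("layerLabel", "ReportMatrix", function(x) x@layer)

setMethod("show", "ReportMatrix", function(object) {
  cat("ReportMatrix (", object@layer, "): ", nrow(object@mat),
      " organizations, ", sum(object@mat), " directed reports, ",
      sum(object@responded), " responding organizations (",
      round(100 * mean(object@responded)), "%)\n", sep = "")
})

#' Read / write respondent-level tie reports
#'
#' CSV edge-list interchange with mandatory header and columns
#' \code{respondent_id,reporter_org,target_org,layer}.
#'
#' @param path file path.
#' @param roster roster to validate against.
#' @return \code{readTieReports} returns a \linkS4class{TieReportSet}.
#' @export
readTieReports <- function(path, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  TieReportSet(df, roster)
}

#' @rdname readTieReports
#' @param reports a \linkS4class{TieReportSet} to write.
#' @export
writeTieReports <- function(reports, path) {
  utils::write.csv(reports@records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname readTieReports
#' @return \code{readResponses} returns a data.frame
#'   (\code{respondent_id}, \code{responded}).
#' @export
readResponses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("respondent_id", "responded") %in% names(df)))
    stop("responses CSV must have columns respondent_id, responded")
  df$respondent_id <- as.character(df$respondent_id)
  df$responded <- as.integer(df$responded)
  df
}
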