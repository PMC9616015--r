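#' @rdname Roster-class
#' @param object,x an orgnet object
#' @export
setGeneric("nOrgs", function(x) standardGeneric("nOrgs"))

#' @rdname Roster-class
#' @export
setGeneric("orgIds", function(x) standardGeneric("orgIds"))

#' @rdname Roster-class
#' @export
setGeneric("orgSectors", function(x) standardGeneric("orgSectors"))

#' @rdname Roster-class
#' @export
setGeneric("orgTasks", function(x) standardGeneric("orgTasks"))

#' @rdname Roster-class
#' @export
setGeneric("rosterRespondents", function(x) standardGeneric("rosterRespondents"))

#' Extract the underlying 0/1 matrix
#' @param x a \linkS4class{ReportMatrix}, \linkS4class{Adjacency} or
#'   \linkS4class{GroundTruth} (for the latter, pass \code{layer}).
#' @param ... passed on to methods.
#' @return an integer matrix with org_id dimnames.
#' @export
setGeneric("adjMatrix", function(x, ...) standardGeneric("adjMatrix"))

#' Which organizations responded?
#' @param x a \linkS4class{ReportMatrix} or \linkS4class{Adjacency}.
#' @return named logical vector.
#' @export
setGeneric("responded", function(x) standardGeneric("responded"))

#' Relational layer label
#' @param x an object carrying a layer ("contact" or "referral").
#' @export
setGeneric("layerLabel", function(x) standardGeneric("layerLabel"))
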