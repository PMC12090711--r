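#' PresenceMatrix: OG presence/absence across strains
#'
#' S4 container for a gene presence/absence table in the shape produced by
#' pangenome tools such as Roary: one row per orthologous gene group (OG),
#' one column per strain, \code{TRUE} where the strain carries a member of
#' the OG.
#'
#' @slot present logical matrix, OGs in rows (rownames = OG identifiers),
#'   strains in columns (colnames = strain identifiers).
#' @slot annotation character vector of per-OG free-text annotations,
#'   parallel to the rows (may be empty).
#'
#' @seealso [readPresenceAbsence()], [writePresenceAbsence()]
#' @importClassesFrom Biostrings AAStringSet
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
  representation(present = "matrix", annotation = "character"))

setValidity("PresenceMatrix", function(object) {
  m <- object@present
  msg <- character()
  if (!is.logical(m)) msg <- c(msg, "'present' must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "'present' must carry OG rownames and strain colnames")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate OG identifiers")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate strain identifiers")
  }
  if (length(object@annotation) && length(object@annotation) != nrow(m))
    msg <- c(msg, "'annotation' length must match the number of OGs")
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param present logical matrix (OG x strain) with dimnames.
#' @param annotation optional character vector of per-OG annotations.
#' @return A [PresenceMatrix-class] object.
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
#'             dimnames = list(c("og1", "og2"), c("s1", "s2")))
#' PresenceMatrix(m)
#' @export
PresenceMatrix <- function(present, annotation = character()) {
  storage.mode(present) <- "logical"
  new("PresenceMatrix", present = present, annotation = annotation)
}

#' OgFamily: one orthologous gene group's member sequences
#'
#' Holds the amino-acid sequences of one OG, one sequence per member strain
#' (paralogs are resolved at read time; see [readOgSequences()]).
#'
#' @slot ogId single OG identifier.
#' @slot members [Biostrings::AAStringSet] named by strain identifier.
#' @slot aligned logical flag; \code{TRUE} when all members have equal
#'   length (gapped alignment columns are allowed).
#'
#' @exportClass OgFamily
setClass("OgFamily",
  representation(ogId = "character", members = "AAStringSet",
                 aligned = "logical"))

setValidity("OgFamily", function(object) {
  msg <- character()
  if (length(object@ogId) != 1L || !nzchar(object@ogId))
    msg <- c(msg, "'ogId' must be a single non-empty string")
  nm <- names(object@members)
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "members must be named by strain identifier")
  else if (anyDuplicated(nm))
    msg <- c(msg, "duplicate member strain identifiers")
  if (length(object@members) && any(width(object@members) == 0L))
    msg <- c(msg, "member sequences must be non-empty")
  if (isTRUE(object@aligned) && length(object@members) &&
      length(unique(width(object@members))) != 1L)
    msg <- c(msg, "'aligned' families must have equal-length members")
  if (length(msg)) msg else TRUE
})

#' Construct an OgFamily
#'
#' @param ogId OG identifier.
#' @param members named character vector or [Biostrings::AAStringSet] of
#'   member amino-acid sequences; names are strain identifiers.
#' @param aligned logical; if \code{NA} (default) it is inferred: a family
#'   is flagged aligned when all members have equal length.
#' @return An [OgFamily-class] object.
#' @examples
#' OgFamily("og1", c(s1 = "AAAA", s2 = "AAAT"))
#' @export
OgFamily <- function(ogId, members, aligned = NA) {
  if (!is(members, "AAStringSet")) members <- AAStringSet(members)
  if (is.na(aligned))
    aligned <- length(members) > 0L && length(unique(width(members))) == 1L
  new("OgFamily", ogId = as.character(ogId), members = members,
      aligned = isTRUE(aligned))
}

#' PhenotypeGroups: the active/silent split for one comparison
#'
#' Result of the median-split classification of strains for one
#' (species, cytokine) comparison: the median of per-strain mean cytokine
#' levels and the disjoint active / silent strain sets.
#'
#' @slot species species label of the comparison.
#' @slot cytokine cytokine label (e.g. \code{"IL10"}, \code{"IL12"}).
#' @slot median median cytokine level (pg/mL) used as the threshold.
#' @slot active strain identifiers at or above the threshold.
#' @slot silent strain identifiers below the threshold.
#' @slot degenerate \code{TRUE} when one side is empty (e.g. all means
#'   identical); downstream screening refuses degenerate groups.
#'
#' @seealso [classifyActiveSilent()]
#' @exportClass PhenotypeGroups
setClass("PhenotypeGroups",
  representation(species = "character", cytokine = "character",
                 median = "numeric", active = "character",
                 silent = "character", degenerate = "logical"))

setValidity("PhenotypeGroups", function(object) {
  msg <- character()
  if (length(intersect(object@active, object@silent)))
    msg <- c(msg, "active and silent sets must be disjoint")
  if (anyDuplicated(object@active) || anyDuplicated(object@silent))
    msg <- c(msg, "duplicate strain identifiers within a group")
  if (length(object@median) != 1L) msg <- c(msg, "'median' must be scalar")
  if (length(msg)) msg else TRUE
})

#' ScreenResult: the full screen output for one comparison
#'
#' Produced by [runScreen()]: all per-OG scores, the top-fraction candidate
#' list, per-candidate k-means labels and the recalculated-CH ranking.
#'
#' @slot species,cytokine comparison labels.
#' @slot scores data.frame of per-OG scores (see [writeScoreTable()] for the
#'   column contract).
#' @slot top OG identifiers selected into the top PG-index fraction, in
#'   selection order.
#' @slot kmeansLabels named list (per top OG) of integer cluster labels
#'   (1/2) named by strain.
#' @slot config the [screenConfig()] list used.
#'
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(species = "character", cytokine = "character",
                 scores = "data.frame", top = "character",
                 kmeansLabels = "list", config = "list"))

setValidity("ScreenResult", function(object) {
  if (!all(object@top %in% object@scores$og_id))
    "top candidates must be scored OGs" else TRUE
})
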