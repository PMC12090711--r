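#' @rdname PresenceMatrix-class
#' @param x,object a PGscreen S4 object.
#' @export
setGeneric("ogIds", function(x) standardGeneric("ogIds"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("isPresent", function(x) standardGeneric("isPresent"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname OgFamily-class
#' @export
setGeneric("ogId", function(x) standardGeneric("ogId"))

#' @rdname OgFamily-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname OgFamily-class
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' @rdname PhenotypeGroups-class
#' @export
setGeneric("activeStrains", function(x) standardGeneric("activeStrains"))

#' @rdname PhenotypeGroups-class
#' @export
setGeneric("silentStrains", function(x) standardGeneric("silentStrains"))

#' @rdname PhenotypeGroups-class
#' @export
setGeneric("groupMedian", function(x) standardGeneric("groupMedian"))

#' @rdname PhenotypeGroups-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname ScreenResult-class
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname ScreenResult-class
#' @export
setGeneric("topCandidates", function(x) standardGeneric("topCandidates"))

#' @rdname ScreenResult-class
#' @export
setGeneric("kmeansLabels", function(x) standardGeneric("kmeansLabels"))
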