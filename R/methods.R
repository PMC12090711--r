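#' @rdname PresenceMatrix-class
#' @export
setMethod("ogIds", "PresenceMatrix", function(x) rownames(x@present))

#' @rdname PresenceMatrix-class
#' @export
setMethod("strainIds", "PresenceMatrix", function(x) colnames(x@present))

#' @rdname PresenceMatrix-class
#' @export
setMethod("isPresent", "PresenceMatrix", function(x) x@present)

#' @rdname PresenceMatrix-class
#' @export
setMethod("annotations", "PresenceMatrix", function(x) {
  if (length(x@annotation)) setNames(x@annotation, rownames(x@present))
  else setNames(rep("", nrow(x@present)), rownames(x@present))
})

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@present
  cat(sprintf("PresenceMatrix: %d OGs x %d strains (%.1f%% present)\n",
              nrow(m), ncol(m), if (length(m)) 100 * mean(m) else 0))
  cat("  OGs:    ", paste(head(rownames(m), 4), collapse = ", "),
      if (nrow(m) > 4) ", ..." else "", "\n", sep = "")
  cat("  strains:", paste(head(colnames(m), 4), collapse = ", "),
      if (ncol(m) > 4) ", ..." else "", "\n", sep = "")
})

#' @rdname OgFamily-class
#' @export
setMethod("ogId", "OgFamily", function(x) x@ogId)

#' @rdname OgFamily-class
#' @export
setMethod("members", "OgFamily", function(x) x@members)

#' @rdname OgFamily-class
#' @export
setMethod("isAligned", "OgFamily", function(x) x@aligned)

#' @rdname OgFamily-class
#' @export
setMethod("strainIds", "OgFamily", function(x) names(x@members))

setMethod("show", "OgFamily", function(object) {
  cat(sprintf("OgFamily '%s': %d members%s\n", object@ogId,
              length(object@members),
              if (object@aligned)
                sprintf(", aligned (width %d)",
                        if (length(object@members)) width(object@members)[1]
                        else 0L)
              else ", unaligned"))
})

#' @rdname PhenotypeGroups-class
#' @export
setMethod("activeStrains", "PhenotypeGroups", function(x) x@active)

#' @rdname PhenotypeGroups-class
#' @export
setMethod("silentStrains", "PhenotypeGroups", function(x) x@silent)

#' @rdname PhenotypeGroups-class
#' @export
setMethod("groupMedian", "PhenotypeGroups", function(x) x@median)

#' @rdname PhenotypeGroups-class
#' @export
setMethod("isDegenerate", "PhenotypeGroups", function(x) x@degenerate)

#' @rdname PhenotypeGroups-class
#' @export
setMethod("strainIds", "PhenotypeGroups", function(x) c(x@active, x@silent))

setMethod("show", "PhenotypeGroups", function(object) {
  cat(sprintf("PhenotypeGroups %s / %s: median %.4g pg/mL, %d active, %d silent%s\n",
              object@species, object@cytokine, object@median,
              length(object@active), length(object@silent),
              if (object@degenerate) " [degenerate]" else ""))
})

#' @rdname ScreenResult-class
#' @export
setMethod("scoreTable", "ScreenResult", function(x) x@scores)

#' @rdname ScreenResult-class
#' @export
setMethod("topCandidates", "ScreenResult", function(x) x@top)

#' @rdname ScreenResult-class
#' @export
setMethod("kmeansLabels", "ScreenResult", function(x) x@kmeansLabels)

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult %s / %s: %d OGs scored, top fraction = %d candidates\n",
              object@species, object@cytokine, nrow(object@scores),
              length(object@top)))
  ranked <- object@scores[!is.na(object@scores$kmeans_rank), , drop = FALSE]
  if (nrow(ranked)) {
    ranked <- ranked[order(ranked$kmeans_rank), , drop = FALSE]
    cat("  recalculated-CH ranking: ",
        paste(head(ranked$og_id, 5), collapse = " > "), "\n", sep = "")
  }
})
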