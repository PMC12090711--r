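# Phenotype classification: duplicate ELISA reads -> per-strain means ->
# median-split active/silent groups, one split per (species, cytokine).

#' Mean of duplicate cytokine measurements
#'
#' Per-strain cytokine production is quantified as the arithmetic mean of
#' the two replicate ELISA reads.
#'
#' @param rep1,rep2 non-negative measurements (pg/mL); vectorised.
#' @return numeric vector of means.
#' @examples
#' summarizeDuplicates(4, 2)   # 3
#' @export
summarizeDuplicates <- function(rep1, rep2) {
  if (anyNA(rep1) || anyNA(rep2))
    stopf("validation error: missing replicate measurement")
  if (any(rep1 < 0) || any(rep2 < 0))
    stopf("validation error: negative cytokine measurement")
  (rep1 + rep2) / 2
}

#' Classify strains into active and silent groups
#'
#' For one (species, cytokine) comparison, strains whose mean cytokine
#' production is greater than or equal to the median across all strains of
#' the species are classified \emph{active}; the rest are \emph{silent}.
#' With two species and two cytokines this yields the four groups
#' "IL-10 active", "IL-10 silent", "IL-12 active", "IL-12 silent".
#'
#' @param phenotypes data.frame as returned by [readPhenotypes()].
#' @param species species label to subset on.
#' @param cytokine cytokine label (\code{"IL10"} or \code{"IL12"}).
#' @param strictGt if \code{TRUE}, classify active as strictly above the
#'   median instead of at-or-above.
#' @param pooledMedian if \code{TRUE}, threshold on the single per-species
#'   median pooled over both cytokines' per-strain means instead of the
#'   per-cytokine median.
#' @return A [PhenotypeGroups-class]. If one side of the split is empty
#'   (e.g. all means identical) the result is flagged degenerate and
#'   downstream screening refuses it.
#' @examples
#' ph <- data.frame(strain_id = rep(sprintf("s%d", 1:4), each = 2),
#'                  species = "L_plantarum",
#'                  cytokine = rep(c("IL10", "IL12"), 4),
#'                  rep1 = c(1, 5, 2, 5, 3, 5, 4, 5),
#'                  rep2 = c(1, 5, 2, 5, 3, 5, 4, 5))
#' ph$mean <- summarizeDuplicates(ph$rep1, ph$rep2)
#' classifyActiveSilent(ph, "L_plantarum", "IL10")
#' @export
classifyActiveSilent <- function(phenotypes, species, cytokine,
                                 strictGt = FALSE, pooledMedian = FALSE) {
  cytokine <- gsub("-", "", toupper(cytokine))
  sp <- phenotypes[phenotypes$species == species, , drop = FALSE]
  sub <- sp[sp$cytokine == cytokine, , drop = FALSE]
  if (nrow(sub) < 2L)
    stopf("need >= 2 strains of species '%s' with %s measurements",
          species, cytokine)
  if (anyDuplicated(sub$strain_id))
    stopf("validation error: duplicate strain rows for %s", cytokine)
  med <- if (pooledMedian) median(sp$mean) else median(sub$mean)
  act <- if (strictGt) sub$mean > med else sub$mean >= med
  groups <- new("PhenotypeGroups", species = species, cytokine = cytokine,
                median = med, active = sub$strain_id[act],
                silent = sub$strain_id[!act],
                degenerate = !any(act) || all(act))
  if (groups@degenerate)
    warnf("degenerate split for %s/%s: one group is empty", species, cytokine)
  groups
}

#' Tabulate phenotype groups for all comparisons
#'
#' Runs [classifyActiveSilent()] for every (species, cytokine) pair in the
#' table and returns a long data.frame suitable for writing to TSV
#' (columns \code{species, cytokine, median, strain_id, group}).
#'
#' @inheritParams classifyActiveSilent
#' @return data.frame, one row per (species, cytokine, strain).
#' @export
classifyAllComparisons <- function(phenotypes, strictGt = FALSE,
                                   pooledMedian = FALSE) {
  out <- list()
  for (sp in unique(phenotypes$species)) {
    for (cy in unique(phenotypes$cytokine[phenotypes$species == sp])) {
      g <- classifyActiveSilent(phenotypes, sp, cy, strictGt, pooledMedian)
      out[[paste(sp, cy)]] <- data.frame(
        species = sp, cytokine = cy, median = groupMedian(g),
        strain_id = c(activeStrains(g), silentStrains(g)),
        group = rep(c("active", "silent"),
                    c(length(activeStrains(g)), length(silentStrains(g)))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
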