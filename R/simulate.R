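# Synthetic pangenome generator. Emulates the data regime the screen
# assumes: ~30 strains of one species with right-skewed duplicate cytokine
# measurements, a core/accessory OG structure, "signal" OGs whose member
# sequences form two divergent allele clusters aligned with the active/
# silent median split of one designated cytokine (with occasional
# misassigned strains), and marker OGs defined only by presence pattern.
# Every OG draws from its own derived RNG stream, so adding OGs never
# perturbs sequences generated for earlier ones.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic-study configuration
#'
#' Defaults describe the emulated study conditions: 30 strains, 150 core +
#' 45 accessory + 1 signal + 4 marker OGs (199 OGs without planted
#' phenotype-linked sequence signal), 300-residue proteins, 1\% within-
#' cluster and 15\% between-cluster divergence for the planted alleles, 2\%
#' background diversity, lognormal cytokine means with median ~3.8 pg/mL,
#' and a 10\% chance that a planted allele disagrees with the strain's
#' phenotype group.
#'
#' @param nStrains number of strains (>= 4).
#' @param nCoreOgs,nAccessoryOgs,nSignalOgs,nMarkerOgs OG counts by class.
#' @param seqLength protein length in residues.
#' @param withinRate per-site substitution probability within an allele
#'   cluster of a signal OG.
#' @param betweenRate per-site divergence between the two planted allele
#'   ancestors.
#' @param backgroundRate per-site diversity of core/accessory/marker OGs.
#' @param accessoryPresenceProb per-strain presence probability of an
#'   accessory OG.
#' @param phenotypeLogMu,phenotypeLogSigma lognormal meanlog/sdlog of the
#'   per-strain cytokine means (pg/mL).
#' @param noiseFlipProb probability a signal OG's allele assignment
#'   disagrees with the strain's phenotype group.
#' @param markerActiveProb,markerSilentProb per-strain presence probability
#'   of a marker OG in active resp. silent strains (0.95 / 0.15: fractions
#'   >= 0.9 and <= 0.3 in expectation, clearing the 0.8 / 0.5 screen
#'   thresholds).
#' @param linkedCytokine cytokine whose median split drives the planted
#'   alleles and marker presence.
#' @param species species label written to the phenotype table.
#' @param seed master RNG seed.
#' @return named list of class \code{SimConfig}.
#' @export
simConfig <- function(nStrains = 30L, nCoreOgs = 150L, nAccessoryOgs = 45L,
                      nSignalOgs = 1L, nMarkerOgs = 4L, seqLength = 300L,
                      withinRate = 0.01, betweenRate = 0.15,
                      backgroundRate = 0.02, accessoryPresenceProb = 0.5,
                      phenotypeLogMu = log(3.8), phenotypeLogSigma = 1.0,
                      noiseFlipProb = 0.1, markerActiveProb = 0.95,
                      markerSilentProb = 0.15, linkedCytokine = "IL10",
                      species = "L_plantarum", seed = 1L) {
  rates <- c(withinRate, betweenRate, backgroundRate, accessoryPresenceProb,
             noiseFlipProb, markerActiveProb, markerSilentProb)
  if (any(rates < 0) || any(rates > 1))
    stopf("validation error: all rates/probabilities must lie in [0, 1]")
  if (nStrains < 4L) stopf("validation error: need >= 4 strains")
  if (nSignalOgs < 1L) stopf("validation error: need >= 1 signal OG")
  structure(list(nStrains = as.integer(nStrains),
                 nCoreOgs = as.integer(nCoreOgs),
                 nAccessoryOgs = as.integer(nAccessoryOgs),
                 nSignalOgs = as.integer(nSignalOgs),
                 nMarkerOgs = as.integer(nMarkerOgs),
                 seqLength = as.integer(seqLength),
                 withinRate = withinRate, betweenRate = betweenRate,
                 backgroundRate = backgroundRate,
                 accessoryPresenceProb = accessoryPresenceProb,
                 phenotypeLogMu = phenotypeLogMu,
                 phenotypeLogSigma = phenotypeLogSigma,
                 noiseFlipProb = noiseFlipProb,
                 markerActiveProb = markerActiveProb,
                 markerSilentProb = markerSilentProb,
                 linkedCytokine = gsub("-", "", toupper(linkedCytokine)),
                 species = species, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate the strain phenotype table
#'
#' Per strain and cytokine, the true mean is drawn
#' lognormal(\code{phenotypeLogMu}, \code{phenotypeLogSigma}) — right-skewed
#' pg/mL values on the scale of real ELISA panels — and the duplicate reads
#' are \code{mean * (1 +/- u)} with \code{u ~ Uniform(0, 0.05)}, so the
#' replicate mean reproduces the true mean exactly. Deterministic given the
#' configuration seed.
#'
#' @param config a [simConfig()].
#' @return data.frame with columns \code{strain_id, species, cytokine,
#'   rep1, rep2, mean}.
#' @export
simulatePhenotypes <- function(config = simConfig()) {
  set.seed(deriveSeed(config$seed, 0L))
  strains <- sprintf("S%03d", seq_len(config$nStrains))
  rows <- expand.grid(cytokine = c("IL10", "IL12"), strain_id = strains,
                      stringsAsFactors = FALSE)[, 2:1]
  mu <- rlnorm(nrow(rows), config$phenotypeLogMu, config$phenotypeLogSigma)
  u <- runif(nrow(rows), 0, 0.05)
  df <- data.frame(strain_id = rows$strain_id, species = config$species,
                   cytokine = rows$cytokine,
                   rep1 = mu * (1 + u), rep2 = mu * (1 - u),
                   stringsAsFactors = FALSE)
  df$mean <- summarizeDuplicates(df$rep1, df$rep2)
  df[order(df$strain_id, df$cytokine), , drop = FALSE]
}

#' Mutate a sequence at a fixed per-site rate
#'
#' Each site is substituted with probability \code{rate} by a uniformly
#' chosen \emph{different} residue from the 20-letter amino-acid alphabet
#' (so \code{rate = 1} changes every site).
#'
#' @param ancestor amino-acid sequence (character scalar).
#' @param rate per-site substitution probability in \[0, 1\].
#' @return mutated sequence (character scalar). Uses the current RNG state;
#'   seed beforehand for reproducibility.
#' @export
mutateSequence <- function(ancestor, rate) {
  if (rate < 0 || rate > 1) stopf("validation error: rate must be in [0, 1]")
  idx <- match(strsplit(ancestor, "", fixed = TRUE)[[1]], .AA20)
  out <- .mutateRows(matrix(idx, nrow = 1L), rate)
  paste(.AA20[out[1L, ]], collapse = "")
}

# internal: mutate an integer-coded matrix of sequences (rows) at `rate`;
# a hit residue moves by a uniform offset in 1..19 mod 20, i.e. uniformly
# to one of the 19 other residues.
.mutateRows <- function(idxMat, rate) {
  hit <- which(runif(length(idxMat)) < rate)
  if (length(hit)) {
    off <- sample.int(19L, length(hit), replace = TRUE)
    idxMat[hit] <- (idxMat[hit] - 1L + off) %% 20L + 1L
  }
  idxMat
}

# internal: integer-coded rows -> named character vector of sequences
.rowsToSeqs <- function(idxMat, strains) {
  setNames(vapply(seq_len(nrow(idxMat)),
                  function(i) paste(.AA20[idxMat[i, ]], collapse = ""),
                  character(1)), strains)
}

#' Simulate a pangenome with planted signal and marker OGs
#'
#' Generates core OGs (present in all strains, background diversity),
#' accessory OGs (per-strain presence draws, background diversity), signal
#' OGs (present everywhere; two ancestors at \code{betweenRate} divergence;
#' each strain's member descends from the ancestor matching its phenotype
#' group, misassigned with probability \code{noiseFlipProb}, then mutated
#' at \code{withinRate}), and marker OGs (presence biased towards active
#' strains, background sequences). The phenotype group is the median split
#' of the linked cytokine computed from [simulatePhenotypes()] at
#' generation time.
#'
#' @param config a [simConfig()].
#' @param groups optional precomputed [PhenotypeGroups-class]; by default
#'   the generator simulates phenotypes (same seed) and splits them itself.
#' @return list with \code{presence} ([PresenceMatrix-class]),
#'   \code{families} (named list of [OgFamily-class]), and \code{truth}
#'   (planted signal/marker OG ids, per-strain allele assignment, and the
#'   generation-time phenotype groups).
#' @export
simulatePangenome <- function(config = simConfig(), groups = NULL) {
  if (is.null(groups)) {
    ph <- simulatePhenotypes(config)
    groups <- classifyActiveSilent(ph, config$species, config$linkedCytokine)
  }
  strains <- sort(strainIds(groups))
  n <- length(strains)
  L <- config$seqLength
  isActive <- setNames(strains %in% activeStrains(groups), strains)

  ogClass <- rep(c("core", "acc", "sig", "marker"),
                 c(config$nCoreOgs, config$nAccessoryOgs,
                   config$nSignalOgs, config$nMarkerOgs))
  ogIdsAll <- sprintf("%s_%04d", ogClass, unlist(lapply(
    c(config$nCoreOgs, config$nAccessoryOgs, config$nSignalOgs,
      config$nMarkerOgs), seq_len)))

  present <- matrix(FALSE, length(ogIdsAll), n,
                    dimnames = list(ogIdsAll, strains))
  families <- list()
  truth_alleles <- list()

  for (k in seq_along(ogIdsAll)) {
    og <- ogIdsAll[k]
    set.seed(deriveSeed(config$seed, k))
    anc <- sample.int(20L, L, replace = TRUE)
    cls <- ogClass[k]
    if (cls == "core") {
      who <- strains
    } else if (cls == "acc") {
      who <- strains[runif(n) < config$accessoryPresenceProb]
    } else if (cls == "marker") {
      p <- ifelse(isActive, config$markerActiveProb, config$markerSilentProb)
      who <- strains[runif(n) < p]
    } else {                                   # signal OG
      who <- strains
    }
    present[og, who] <- TRUE
    if (length(who) == 0L) next
    if (cls == "sig") {
      ancB <- .mutateRows(matrix(anc, nrow = 1L), config$betweenRate)[1L, ]
      useA <- isActive[who]
      flip <- runif(length(who)) < config$noiseFlipProb
      useA[flip] <- !useA[flip]
      base <- matrix(0L, length(who), L)
      base[useA, ] <- matrix(anc, sum(useA), L, byrow = TRUE)
      base[!useA, ] <- matrix(ancB, sum(!useA), L, byrow = TRUE)
      rows <- .mutateRows(base, config$withinRate)
      truth_alleles[[og]] <- setNames(ifelse(useA, "A", "B"), who)
    } else {
      base <- matrix(anc, length(who), L, byrow = TRUE)
      rows <- .mutateRows(base, config$backgroundRate)
    }
    families[[og]] <- OgFamily(og, .rowsToSeqs(rows, who))
  }

  truth <- list(
    signal_ogs = ogIdsAll[ogClass == "sig"],
    marker_ogs = ogIdsAll[ogClass == "marker"],
    alleles = truth_alleles,
    linked_cytokine = config$linkedCytokine,
    median = groupMedian(groups),
    active = activeStrains(groups),
    silent = silentStrains(groups))

  list(presence = PresenceMatrix(present,
                                 annotation = paste(ogClass, "protein")),
       families = families, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper: phenotypes, phenotype groups of the linked
#' cytokine, and the pangenome with ground truth, all from one seed.
#'
#' @param config a [simConfig()].
#' @return list with \code{config, phenotypes, groups, presence, families,
#'   truth}.
#' @export
simulateStudy <- function(config = simConfig()) {
  phenotypes <- simulatePhenotypes(config)
  groups <- classifyActiveSilent(phenotypes, config$species,
                                 config$linkedCytokine)
  pg <- simulatePangenome(config, groups)
  list(config = config, phenotypes = phenotypes, groups = groups,
       presence = pg$presence, families = pg$families, truth = pg$truth)
}

#' Write a simulated study to disk
#'
#' Emits the file set the pipeline consumes: \code{gpa.csv} (Roary
#' dialect), \code{ogs/<og>.faa} per OG with members, \code{phenotypes.csv},
#' \code{truth.json}, and \code{config.json} (the resolved configuration
#' including the seed).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "ogs"), showWarnings = FALSE)
  writePresenceAbsence(study$presence, file.path(dir, "gpa.csv"), "roary")
  writePhenotypes(study$phenotypes, file.path(dir, "phenotypes.csv"))
  for (fam in study$families) {
    writeXStringSet(members(fam),
                    file.path(dir, "ogs", paste0(ogId(fam), ".faa")))
  }
  write_json(study$truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  write_json(unclass(study$config), file.path(dir, "config.json"),
             auto_unbox = TRUE)
  invisible(dir)
}
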