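# Readers/writers for the file formats the screen touches: Roary-style
# gene_presence_absence.csv, a simplified binary matrix TSV, per-OG FASTA
# files, the phenotype CSV, and the score table TSV.

# Roary 3.x metadata columns; strain columns start right after them.
.ROARY_META <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Read a gene presence/absence table
#'
#' Reads either the quoted-CSV \code{gene_presence_absence.csv} dialect of
#' Roary 3.x (14 fixed metadata columns, then one column per strain holding
#' locus tags; an empty cell means absent) or a simplified binary matrix
#' (TSV: header row of strain identifiers, rows of OG identifier followed by
#' 0/1).
#'
#' @param path path to the table.
#' @param dialect \code{"roary"} or \code{"binary"}.
#' @return A [PresenceMatrix-class].
#' @examples
#' pm <- PresenceMatrix(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2,
#'   dimnames = list(c("og1", "og2"), c("s1", "s2"))))
#' f <- tempfile(fileext = ".csv")
#' writePresenceAbsence(pm, f, dialect = "roary")
#' identical(isPresent(readPresenceAbsence(f, "roary")), isPresent(pm))
#' @export
readPresenceAbsence <- function(path, dialect = c("roary", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "roary") .readRoary(path) else .readBinaryMatrix(path)
}

.checkRagged <- function(path, sep) {
  n <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(n)) != 1L)
    stopf("format error: ragged rows in %s (field counts %s)", path,
          paste(unique(n), collapse = "/"))
}

.readRoary <- function(path) {
  .checkRagged(path, ",")
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 stringsAsFactors = FALSE)
  if (ncol(df) < 15L || names(df)[1] != "Gene")
    stopf("format error: not a Roary gene_presence_absence.csv (need 'Gene' in column 1 and >= 15 columns)")
  og <- df[["Gene"]]
  if (anyDuplicated(og)) stopf("format error: duplicate OG id '%s'",
                               og[duplicated(og)][1])
  strains <- names(df)[15:ncol(df)]
  m <- as.matrix(df[, 15:ncol(df), drop = FALSE]) != ""
  dimnames(m) <- list(og, strains)
  PresenceMatrix(m, annotation = df[["Annotation"]])
}

.readBinaryMatrix <- function(path) {
  .checkRagged(path, "\t")
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("format error: binary matrix needs an OG column and >= 1 strain column")
  og <- df[[1]]
  if (anyDuplicated(og)) stopf("format error: duplicate OG id '%s'",
                               og[duplicated(og)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!all(vals %in% c("0", "1")))
    stopf("format error: binary matrix cells must be 0 or 1")
  m <- vals == "1"
  dimnames(m) <- list(og, names(df)[-1])
  PresenceMatrix(m)
}

#' Write a gene presence/absence table
#'
#' Inverse of [readPresenceAbsence()]. The Roary dialect fills the metadata
#' columns with the information available (annotation, per-OG isolate
#' counts) and writes a synthetic locus tag \code{<og>_<strain>} in present
#' cells.
#'
#' @param x a [PresenceMatrix-class].
#' @param path output path.
#' @param dialect \code{"roary"} or \code{"binary"}.
#' @return \code{path}, invisibly.
#' @export
writePresenceAbsence <- function(x, path, dialect = c("roary", "binary")) {
  dialect <- match.arg(dialect)
  m <- isPresent(x)
  if (dialect == "binary") {
    df <- data.frame(og_id = rownames(m),
                     ifelse(m, "1", "0"), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[-1] <- colnames(m)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ann <- unname(annotations(x))
  meta <- data.frame(
    rownames(m), "", ann, rowSums(m), rowSums(m),
    ifelse(rowSums(m) > 0, "1", "0"), "", "", "", "", "", "", "", "",
    stringsAsFactors = FALSE, check.names = FALSE)
  names(meta) <- .ROARY_META
  cells <- outer(rownames(m), colnames(m), paste, sep = "_")
  cells[!m] <- ""
  df <- cbind(meta, as.data.frame(cells, stringsAsFactors = FALSE))
  names(df)[15:ncol(df)] <- colnames(m)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read per-OG FASTA sequence files
#'
#' Reads one amino-acid FASTA per OG from a directory (files named
#' \code{<og_id>.faa}); the strain identifier is the first
#' whitespace-delimited token of each header. Sequences are upper-cased and
#' \code{'*'} stop characters are stripped. If a strain contributes several
#' records (paralogs), the longest sequence is kept, ties broken by the
#' lexicographically first full header. Records whose strain is unknown to
#' the companion [PresenceMatrix-class] are skipped with a warning, as are
#' empty files.
#'
#' @param dir directory containing \code{.faa} files.
#' @param presence companion [PresenceMatrix-class]; members are restricted
#'   to its strains.
#' @return Named list of [OgFamily-class] objects (names = OG identifiers).
#' @export
readOgSequences <- function(dir, presence) {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  strains <- strainIds(presence)
  fams <- list()
  for (f in files) {
    og <- sub("\\.faa$", "", basename(f))
    aa <- tryCatch(readAAStringSet(f), error = function(e) NULL)
    if (is.null(aa) || length(aa) == 0L) {
      warnf("empty or unreadable FASTA for OG '%s'; skipped", og)
      next
    }
    hdr <- names(aa)
    sid <- sub("\\s.*$", "", hdr)
    seqs <- gsub("\\*", "", toupper(as.character(aa)))
    keep <- sid %in% strains
    if (any(!keep))
      warnf("OG '%s': %d record(s) with headers not matching any strain skipped",
            og, sum(!keep))
    if (!any(keep)) next
    sid <- sid[keep]; seqs <- seqs[keep]; hdr <- hdr[keep]
    nonempty <- nzchar(seqs)
    if (any(!nonempty)) {
      warnf("OG '%s': %d empty sequence record(s) dropped", og, sum(!nonempty))
      sid <- sid[nonempty]; seqs <- seqs[nonempty]; hdr <- hdr[nonempty]
    }
    if (!length(sid)) next
    # paralog resolution: longest sequence per strain, tie -> first header
    ord <- order(sid, -nchar(seqs), hdr)
    first <- !duplicated(sid[ord])
    pick <- ord[first]
    fams[[og]] <- OgFamily(og, setNames(seqs[pick], sid[pick]))
  }
  fams
}

#' Read the strain phenotype table
#'
#' CSV with columns \code{strain_id, species, cytokine, rep1, rep2}:
#' duplicate cytokine measurements (pg/mL) per strain per cytokine
#' (\code{IL10}, \code{IL12}; dashes as in \code{"IL-10"} are tolerated).
#' Both cytokines are required for every strain and measurements must be
#' non-negative. A \code{mean} column (the per-strain mean of the duplicate
#' reads) is appended.
#'
#' @param path path to the CSV.
#' @return data.frame with columns \code{strain_id, species, cytokine,
#'   rep1, rep2, mean}.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "species", "cytokine", "rep1", "rep2")
  if (!all(need %in% names(df)))
    stopf("phenotype table must have columns %s", paste(need, collapse = ", "))
  df$cytokine <- gsub("-", "", toupper(df$cytokine))
  if (!all(df$cytokine %in% c("IL10", "IL12")))
    stopf("validation error: cytokine must be IL10 or IL12")
  df$rep1 <- as.numeric(df$rep1); df$rep2 <- as.numeric(df$rep2)
  if (anyNA(df$rep1) || anyNA(df$rep2))
    stopf("validation error: missing or non-numeric replicate measurement")
  if (any(df$rep1 < 0) || any(df$rep2 < 0))
    stopf("validation error: negative cytokine measurement")
  if (anyDuplicated(df[, c("strain_id", "cytokine")]))
    stopf("validation error: duplicate (strain, cytokine) rows")
  cyt_per_strain <- tapply(df$cytokine, df$strain_id,
                           function(v) length(unique(v)))
  if (any(cyt_per_strain < 2L))
    stopf("validation error: strain(s) missing a cytokine row: %s",
          paste(names(cyt_per_strain)[cyt_per_strain < 2L], collapse = ", "))
  df$mean <- summarizeDuplicates(df$rep1, df$rep2)
  df[order(df$strain_id, df$cytokine), , drop = FALSE]
}

#' Write the strain phenotype table
#'
#' @param phenotypes data.frame as returned by [readPhenotypes()] or
#'   [simulatePhenotypes()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
  keep <- c("strain_id", "species", "cytokine", "rep1", "rep2")
  write.csv(phenotypes[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Score-table column contract, shared by writer and reader.
.SCORE_COLS <- c("og_id", "n_overall", "n_active", "n_silent", "bgss",
                 "wgss", "ch_index", "seq_dist_factor", "pg_index",
                 "pg_rank", "in_top_fraction", "kmeans_ch", "kmeans_rank")

#' Write the per-OG score table
#'
#' TSV with columns \code{og_id, n_overall, n_active, n_silent, bgss, wgss,
#' ch_index, seq_dist_factor, pg_index, pg_rank, in_top_fraction,
#' kmeans_ch, kmeans_rank}; floating-point values at 6 significant digits;
#' rows sorted by \code{pg_index} descending, ties broken by \code{og_id}
#' ascending.
#'
#' @param scores data.frame of per-OG scores ([scoreAll()] / [runScreen()]).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  if (!nrow(scores)) stopf("no scores to write")
  for (col in setdiff(.SCORE_COLS, names(scores))) {
    scores[[col]] <- if (col == "in_top_fraction") FALSE else NA
  }
  scores <- scores[, .SCORE_COLS]
  scores <- scores[order(-scores$pg_index, scores$og_id), , drop = FALSE]
  num <- c("bgss", "wgss", "ch_index", "seq_dist_factor", "pg_index",
           "kmeans_ch")
  for (col in num) scores[[col]] <- signif(scores[[col]], 6)
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [writeScoreTable()]
#'
#' @param path TSV path.
#' @return data.frame with the score-table columns.
#' @export
readScoreTable <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(.SCORE_COLS %in% names(df)))
    stopf("format error: not a PGscreen score table")
  df
}

#' Write a labelled square distance matrix
#'
#' Square TSV with a header row and a leading identifier column, readable
#' back with [readDistanceMatrix()].
#'
#' @param d symmetric numeric matrix with strain dimnames.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(strain_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
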