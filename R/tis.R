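#' Create a table of unique insertion sites
#'
#' Positions are 0-based; duplicates are merged (read counts summed) with a
#' warning, and the result is sorted. Every density statistic downstream
#' counts unique sites; read counts are carried along but never used.
#'
#' @param genome A [GenomeModel-class].
#' @param positions 0-based insertion positions.
#' @param readCounts Read count per position (default 1 each).
#' @return A [TisTable-class].
#' @examples
#' g <- GenomeModel("toy", length = 100)
#' TisTable(g, positions = c(10, 42), readCounts = c(3, 5))
#' @export
TisTable <- function(genome, positions, readCounts = NULL) {
  if (is.null(readCounts)) readCounts <- rep(1L, length(positions))
  if (length(readCounts) != length(positions))
    stop("positions and readCounts must have equal length")
  if (length(positions)) {
    if (anyNA(positions) || any(positions < 0) ||
        any(positions >= genomeLength(genome)))
      stop("range error: positions must lie in [0, genome length)")
    o <- order(positions)
    positions <- positions[o]
    readCounts <- readCounts[o]
    if (anyDuplicated(positions)) {
      warning("duplicate insertion positions merged (read counts summed)")
      readCounts <- as.vector(tapply(readCounts, positions, sum))
      positions <- sort(unique(positions))
    }
  }
  methods::new("TisTable", genome = genome,
               positions = as.numeric(positions),
               readCounts = as.integer(readCounts))
}

#' Load insertion sites from BED or TSV
#'
#' BED input follows the convention that the 0-based `start` field is the
#' insertion site and the score field (column 5) the read count (missing
#' score = 1). TSV input is two tab-separated columns, `position<TAB>count`.
#' Duplicate positions are merged with a warning; positions at or beyond the
#' genome length are an error.
#'
#' @param path Input file.
#' @param format `"bed"` or `"tsv"`.
#' @param genome The [GenomeModel-class] the coordinates refer to.
#' @return A [TisTable-class].
#' @export
loadTis <- function(path, format = c("bed", "tsv"), genome) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    if (file.size(path) == 0L)
      return(TisTable(genome, numeric(0)))
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                     stop("parse error in BED file ", path, ": ",
                          conditionMessage(e)))
    positions <- GenomicRanges::start(gr) - 1
    counts <- gr$score
    if (is.null(counts)) counts <- rep(1L, length(positions))
    counts[is.na(counts)] <- 1L
  } else {
    tab <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE,
                        colClasses = "numeric"),
      error = function(e)
        stop("parse error in TSV file ", path, ": ", conditionMessage(e)))
    if (nrow(tab) == 0L) return(TisTable(genome, numeric(0)))
    if (ncol(tab) < 2L)
      stop("parse error: TSV must have columns position<TAB>count")
    positions <- tab[[1]]
    counts <- tab[[2]]
  }
  bad <- which(positions < 0 | positions >= genomeLength(genome))
  if (length(bad))
    stop(sprintf("range error: line %d: position %s outside [0, %d)",
                 bad[1], format(positions[bad[1]], scientific = FALSE),
                 as.integer(genomeLength(genome))))
  TisTable(genome, positions, counts)
}

#' Write insertion sites to BED or TSV
#'
#' The BED written is six-column with name "." and the read count in the
#' score field; reloading it with [loadTis()] reproduces the table exactly.
#'
#' @param tis A [TisTable-class].
#' @param path Output file.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeTis <- function(tis, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  pos <- tisPositions(tis)
  if (format == "bed") {
    df <- data.frame(
      chrom = genomeName(tis@genome),
      start = format(pos, scientific = FALSE, trim = TRUE),
      end = format(pos + 1, scientific = FALSE, trim = TRUE),
      name = ".", score = tisCounts(tis), strand = "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(
      data.frame(format(pos, scientific = FALSE, trim = TRUE),
                 tisCounts(tis)),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Normalize an insertion landscape to insertions per million insertions
#'
#' Each unique site contributes `1e6 / totalUnique`, so the profile sums to
#' one million regardless of sequencing depth; read counts are ignored.
#'
#' @param tis A [TisTable-class] with at least one site.
#' @return An [InsertionProfile-class].
#' @examples
#' g <- GenomeModel("toy", length = 100)
#' normalizeInsertions(TisTable(g, c(1, 5, 20, 70)))  # 250000 each
#' @export
normalizeInsertions <- function(tis) {
  n <- totalUnique(tis)
  if (n == 0L) stop("empty input: no insertion sites to normalize")
  methods::new("InsertionProfile", positions = tisPositions(tis),
               intensity = rep(1e6 / n, n), totalUnique = as.numeric(n))
}

#' Write a normalized profile as variableStep wiggle
#'
#' @param profile An [InsertionProfile-class].
#' @param genome The [GenomeModel-class] (chromosome name).
#' @param path Output `.wig` path.
#' @return `path`, invisibly.
#' @export
writeProfileWig <- function(profile, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genomeName(genome),
    ranges = IRanges::IRanges(start = tisPositions(profile) + 1, width = 1),
    score = profileIntensity(profile))
  rtracklayer::export(gr, path, format = "WIG")
  invisible(path)
}
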