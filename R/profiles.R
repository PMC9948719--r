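#' Construct a binned binding profile
#'
#' Bins a per-base (or per-interval) intensity signal into fixed-width bins
#' covering the genome; empty bins are zero.
#'
#' @param proteinName Protein the signal belongs to.
#' @param start,end Signal intervals, 0-based half-open.
#' @param values Intensity per interval.
#' @param genome A [GenomeModel-class].
#' @param binWidth Bin width in bp (default 500).
#' @return A [BindingProfile-class] whose bin values are length-weighted
#'   mean intensities.
#' @export
binProfile <- function(proteinName, start, end, values, genome,
                       binWidth = 500) {
  L <- genomeLength(genome)
  nBins <- ceiling(L / binWidth)
  keep <- values != 0 & end > start
  start <- start[keep]; end <- pmin(end[keep], L); values <- values[keep]
  cov <- numeric(nBins)
  if (length(start)) {
    gr <- GenomicRanges::GRanges(
      "g", IRanges::IRanges(start = start + 1, end = end), score = values)
    rle <- GenomicRanges::coverage(gr, weight = "score")[[1]]
    if (length(rle) < L)
      rle <- c(rle, S4Vectors::Rle(0, L - length(rle)))
    binStart <- seq(1, L, by = binWidth)
    binEnd <- pmin(binStart + binWidth - 1, L)
    cov <- IRanges::viewMeans(IRanges::Views(
      rle, IRanges::IRanges(start = binStart, end = binEnd)))
  }
  methods::new("BindingProfile", proteinName = proteinName,
               binWidth = as.numeric(binWidth), values = as.numeric(cov),
               genomeLength = L)
}

#' Read a ChIP intensity track into a binned profile
#'
#' Reads a bedGraph or wiggle track (via rtracklayer) and bins it.
#'
#' @param path Track file (`.bedGraph`, `.wig`).
#' @param genome A [GenomeModel-class].
#' @param proteinName Name for the profile; defaults to the file base name.
#' @param binWidth Bin width in bp.
#' @return A [BindingProfile-class].
#' @export
readIntensityTrack <- function(path, genome, proteinName = NULL,
                               binWidth = 500) {
  if (is.null(proteinName))
    proteinName <- sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path)
  score <- gr$score
  if (is.null(score)) stop("track has no score column: ", path)
  binProfile(proteinName, GenomicRanges::start(gr) - 1,
             GenomicRanges::end(gr), score, genome, binWidth)
}

#' Pairwise Pearson correlation of binding profiles
#'
#' Correlates binned genome-wide intensities between proteins; all profiles
#' must share the genome length and bin width. A zero-variance profile
#' yields `NA` against the others (flagged with a warning); the diagonal is
#' 1 by convention.
#'
#' @param profiles List of [BindingProfile-class] objects.
#' @return Symmetric correlation matrix named by protein.
#' @export
profileCorrelation <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  bw <- unique(vapply(profiles, function(p) p@binWidth, numeric(1)))
  gl <- unique(vapply(profiles, function(p) p@genomeLength, numeric(1)))
  if (length(bw) != 1L || length(gl) != 1L)
    stop("profiles must share genome length and bin width")
  m <- vapply(profiles, function(p) p@values,
              numeric(length(profiles[[1]]@values)))
  colnames(m) <- vapply(profiles, function(p) p@proteinName, character(1))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance profile(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  cm <- suppressWarnings(stats::cor(m))
  diag(cm) <- 1
  cm
}
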