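#' Nearest-neighbour and gap statistics of insertion sites
#'
#' For each site the distance to its nearest neighbouring site on either
#' side is computed (on the circle when the genome is circular); for each
#' threshold `t` the fraction of sites whose nearest neighbour lies within
#' `t` bp is reported. The consecutive-gap distribution (distance between
#' adjacent sites along the genome) is returned separately, since both
#' summaries are in common use.
#'
#' @param tis A [TisTable-class] with at least two sites.
#' @param thresholds Distances in bp at which to evaluate the fraction.
#' @param circular Override the genome's topology (linear mode computes
#'   one-sided distances at the ends).
#' @return A list: `fractions` (named by threshold), `nnDistances` (per
#'   site), `gaps` (consecutive gaps, length = number of sites on a circle,
#'   sites − 1 on a line), and `gapHistogram` (a [table] of the gaps).
#' @examples
#' g <- GenomeModel("toy", length = 100)
#' adjacentDistanceStats(TisTable(g, c(0, 10, 30)), thresholds = 10)
#' @export
adjacentDistanceStats <- function(tis, thresholds = c(10, 25),
                                  circular = isCircular(tis@genome)) {
  pos <- tisPositions(tis)
  n <- length(pos)
  if (n < 2L)
    stop("undefined statistic: at least two insertion sites required")
  L <- genomeLength(tis@genome)
  gaps <- diff(pos)
  if (circular) {
    wrap <- L - pos[n] + pos[1]
    left <- c(wrap, gaps)     # gap to predecessor
    right <- c(gaps, wrap)    # gap to successor
    allGaps <- c(gaps, wrap)
  } else {
    left <- c(Inf, gaps)
    right <- c(gaps, Inf)
    allGaps <- gaps
  }
  nn <- pmin(left, right)
  fr <- vapply(thresholds, function(t) mean(nn <= t), numeric(1))
  names(fr) <- as.character(thresholds)
  list(fractions = fr, nnDistances = nn, gaps = allGaps,
       gapHistogram = table(allGaps))
}

#' Mean GC content in windows centred on insertion sites
#'
#' For each site the GC fraction of the window from `-window/2` to
#' `+window/2` around it (insertion base counted once, circular wrap) is
#' computed; `N` bases are dropped from numerator and denominator. The mean
#' over sites is returned, for comparison against the genome-wide GC.
#'
#' @param tis A [TisTable-class].
#' @param genome A [GenomeModel-class] with a sequence.
#' @param window Even window size in bp, `>= 2` and smaller than the genome.
#' @return Mean per-site GC proportion.
#' @export
gcNearTis <- function(tis, genome, window = 100) {
  seqn <- genomeSequence(genome)
  if (is.null(seqn)) stop("missing data: genome has no sequence")
  if (window < 2 || window %% 2 != 0)
    stop("window must be even and >= 2")
  L <- genomeLength(genome)
  if (window >= L) stop("window must be smaller than the genome")
  cums <- .gcCumsums(seqn)
  half <- window / 2
  pos <- tisPositions(tis)
  gc <- .circRangeSum(cums$gc, pos - half, pos + half, L)
  valid <- .circRangeSum(cums$valid, pos - half, pos + half, L)
  frac <- gc / valid
  mean(frac[valid > 0])
}

#' Insertion density of extreme-GC regions
#'
#' Scans the genome in fixed windows, selects windows whose GC content
#' exceeds `highThreshold` or falls below `lowThreshold`, merges overlapping
#' selected windows, and reports each merged region's IPKM (no end
#' curation). On an unbiased library the selected regions should show no
#' depletion relative to the genome-wide density.
#'
#' @param tis A [TisTable-class].
#' @param genome A [GenomeModel-class] with a sequence.
#' @param highThreshold,lowThreshold GC proportions delimiting "extreme"
#'   (defaults 0.65 and 0.15).
#' @param window,step Scan window and step in bp (defaults 100 and 50).
#' @return data.frame with columns `start`, `end`, `class` (`high`/`low`),
#'   `n_tis`, `ipkm`.
#' @export
extremeGcRegionIpkm <- function(tis, genome, highThreshold = 0.65,
                                lowThreshold = 0.15, window = 100,
                                step = 50) {
  seqn <- genomeSequence(genome)
  if (is.null(seqn)) stop("missing data: genome has no sequence")
  L <- genomeLength(genome)
  cums <- .gcCumsums(seqn)
  starts <- seq(0, max(0, L - window), by = step)
  gc <- .circRangeSum(cums$gc, starts, starts + window - 1, L)
  valid <- .circRangeSum(cums$valid, starts, starts + window - 1, L)
  frac <- ifelse(valid > 0, gc / valid, NA_real_)
  pick <- function(sel, lab) {
    if (!any(sel, na.rm = TRUE))
      return(data.frame(start = numeric(0), end = numeric(0),
                        class = character(0)))
    sel[is.na(sel)] <- FALSE
    m <- .mergeIntervals(starts[sel], starts[sel] + window)
    m$class <- lab
    m
  }
  out <- rbind(pick(frac > highThreshold, "high"),
               pick(frac < lowThreshold, "low"))
  if (nrow(out) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      class = character(0), n_tis = numeric(0),
                      ipkm = numeric(0)))
  out <- out[order(out$start), , drop = FALSE]
  dens <- .ipkmForIntervals(tis, out$start, out$end, endTrim = 0)
  out$n_tis <- dens$nTis
  out$ipkm <- dens$ipkm
  rownames(out) <- NULL
  out
}

#' Genome-wide mean IPKM
#'
#' The IPKM of the whole genome treated as one interval; a convenient
#' reference level for region-level densities.
#'
#' @param tis A [TisTable-class].
#' @return A single IPKM value.
#' @export
genomeMeanIpkm <- function(tis) {
  L <- genomeLength(tis@genome)
  totalUnique(tis) * 1e9 / (L * totalUnique(tis))
}
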