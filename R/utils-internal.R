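# Internal helpers shared across modules. All coordinates 0-based,
# intervals half-open [start, end); circular intervals may have end >
# genome length, in which case they wrap across the origin.

# Number of sorted positions strictly below x (positions are integers).
.nBelow <- function(positions, x) findInterval(x - 0.5, positions)

# Count sites in [start, end), vectorized over start/end. With circular =
# TRUE an interval may wrap (end > L); intervals longer than the genome are
# capped at the full site count.
.countSites <- function(positions, start, end, L, circular = TRUE) {
  n <- max(length(start), length(end))
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  width <- end - start
  if (circular) {
    wraps <- end > L
    base <- .nBelow(positions, pmin(end, L)) -
      .nBelow(positions, pmax(start, 0))
    extra <- numeric(n)
    if (any(wraps))
      extra[wraps] <- .nBelow(positions, pmin(end[wraps] - L, start[wraps]))
    out <- base + extra
    out[width >= L] <- length(positions)
  } else {
    out <- .nBelow(positions, pmin(end, L)) -
      .nBelow(positions, pmax(start, 0))
  }
  pmax(out, 0)
}

# Inclusive circular range sum over a 0-based indicator cumulative sum
# (cum has length L+1, cum[i+1] = sum of first i elements). a and b may
# lie outside [0, L); they are reduced modulo L. Vectorized.
.circRangeSum <- function(cum, a, b, L) {
  a <- a %% L
  b <- b %% L
  lin <- function(x, y) cum[y + 2] - cum[x + 1]
  ifelse(a <= b, lin(a, b), lin(a, L - 1) + lin(0, b))
}

# Stage-specific seeds derived from one global seed so pipeline stages can
# be re-run in isolation yet the full run stays reproducible. Kept within
# 32-bit integer range.
.stageSeed <- function(seed, stage) {
  offsets <- c(genome = 11L, annotation = 29L, insertions = 47L,
               regions = 71L, bootstrap = 101L, counts = 131L)
  if (!stage %in% names(offsets))
    stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% .Machine$integer.max)
}

# Merge possibly-overlapping 0-based half-open intervals into a disjoint
# union, via IRanges (1-based closed internally).
.mergeIntervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

# logical GC / valid-base indicators from a DNAString, as cumulative sums
# ready for .circRangeSum. N bases count as invalid.
.gcCumsums <- function(sequence) {
  raw <- charToRaw(as.character(sequence))
  isGC <- raw == charToRaw("G") | raw == charToRaw("C")
  isN <- raw == charToRaw("N")
  list(gc = c(0, cumsum(as.numeric(isGC))),
       valid = c(0, cumsum(as.numeric(!isN))))
}
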