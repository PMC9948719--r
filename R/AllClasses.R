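#' @import methods
#' @importFrom S4Vectors Rle
NULL

setClassUnion("DNAStringOrNULL", members = c("DNAString", "NULL"))

#' GenomeModel: the coordinate frame for a single bacterial replicon
#'
#' Holds the identity, length, topology and (optionally) the nucleotide
#' sequence of one replicon. All coordinates in the package are 0-based and
#' intervals are half-open `[start, end)`, matching BED conventions.
#'
#' @slot name Replicon name (used as the chromosome field when writing BED,
#'   GFF3 or wiggle output).
#' @slot length Replicon length in bp.
#' @slot circular Whether the replicon is circular. Circular semantics affect
#'   nearest-neighbour distances, sequence windows and random-region sampling,
#'   all of which wrap across the origin when `TRUE`.
#' @slot sequence A [Biostrings::DNAString] of exactly `length` bases, or
#'   `NULL` when the sequence is not materialised (GC diagnostics then error).
#'
#' @export
setClass("GenomeModel",
  representation(
    name = "character",
    length = "numeric",
    circular = "logical",
    sequence = "DNAStringOrNULL"
  ),
  prototype(name = "genome", length = 0, circular = TRUE, sequence = NULL)
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (length(object@length) != 1L || is.na(object@length) || object@length <= 0)
    msg <- c(msg, "genome length must be a single positive number")
  if (!is.null(object@sequence) &&
      length(object@sequence) != object@length)
    msg <- c(msg, sprintf(
      "sequence length (%d) does not match declared genome length (%d)",
      length(object@sequence), as.integer(object@length)))
  if (!is.null(object@sequence)) {
    freq <- Biostrings::alphabetFrequency(object@sequence)
    bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
    if (bad > 0)
      msg <- c(msg, "sequence must use only the alphabet {A,C,G,T,N}")
  }
  if (length(msg)) msg else TRUE
})

#' TisTable: the deduplicated set of unique transposon insertion sites
#'
#' The central data object of the package: the sorted set of unique 0-based
#' insertion positions on one genome, with a positive read count per site.
#' Read counts are auxiliary — every density statistic in the package counts
#' unique sites only.
#'
#' @slot genome The [GenomeModel-class] the positions refer to.
#' @slot positions Strictly increasing 0-based positions, all in
#'   `[0, genomeLength)`.
#' @slot readCounts Integer read count per position, all `>= 1`.
#'
#' @export
setClass("TisTable",
  representation(
    genome = "GenomeModel",
    positions = "numeric",
    readCounts = "integer"
  )
)

setValidity("TisTable", function(object) {
  msg <- character()
  p <- object@positions
  if (length(p) != length(object@readCounts))
    msg <- c(msg, "positions and readCounts must have equal length")
  if (length(p)) {
    if (anyNA(p) || any(p < 0) || any(p >= object@genome@length))
      msg <- c(msg, "positions must lie in [0, genome length)")
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, "positions must be strictly increasing (unique sites)")
    if (anyNA(object@readCounts) || any(object@readCounts < 1L))
      msg <- c(msg, "read counts must all be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' InsertionProfile: per-site normalized insertion intensity
#'
#' Normalizes a [TisTable-class] so that each unique site carries an
#' intensity of `1e6 / totalUnique` "insertions per million insertions";
#' intensities therefore always sum to one million. Read counts are ignored.
#'
#' @slot positions 0-based site positions (as in the source table).
#' @slot intensity Per-site normalized intensity.
#' @slot totalUnique Number of unique sites the normalization used.
#'
#' @export
setClass("InsertionProfile",
  representation(
    positions = "numeric",
    intensity = "numeric",
    totalUnique = "numeric"
  )
)

setValidity("InsertionProfile", function(object) {
  if (length(object@positions) != length(object@intensity))
    return("positions and intensity must have equal length")
  if (length(object@intensity) &&
      abs(sum(object@intensity) - 1e6) > 1e-6 * 1e6)
    return("intensities must sum to 1e6")
  TRUE
})

#' SynthConfig: parameters of the synthetic Tn-Seq landscape generator
#'
#' Describes one simulated study: a circular genome, a non-overlapping gene
#' annotation with essential / nonessential / pseudogene labels, a set of
#' planted protein-protected intervals, and a hypersaturated insertion
#' landscape in which essential-gene cores and protected intervals are
#' depleted of insertions. See [synthConfig()] for defaults and units.
#'
#' @slot genomeLength Genome length in bp.
#' @slot gcFraction Target GC proportion of the generated sequence.
#' @slot nGenes Number of genes to place.
#' @slot meanGeneLength Mean gene length in bp.
#' @slot fractionEssential Proportion of genes labelled essential.
#' @slot fractionPseudogene Proportion of genes labelled pseudogene.
#' @slot fractionEssentialWithDispensableDomain Proportion of essential genes
#'   whose 3'-terminal 30% tolerates insertion.
#' @slot endPermissiveFraction Proportion of each gene end that tolerates
#'   insertion even in essential genes.
#' @slot nInsertions Number of unique insertion sites to place.
#' @slot essentialBodyRateRatio Insertion rate inside essential-gene cores
#'   relative to background.
#' @slot protectedRegionCount,protectedRegionLength Number and length (bp) of
#'   planted protein-protected intervals.
#' @slot protectionRateRatio Insertion rate inside protected intervals
#'   relative to background.
#' @slot readCountMu,readCountSize Per-site read counts are
#'   `1 + rnbinom(mu = readCountMu, size = readCountSize)`.
#' @slot seed Integer seed; identical configs generate identical data.
#'
#' @export
setClass("SynthConfig",
  representation(
    genomeLength = "numeric",
    gcFraction = "numeric",
    nGenes = "numeric",
    meanGeneLength = "numeric",
    fractionEssential = "numeric",
    fractionPseudogene = "numeric",
    fractionEssentialWithDispensableDomain = "numeric",
    endPermissiveFraction = "numeric",
    nInsertions = "numeric",
    essentialBodyRateRatio = "numeric",
    protectedRegionCount = "numeric",
    protectedRegionLength = "numeric",
    protectionRateRatio = "numeric",
    readCountMu = "numeric",
    readCountSize = "numeric",
    seed = "numeric"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  prop <- c(
    gcFraction = object@gcFraction,
    fractionEssential = object@fractionEssential,
    fractionPseudogene = object@fractionPseudogene,
    fractionEssentialWithDispensableDomain =
      object@fractionEssentialWithDispensableDomain,
    endPermissiveFraction = object@endPermissiveFraction
  )
  if (anyNA(prop) || any(prop < 0) || any(prop > 1))
    msg <- c(msg, "all proportions must lie in [0, 1]")
  if (object@fractionEssential + object@fractionPseudogene > 1)
    msg <- c(msg, "fractionEssential + fractionPseudogene must be <= 1")
  if (object@genomeLength <= 0)
    msg <- c(msg, "genomeLength must be positive")
  if (object@nInsertions > object@genomeLength)
    msg <- c(msg, "nInsertions must not exceed genomeLength (sites are unique)")
  if (any(c(object@essentialBodyRateRatio, object@protectionRateRatio) < 0))
    msg <- c(msg, "rate ratios must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the known answer key of a synthetic landscape
#'
#' @slot genes data.frame with one row per annotated gene: `gene_id`,
#'   `start`, `end` (0-based half-open), `strand`, `class` (one of
#'   `essential`, `essential_with_dispensable_domain`, `nonessential`,
#'   `pseudogene`), and for dispensable-domain genes the domain interval
#'   (`domain_start`, `domain_end`, `NA` otherwise).
#' @slot protectedRegions data.frame of planted protected intervals
#'   (`start`, `end`).
#' @slot rates Per-base relative insertion rate actually used, as an
#'   [S4Vectors::Rle] of length `genomeLength`.
#'
#' @export
setClass("GroundTruth",
  representation(
    genes = "data.frame",
    protectedRegions = "data.frame",
    rates = "Rle"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  g <- object@genes
  if (nrow(g) && anyDuplicated(g$gene_id))
    msg <- c(msg, "every gene must appear exactly once")
  L <- length(object@rates)
  pr <- object@protectedRegions
  if (nrow(pr) && (any(pr$start < 0) || any(pr$end > L)))
    msg <- c(msg, "protected intervals must lie within [0, genome length)")
  if (length(msg)) msg else TRUE
})

#' CutoffCurve: confusion counts and accuracy along an ecIPKM cutoff grid
#'
#' @slot curve data.frame with one row per cutoff: `cutoff`, `TP`, `FP`,
#'   `TN`, `FN`, `accuracy`, `coverage`, `precision`, `TPR`, `FPR`.
#' @slot selectedCutoff The accuracy-maximizing cutoff (ties resolved to the
#'   smallest).
#' @slot auc Area under the ROC curve, by the trapezoid rule.
#'
#' @export
setClass("CutoffCurve",
  representation(curve = "data.frame", selectedCutoff = "numeric",
                 auc = "numeric")
)

setValidity("CutoffCurve", function(object) {
  cv <- object@curve
  if (nrow(cv)) {
    refsize <- unique(cv$TP + cv$FN)
    if (length(refsize) != 1L)
      return("TP + FN must equal the reference-set size at every cutoff")
    n <- unique(cv$TP + cv$FP + cv$TN + cv$FN)
    if (length(n) != 1L)
      return("TP+FP+TN+FN must be constant across cutoffs")
    if (any(cv$accuracy < 0 | cv$accuracy > 1))
      return("accuracy must lie in [0, 1]")
  }
  TRUE
})

#' ConfusionSummary: agreement between a call set and the reference set
#'
#' @slot nCalledEssential Number of genes called essential.
#' @slot nReference Size of the reference essential-gene set among evaluated
#'   genes.
#' @slot truePositives,falsePositives,falseNegatives Confusion counts.
#' @slot coveragePercent `100 * TP / nReference`.
#'
#' @export
setClass("ConfusionSummary",
  representation(
    nCalledEssential = "numeric",
    nReference = "numeric",
    truePositives = "numeric",
    falsePositives = "numeric",
    falseNegatives = "numeric",
    coveragePercent = "numeric"
  )
)

setValidity("ConfusionSummary", function(object) {
  msg <- character()
  if (object@nCalledEssential !=
      object@truePositives + object@falsePositives)
    msg <- c(msg, "called = TP + FP must hold")
  if (object@nReference != object@truePositives + object@falseNegatives)
    msg <- c(msg, "reference = TP + FN must hold")
  if (object@nReference > 0 &&
      abs(object@coveragePercent -
          100 * object@truePositives / object@nReference) > 1e-8)
    msg <- c(msg, "coveragePercent must equal 100*TP/reference")
  if (length(msg)) msg else TRUE
})

#' BindingRegionSet: intervals bound by one DNA-binding protein
#'
#' A named set of protein-bound intervals, typically ChIP-Exo peak calls for
#' one nucleoid-associated protein or transcription factor, consumed by the
#' insertion-protection analysis.
#'
#' @slot proteinName Protein the regions belong to.
#' @slot regions data.frame with 0-based half-open `start`, `end`, sorted by
#'   `start`, and an optional `qvalue` column.
#'
#' @export
setClass("BindingRegionSet",
  representation(proteinName = "character", regions = "data.frame")
)

setValidity("BindingRegionSet", function(object) {
  r <- object@regions
  if (!all(c("start", "end") %in% names(r)))
    return("regions must have columns start and end")
  if (nrow(r)) {
    if (any(r$start < 0) || any(r$start >= r$end))
      return("each region must satisfy 0 <= start < end")
    if (is.unsorted(r$start))
      return("regions must be sorted by start")
  }
  TRUE
})

#' RegionIpkmSet: per-region insertion densities for one region set
#'
#' @slot values Per-region IPKM (no end curation).
#' @slot mean Arithmetic mean of `values`.
#' @slot nRegions Number of regions.
#'
#' @export
setClass("RegionIpkmSet",
  representation(values = "numeric", mean = "numeric", nRegions = "numeric")
)

setValidity("RegionIpkmSet", function(object) {
  if (length(object@values) != object@nRegions)
    return("nRegions must equal length(values)")
  if (any(object@values < 0)) return("IPKM values must be >= 0")
  if (object@nRegions > 0 &&
      abs(object@mean - mean(object@values)) > 1e-9 * (1 + abs(object@mean)))
    return("mean must be the arithmetic mean of values")
  TRUE
})

#' BootstrapResult: outcome of the insertion-protection bootstrap test
#'
#' @slot observed [RegionIpkmSet-class] of the tested regions.
#' @slot nSets Number of random same-sized region sets in the null.
#' @slot seed Seed used for region sampling.
#' @slot nullMeans Mean IPKM of each random set.
#' @slot empiricalP One-sided (depletion) empirical p with the +1 correction,
#'   never zero.
#' @slot welchT,welchP Welch's unequal-variance t statistic and p-value of
#'   observed per-region IPKMs against a null set's per-region IPKMs.
#' @slot welchVariant `"single"` (against null set 1) or `"pooled"` (against
#'   all null per-region values).
#'
#' @export
setClass("BootstrapResult",
  representation(
    observed = "RegionIpkmSet",
    nSets = "numeric",
    seed = "numeric",
    nullMeans = "numeric",
    empiricalP = "numeric",
    welchT = "numeric",
    welchP = "numeric",
    welchVariant = "character"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (length(object@nullMeans) != object@nSets)
    msg <- c(msg, "length(nullMeans) must equal nSets")
  lo <- 1 / (object@nSets + 1)
  if (object@empiricalP < lo - 1e-12 || object@empiricalP > 1)
    msg <- c(msg, "empiricalP must lie in [1/(nSets+1), 1]")
  if (length(msg)) msg else TRUE
})

#' BindingProfile: a binned genome-wide binding-intensity track
#'
#' @slot proteinName Protein the track belongs to.
#' @slot binWidth Bin width in bp.
#' @slot values One non-negative intensity per bin;
#'   `ceiling(genomeLength / binWidth)` bins.
#' @slot genomeLength Genome length the binning refers to.
#'
#' @export
setClass("BindingProfile",
  representation(
    proteinName = "character",
    binWidth = "numeric",
    values = "numeric",
    genomeLength = "numeric"
  )
)

setValidity("BindingProfile", function(object) {
  if (length(object@values) != ceiling(object@genomeLength / object@binWidth))
    return("bin count must equal ceiling(genomeLength / binWidth)")
  if (any(object@values < 0)) return("intensities must be >= 0")
  TRUE
})
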