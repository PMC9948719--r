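#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `genomeName`, `genomeLength`, `isCircular`, `genomeSequence` for
#' [GenomeModel-class]; `tisPositions`, `tisCounts`, `totalUnique` for
#' [TisTable-class]; `profileIntensity` for [InsertionProfile-class];
#' `regionTable`, `proteinName` for [BindingRegionSet-class]; `ipkmValues`
#' for [RegionIpkmSet-class]; `nullMeans`, `empiricalP`, `welchP`, `welchT`,
#' `observedIpkm` for [BootstrapResult-class]; `cutoffTable`,
#' `selectedCutoff`, `rocAuc` for [CutoffCurve-class]; `truthGenes`,
#' `truthRegions`, `truthRates` for [GroundTruth-class].
#'
#' @param x The object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases genomeName genomeLength isCircular genomeSequence tisPositions
#'   tisCounts totalUnique profileIntensity regionTable proteinName
#'   ipkmValues nullMeans empiricalP welchP welchT observedIpkm cutoffTable
#'   selectedCutoff rocAuc truthGenes truthRegions truthRates
NULL

#' @rdname accessors
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("tisPositions", function(x) standardGeneric("tisPositions"))
#' @rdname accessors
#' @export
setGeneric("tisCounts", function(x) standardGeneric("tisCounts"))
#' @rdname accessors
#' @export
setGeneric("totalUnique", function(x) standardGeneric("totalUnique"))
#' @rdname accessors
#' @export
setGeneric("profileIntensity", function(x) standardGeneric("profileIntensity"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("proteinName", function(x) standardGeneric("proteinName"))
#' @rdname accessors
#' @export
setGeneric("ipkmValues", function(x) standardGeneric("ipkmValues"))
#' @rdname accessors
#' @export
setGeneric("nullMeans", function(x) standardGeneric("nullMeans"))
#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @rdname accessors
#' @export
setGeneric("welchP", function(x) standardGeneric("welchP"))
#' @rdname accessors
#' @export
setGeneric("welchT", function(x) standardGeneric("welchT"))
#' @rdname accessors
#' @export
setGeneric("observedIpkm", function(x) standardGeneric("observedIpkm"))
#' @rdname accessors
#' @export
setGeneric("cutoffTable", function(x) standardGeneric("cutoffTable"))
#' @rdname accessors
#' @export
setGeneric("selectedCutoff", function(x) standardGeneric("selectedCutoff"))
#' @rdname accessors
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))
#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))
#' @rdname accessors
#' @export
setGeneric("truthRegions", function(x) standardGeneric("truthRegions"))
#' @rdname accessors
#' @export
setGeneric("truthRates", function(x) standardGeneric("truthRates"))

#' @rdname accessors
#' @export
setMethod("genomeName", "GenomeModel", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomeModel", function(x) x@length)
#' @rdname accessors
#' @export
setMethod("isCircular", "GenomeModel", function(x) x@circular)
#' @rdname accessors
#' @export
setMethod("genomeSequence", "GenomeModel", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("tisPositions", "TisTable", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("tisCounts", "TisTable", function(x) x@readCounts)
#' @rdname accessors
#' @export
setMethod("totalUnique", "TisTable", function(x) length(x@positions))
#' @rdname accessors
#' @export
setMethod("genomeLength", "TisTable", function(x) x@genome@length)

#' @rdname accessors
#' @export
setMethod("tisPositions", "InsertionProfile", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("profileIntensity", "InsertionProfile", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("totalUnique", "InsertionProfile", function(x) x@totalUnique)

#' @rdname accessors
#' @export
setMethod("regionTable", "BindingRegionSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("proteinName", "BindingRegionSet", function(x) x@proteinName)

#' @rdname accessors
#' @export
setMethod("ipkmValues", "RegionIpkmSet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("nullMeans", "BootstrapResult", function(x) x@nullMeans)
#' @rdname accessors
#' @export
setMethod("empiricalP", "BootstrapResult", function(x) x@empiricalP)
#' @rdname accessors
#' @export
setMethod("welchP", "BootstrapResult", function(x) x@welchP)
#' @rdname accessors
#' @export
setMethod("welchT", "BootstrapResult", function(x) x@welchT)
#' @rdname accessors
#' @export
setMethod("observedIpkm", "BootstrapResult", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("cutoffTable", "CutoffCurve", function(x) x@curve)
#' @rdname accessors
#' @export
setMethod("selectedCutoff", "CutoffCurve", function(x) x@selectedCutoff)
#' @rdname accessors
#' @export
setMethod("rocAuc", "CutoffCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("truthGenes", "GroundTruth", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("truthRegions", "GroundTruth", function(x) x@protectedRegions)
#' @rdname accessors
#' @export
setMethod("truthRates", "GroundTruth", function(x) x@rates)

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel '%s': %s bp, %s%s\n",
              object@name, format(object@length, big.mark = ","),
              if (object@circular) "circular" else "linear",
              if (is.null(object@sequence)) ", no sequence"
              else ", sequence attached"))
})

setMethod("show", "TisTable", function(object) {
  cat(sprintf(
    "TisTable: %s unique insertion sites on '%s' (%s bp)\n",
    format(length(object@positions), big.mark = ","),
    object@genome@name, format(object@genome@length, big.mark = ",")))
})

setMethod("show", "InsertionProfile", function(object) {
  cat(sprintf(
    "InsertionProfile: %s sites, %.5f insertions/million each\n",
    format(length(object@positions), big.mark = ","),
    if (object@totalUnique > 0) 1e6 / object@totalUnique else 0))
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  genome: %s bp (GC %.3f), %d genes (mean %d bp)\n",
              format(object@genomeLength, big.mark = ","),
              object@gcFraction, as.integer(object@nGenes),
              as.integer(object@meanGeneLength)))
  cat(sprintf("  classes: %.0f%% essential (%.0f%% with dispensable domain), %.0f%% pseudogene\n",
              100 * object@fractionEssential,
              100 * object@fractionEssentialWithDispensableDomain,
              100 * object@fractionPseudogene))
  cat(sprintf("  insertions: %s unique sites; essential-core ratio %.4g; %d protected regions x %d bp at ratio %.4g\n",
              format(object@nInsertions, big.mark = ","),
              object@essentialBodyRateRatio,
              as.integer(object@protectedRegionCount),
              as.integer(object@protectedRegionLength),
              object@protectionRateRatio))
  cat(sprintf("  seed: %d\n", as.integer(object@seed)))
})

setMethod("show", "CutoffCurve", function(object) {
  cat(sprintf(
    "CutoffCurve: %d cutoffs; selected = %.4g (accuracy %.4f); ROC AUC %.4f\n",
    nrow(object@curve), object@selectedCutoff,
    object@curve$accuracy[match(object@selectedCutoff, object@curve$cutoff)],
    object@auc))
})

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf(
    paste0("ConfusionSummary: %d called essential | reference %d | ",
           "TP %d, FP %d, FN %d | coverage %.1f%%\n"),
    object@nCalledEssential, object@nReference, object@truePositives,
    object@falsePositives, object@falseNegatives, object@coveragePercent))
})

setMethod("show", "BindingRegionSet", function(object) {
  cat(sprintf("BindingRegionSet '%s': %d regions, %s bp total\n",
              object@proteinName, nrow(object@regions),
              format(sum(object@regions$end - object@regions$start),
                     big.mark = ",")))
})

setMethod("show", "RegionIpkmSet", function(object) {
  cat(sprintf("RegionIpkmSet: %d regions, mean IPKM %.4g\n",
              as.integer(object@nRegions), object@mean))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    paste0("BootstrapResult: observed mean IPKM %.4g vs null mean %.4g ",
           "(%d sets)\n  empirical p = %.4g; Welch t = %.3f, p = %.4g (%s)\n"),
    object@observed@mean, mean(object@nullMeans), as.integer(object@nSets),
    object@empiricalP, object@welchT, object@welchP, object@welchVariant))
})

setMethod("show", "BindingProfile", function(object) {
  cat(sprintf("BindingProfile '%s': %d bins of %d bp\n",
              object@proteinName, length(object@values),
              as.integer(object@binWidth)))
})
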