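# IPKM of arbitrary intervals, vectorized. endTrim removes floor(endTrim*L)
# bp from each end before counting; the density denominator is the trimmed
# length unless useTrimmedLength = FALSE (sensitivity mode: raw length).
# Intervals may wrap the origin of a circular genome (end > genome length).
.ipkmForIntervals <- function(tis, start, end, endTrim = 0,
                              useTrimmedLength = TRUE) {
  if (endTrim < 0 || endTrim >= 0.5)
    stop("endTrim must lie in [0, 0.5)")
  L <- genomeLength(tis@genome)
  total <- totalUnique(tis)
  n <- max(length(start), length(end))
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  len <- end - start
  trim <- floor(endTrim * len)
  s <- start + trim
  e <- end - trim
  empty <- e <= s
  if (any(empty)) {
    warning(sum(empty), " interval(s) empty after end trimming; ",
            "effective length clamped to 1 bp")
    e[empty] <- s[empty]  # zero sites counted below
  }
  nTis <- .countSites(tisPositions(tis), s, e, L,
                      circular = isCircular(tis@genome))
  nTis[empty] <- 0
  effLen <- if (useTrimmedLength) pmax(e - s, 1) else pmax(len, 1)
  ipkm <- if (total > 0) nTis * 1e9 / (effLen * total) else rep(0, n)
  list(nTis = nTis, ipkm = ipkm, effLength = effLen)
}

#' IPKM of a gene or interval, with optional end curation
#'
#' IPKM is insertions per kilobase of feature per million total unique
#' insertions: `n_sites * 1e9 / (length_bp * totalUnique)`. With
#' `endTrim = 0.04`, sites in the terminal 4% at each end of the feature are
#' excluded first (end-curated IPKM, ecIPKM), because even essential genes
#' tolerate insertions near their ends; the denominator then uses the
#' trimmed length so the statistic stays an unbiased density (set
#' `useTrimmedLength = FALSE` to reproduce a raw-length denominator).
#' Trimming is `floor(endTrim * L)` bp per end, so genes shorter than
#' `1/endTrim` bp are not trimmed at all.
#'
#' @param start,end Interval in 0-based half-open coordinates (vectorized).
#'   `end` may exceed the genome length on a circular genome (origin-
#'   spanning gene).
#' @param tis A [TisTable-class].
#' @param endTrim Proportion trimmed from each end, in `[0, 0.5)`.
#' @param useTrimmedLength Use the trimmed length as denominator (default).
#' @return A list with `nTis`, `ipkm`, and `effLength` (all vectorized).
#' @examples
#' g <- GenomeModel("toy", length = 10000)
#' tis <- TisTable(g, positions = c(101, 103, 150, 197))
#' computeIpkm(100, 200, tis, endTrim = 0.04)  # only the site at 150 counts
#' @export
computeIpkm <- function(start, end, tis, endTrim = 0,
                        useTrimmedLength = TRUE) {
  .ipkmForIntervals(tis, start, end, endTrim, useTrimmedLength)
}

#' Insertion index of a gene
#'
#' Unique insertion sites in the full gene span divided by gene length in
#' bp — the classical Tn-Seq density metric, exposed for cross-comparison
#' with ecIPKM. With no end trimming it ranks genes identically to raw IPKM
#' (they differ by the constant `1e9 / totalUnique`).
#'
#' @inheritParams computeIpkm
#' @return Insertions per bp (vectorized).
#' @export
computeInsertionIndex <- function(start, end, tis) {
  L <- genomeLength(tis@genome)
  nTis <- .countSites(tisPositions(tis), as.numeric(start), as.numeric(end),
                      L, circular = isCircular(tis@genome))
  nTis / pmax(end - start, 1)
}

#' Per-gene insertion statistics
#'
#' Computes, for every gene, the raw site count and IPKM, the end-curated
#' count and ecIPKM, and the insertion index, carrying through any
#' annotation labels present.
#'
#' @param genes data.frame with columns `gene_id`, `start`, `end`, and
#'   optionally `strand`, `essential`, `pseudo`, `excluded`.
#' @param tis A [TisTable-class].
#' @param endTrim End-curation proportion for ecIPKM (default 0.04).
#' @param useTrimmedLength Denominator convention, see [computeIpkm()].
#' @return data.frame with one row per gene: the input columns plus
#'   `n_tis_raw`, `n_tis_curated`, `ipkm`, `ec_ipkm`, `insertion_index`.
#' @export
geneStats <- function(genes, tis, endTrim = 0.04, useTrimmedLength = TRUE) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  raw <- .ipkmForIntervals(tis, genes$start, genes$end, endTrim = 0)
  cur <- .ipkmForIntervals(tis, genes$start, genes$end, endTrim = endTrim,
                           useTrimmedLength = useTrimmedLength)
  out <- genes
  out$n_tis_raw <- raw$nTis
  out$n_tis_curated <- cur$nTis
  out$ipkm <- raw$ipkm
  out$ec_ipkm <- cur$ipkm
  out$insertion_index <- computeInsertionIndex(genes$start, genes$end, tis)
  out
}

#' Sweep essentiality cutoffs against a reference set
#'
#' At each cutoff `c` a gene is called essential iff `ec_ipkm < c`. Confusion
#' counts against the reference essential-gene set, accuracy
#' `(TP + TN) / N`, coverage `TP / |reference|`, precision, and ROC points
#' are reported per cutoff; the selected cutoff maximizes accuracy (ties go
#' to the smallest cutoff). ROC AUC is computed by the trapezoid rule with
#' the implicit (0,0) and (1,1) endpoints.
#'
#' Genes flagged `excluded` must be removed beforehand (they are dropped
#' here defensively).
#'
#' @param stats Per-gene statistics from [geneStats()] (needs `gene_id` and
#'   `ec_ipkm`).
#' @param reference Character vector of reference essential gene ids.
#' @param cutoffGrid Ascending cutoff values; default a log-spaced grid from
#'   0.05 to 5000.
#' @return A [CutoffCurve-class].
#' @export
sweepCutoffs <- function(stats, reference,
                         cutoffGrid = 10^seq(log10(0.05), log10(5000),
                                             length.out = 200)) {
  if (length(reference) == 0L)
    stop("calibration error: empty reference set")
  if (is.unsorted(cutoffGrid, strictly = TRUE))
    stop("cutoffGrid must be sorted ascending")
  if ("excluded" %in% names(stats)) stats <- stats[!stats$excluded, ]
  isRef <- stats$gene_id %in% reference
  nRef <- sum(isRef)
  if (nRef == 0L)
    stop("calibration error: no reference gene present among evaluated genes")
  N <- nrow(stats)
  # ec_ipkm < c for ascending c: cumulative counts over the sorted values
  TP <- vapply(cutoffGrid, function(c) sum(isRef & stats$ec_ipkm < c),
               numeric(1))
  called <- vapply(cutoffGrid, function(c) sum(stats$ec_ipkm < c), numeric(1))
  FP <- called - TP
  FN <- nRef - TP
  TN <- N - nRef - FP
  curve <- data.frame(
    cutoff = cutoffGrid, TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = (TP + TN) / N,
    coverage = TP / nRef,
    precision = ifelse(called > 0, TP / called, NA_real_),
    TPR = TP / nRef,
    FPR = FP / (N - nRef))
  sel <- curve$cutoff[which.max(curve$accuracy)]
  fpr <- c(0, curve$FPR, 1)
  tpr <- c(0, curve$TPR, 1)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  methods::new("CutoffCurve", curve = curve, selectedCutoff = sel, auc = auc)
}

#' Build a confusion summary from counts
#'
#' @param nCalledEssential Genes called essential.
#' @param truePositives Called genes that are in the reference set.
#' @param nReference Reference-set size among evaluated genes.
#' @return A [ConfusionSummary-class]; false positives, false negatives and
#'   coverage percent follow by arithmetic.
#' @examples
#' confusionSummary(nCalledEssential = 523, truePositives = 233,
#'                  nReference = 301)
#' @export
confusionSummary <- function(nCalledEssential, truePositives, nReference) {
  methods::new("ConfusionSummary",
    nCalledEssential = nCalledEssential,
    nReference = nReference,
    truePositives = truePositives,
    falsePositives = nCalledEssential - truePositives,
    falseNegatives = nReference - truePositives,
    coveragePercent = if (nReference > 0) 100 * truePositives / nReference
                      else NaN)
}

#' Call essential genes at a fixed ecIPKM cutoff
#'
#' A gene is called essential iff its `ec_ipkm` is strictly below the
#' cutoff (a tie at exactly the cutoff is nonessential). Genes flagged
#' `excluded` (e.g. phantom annotations) are dropped before confusion
#' counting. When the stats carry a reference label column (`essential`,
#' the emulated reference-database flag), a [ConfusionSummary-class] is
#' computed against it.
#'
#' @param stats Per-gene statistics from [geneStats()].
#' @param cutoff Positive ecIPKM cutoff (default 2.2, the value calibrated
#'   on a hypersaturated ~400k-site E. coli library; re-calibrate per
#'   dataset with [sweepCutoffs()]).
#' @param referenceColumn Name of the logical reference-label column.
#' @return A list: `stats` (input plus a `call` column, excluded genes
#'   removed) and `summary` (a [ConfusionSummary-class], or `NULL` when no
#'   reference labels are present).
#' @export
callEssential <- function(stats, cutoff = 2.2,
                          referenceColumn = "essential") {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive")
  if ("excluded" %in% names(stats)) stats <- stats[!stats$excluded, ]
  stats$call <- ifelse(stats$ec_ipkm < cutoff, "essential", "nonessential")
  summary <- NULL
  if (referenceColumn %in% names(stats)) {
    isRef <- as.logical(stats[[referenceColumn]])
    called <- stats$call == "essential"
    summary <- confusionSummary(
      nCalledEssential = sum(called),
      truePositives = sum(called & isRef),
      nReference = sum(isRef))
  }
  list(stats = stats, summary = summary)
}

#' Three-way overlap of two call sets with the reference set
#'
#' Computes the seven-region Venn partition of two essential-gene call sets
#' and the reference set, after removing an exclusion list (e.g. phantom
#' genes) from all three, plus each call set's coverage of the reference.
#'
#' @param callsetA,callsetB Character vectors of called gene ids.
#' @param reference Character vector of reference essential gene ids.
#' @param exclusions Gene ids removed from all sets before counting.
#' @return A list with `partition` (named counts: `A_only`, `B_only`,
#'   `R_only`, `AB_only`, `AR_only`, `BR_only`, `ABR`) and `coverage`
#'   (named fractions of the reference covered by A and by B).
#' @export
compareCallsets <- function(callsetA, callsetB, reference,
                            exclusions = character(0)) {
  A <- setdiff(unique(callsetA), exclusions)
  B <- setdiff(unique(callsetB), exclusions)
  R <- setdiff(unique(reference), exclusions)
  all3 <- union(union(A, B), R)
  inA <- all3 %in% A
  inB <- all3 %in% B
  inR <- all3 %in% R
  partition <- c(
    A_only = sum(inA & !inB & !inR),
    B_only = sum(!inA & inB & !inR),
    R_only = sum(!inA & !inB & inR),
    AB_only = sum(inA & inB & !inR),
    AR_only = sum(inA & !inB & inR),
    BR_only = sum(!inA & inB & inR),
    ABR = sum(inA & inB & inR))
  coverage <- c(A = if (length(R)) length(intersect(A, R)) / length(R) else NaN,
                B = if (length(R)) length(intersect(B, R)) / length(R) else NaN)
  list(partition = partition, coverage = coverage)
}

#' Summarize ecIPKM distributions by gene group
#'
#' @param stats Per-gene statistics from [geneStats()].
#' @param groups Named list of gene-id vectors (e.g. all genes, reference
#'   essentials, pseudogenes). Empty groups are omitted with a warning.
#' @return data.frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max` of `ec_ipkm`.
#' @export
summarizeDistributions <- function(stats, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    v <- stats$ec_ipkm[stats$gene_id %in% groups[[g]]]
    if (length(v) == 0L) {
      warning("group '", g, "' is empty; omitted")
      return(NULL)
    }
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  })
  do.call(rbind, rows)
}
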