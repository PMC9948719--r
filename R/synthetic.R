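#' Configure a synthetic Tn-Seq study
#'
#' Builds the parameter set for the synthetic-data generator. The defaults
#' emulate, at 500-kb scale, a hypersaturated insertion landscape on a
#' circular bacterial chromosome: roughly one gene per kilobase, ~0.1 unique
#' insertion sites per bp of background, strong insertion depletion inside
#' essential-gene cores (but not in the permissive terminal 4% of each gene,
#' nor in a tolerated 3'-terminal subdomain of some essential genes), and
#' near-complete suppression inside planted protein-protected intervals.
#'
#' @param genomeLength Genome length in bp (default 500,000; scale up to a
#'   full ~4.6-Mb chromosome as needed).
#' @param gcFraction Target GC proportion (default 0.508).
#' @param nGenes Number of genes (default 400).
#' @param meanGeneLength Mean gene length in bp (default 900).
#' @param fractionEssential Proportion of genes that are essential
#'   (default 0.07).
#' @param fractionPseudogene Proportion of genes that are pseudogenes
#'   (default 0.03).
#' @param fractionEssentialWithDispensableDomain Proportion of essential
#'   genes whose 3'-terminal 30% tolerates insertion (default 0.2).
#' @param endPermissiveFraction Tolerated fraction at each gene end
#'   (default 0.04).
#' @param nInsertions Unique insertion sites to place (default 50,000).
#' @param essentialBodyRateRatio Relative insertion rate inside essential
#'   cores (default 0.005).
#' @param protectedRegionCount,protectedRegionLength Planted protected
#'   intervals: how many (default 50) and how long (default 500 bp).
#' @param protectionRateRatio Relative insertion rate inside protected
#'   intervals (default 0.01).
#' @param readCountMu,readCountSize Negative-binomial parameters of the
#'   auxiliary per-site read counts, drawn as `1 + rnbinom(mu, size)`
#'   (defaults 4 and 2, i.e. mean 5 reads per site).
#' @param seed Integer seed; the full generated study is a deterministic
#'   function of the config.
#' @return A validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(genomeLength = 50000, nGenes = 40, nInsertions = 5000)
#' cfg
#' @export
synthConfig <- function(genomeLength = 500000,
                        gcFraction = 0.508,
                        nGenes = 400,
                        meanGeneLength = 900,
                        fractionEssential = 0.07,
                        fractionPseudogene = 0.03,
                        fractionEssentialWithDispensableDomain = 0.2,
                        endPermissiveFraction = 0.04,
                        nInsertions = 50000,
                        essentialBodyRateRatio = 0.005,
                        protectedRegionCount = 50,
                        protectedRegionLength = 500,
                        protectionRateRatio = 0.01,
                        readCountMu = 4,
                        readCountSize = 2,
                        seed = 1L) {
  methods::new("SynthConfig",
    genomeLength = genomeLength, gcFraction = gcFraction, nGenes = nGenes,
    meanGeneLength = meanGeneLength, fractionEssential = fractionEssential,
    fractionPseudogene = fractionPseudogene,
    fractionEssentialWithDispensableDomain =
      fractionEssentialWithDispensableDomain,
    endPermissiveFraction = endPermissiveFraction,
    nInsertions = nInsertions,
    essentialBodyRateRatio = essentialBodyRateRatio,
    protectedRegionCount = protectedRegionCount,
    protectedRegionLength = protectedRegionLength,
    protectionRateRatio = protectionRateRatio,
    readCountMu = readCountMu, readCountSize = readCountSize,
    seed = seed)
}

.synthFields <- c(
  "genomeLength", "gcFraction", "nGenes", "meanGeneLength",
  "fractionEssential", "fractionPseudogene",
  "fractionEssentialWithDispensableDomain", "endPermissiveFraction",
  "nInsertions", "essentialBodyRateRatio", "protectedRegionCount",
  "protectedRegionLength", "protectionRateRatio", "readCountMu",
  "readCountSize", "seed")

#' Read / write a generator config as flat YAML
#'
#' The config round-trips through a flat key-value YAML file, so a study is
#' fully described by one small text file.
#'
#' @param config A [SynthConfig-class] (for writing).
#' @param path YAML file path.
#' @return `readSynthConfig` returns a [SynthConfig-class];
#'   `writeSynthConfig` returns `path` invisibly.
#' @export
writeSynthConfig <- function(config, path) {
  vals <- lapply(.synthFields, function(f) methods::slot(config, f))
  names(vals) <- .synthFields
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeSynthConfig
#' @export
readSynthConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .synthFields)
  if (length(unknown))
    stop("invalid config: unknown keys: ", paste(unknown, collapse = ", "))
  do.call(synthConfig, vals)
}

#' Generate a random genome sequence
#'
#' Bases are i.i.d. draws matching the configured GC fraction (G and C each
#' with probability `gcFraction/2`); there is no dinucleotide structure, which
#' is sufficient for composition diagnostics.
#'
#' @param config A [SynthConfig-class].
#' @param name Replicon name for the model.
#' @return A circular [GenomeModel-class] with the sequence attached.
#' @export
generateGenome <- function(config, name = "synth") {
  methods::validObject(config)
  L <- config@genomeLength
  set.seed(.stageSeed(config@seed, "genome"))
  gc <- config@gcFraction
  bases <- sample(c("A", "T", "G", "C"), size = L, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  GenomeModel(name = name, length = L, circular = TRUE,
              sequence = paste(bases, collapse = ""))
}

#' Generate a gene annotation and its ground truth
#'
#' Places `nGenes` non-overlapping genes on the genome (lengths gamma-
#' distributed around `meanGeneLength`, random gaps, random strands), labels
#' exactly `round(nGenes * fraction)` of them essential and pseudogene, marks
#' a subset of essential genes as carrying a dispensable 3'-terminal 30%
#' domain, plants the protected intervals, and records the per-base relative
#' insertion-rate vector that [simulateInsertions()] will draw from:
#' background 1.0, essential cores (excluding the permissive terminal
#' `endPermissiveFraction` of the gene and any dispensable domain) multiplied
#' by `essentialBodyRateRatio`, protected intervals multiplied by
#' `protectionRateRatio`.
#'
#' @param config A [SynthConfig-class].
#' @param genome The [GenomeModel-class] from [generateGenome()] (only its
#'   length is used).
#' @return A list with elements `genes` (data.frame with columns `gene_id`,
#'   `start`, `end`, `strand`, `essential`, `pseudo`, `excluded`) and `truth`
#'   (a [GroundTruth-class]).
#' @export
generateAnnotation <- function(config, genome) {
  methods::validObject(config)
  L <- genomeLength(genome)
  n <- as.integer(config@nGenes)
  if (n * config@meanGeneLength > 0.9 * L)
    stop("invalid config: genes cannot be packed into 90% of the genome")
  set.seed(.stageSeed(config@seed, "annotation"))

  if (n > 0) {
    # gamma-distributed lengths (shape 4), floored at 150 bp
    len <- pmax(150, round(stats::rgamma(n, shape = 4,
                                         rate = 4 / config@meanGeneLength)))
    # rescale if an unlucky draw overshoots the packing budget
    if (sum(len) > 0.9 * L)
      len <- pmax(150, floor(len * (0.9 * L) / sum(len)))
    slack <- L - sum(len)
    gapw <- as.vector(stats::rmultinom(1, size = slack, prob = rep(1, n + 1)))
    start <- cumsum(c(gapw[seq_len(n)])) + cumsum(c(0, len[-n]))
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("sg%04d", seq_len(n))

    nEss <- round(n * config@fractionEssential)
    nPse <- round(n * config@fractionPseudogene)
    cls <- rep("nonessential", n)
    pick <- sample.int(n, nEss + nPse)
    cls[pick[seq_len(nEss)]] <- "essential"
    if (nPse > 0) cls[pick[nEss + seq_len(nPse)]] <- "pseudogene"
    nDisp <- round(nEss * config@fractionEssentialWithDispensableDomain)
    essIdx <- which(cls == "essential")
    dispIdx <- if (nDisp > 0) sample(essIdx, nDisp) else integer(0)
    cls[dispIdx] <- "essential_with_dispensable_domain"

    # dispensable domain = 3'-proximal 30% of the gene span (strand aware)
    domain_start <- rep(NA_real_, n)
    domain_end <- rep(NA_real_, n)
    if (length(dispIdx)) {
      dl <- floor(0.3 * len[dispIdx])
      plus <- strand[dispIdx] == "+"
      domain_start[dispIdx] <- ifelse(plus, end[dispIdx] - dl, start[dispIdx])
      domain_end[dispIdx] <- ifelse(plus, end[dispIdx], start[dispIdx] + dl)
    }
  } else {
    gene_id <- character(0); start <- end <- numeric(0)
    strand <- character(0); cls <- character(0)
    domain_start <- domain_end <- numeric(0)
  }

  nProt <- as.integer(config@protectedRegionCount)
  plen <- config@protectedRegionLength
  if (nProt > 0) {
    if (plen > L) stop("invalid config: protected region longer than genome")
    pstart <- sort(floor(stats::runif(nProt, 0, L - plen)))
    prot <- data.frame(start = pstart, end = pstart + plen)
  } else {
    prot <- data.frame(start = numeric(0), end = numeric(0))
  }

  rates <- rep(1, L)
  essAll <- which(cls %in% c("essential", "essential_with_dispensable_domain"))
  for (i in essAll) {
    trim <- floor(config@endPermissiveFraction * (end[i] - start[i]))
    cs <- start[i] + trim
    ce <- end[i] - trim
    if (ce > cs) {
      idx <- seq.int(cs, ce - 1) + 1
      rates[idx] <- rates[idx] * config@essentialBodyRateRatio
      if (!is.na(domain_start[i])) {
        ds <- max(domain_start[i], cs)
        de <- min(domain_end[i], ce)
        if (de > ds)  # the tolerated domain keeps the background rate
          rates[seq.int(ds, de - 1) + 1] <- 1
      }
    }
  }
  if (nrow(prot)) {
    for (j in seq_len(nrow(prot))) {
      idx <- seq.int(prot$start[j], prot$end[j] - 1) + 1
      rates[idx] <- rates[idx] * config@protectionRateRatio
    }
  }

  genesTruth <- data.frame(
    gene_id = gene_id, start = start, end = end, strand = strand,
    class = cls, domain_start = domain_start, domain_end = domain_end,
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = gene_id, start = start, end = end, strand = strand,
    essential = cls %in% c("essential", "essential_with_dispensable_domain"),
    pseudo = cls == "pseudogene",
    excluded = rep(FALSE, length(gene_id)),
    stringsAsFactors = FALSE)
  truth <- methods::new("GroundTruth", genes = genesTruth,
                        protectedRegions = prot, rates = S4Vectors::Rle(rates))
  list(genes = genes, truth = truth)
}

#' Simulate a hypersaturated insertion landscape
#'
#' Samples `nInsertions` unique 0-based positions without replacement, with
#' per-base selection probability proportional to the ground-truth rate
#' vector (exponential-key weighted sampling), then draws auxiliary per-site
#' read counts.
#'
#' @param config A [SynthConfig-class].
#' @param genome The [GenomeModel-class].
#' @param truth The [GroundTruth-class] from [generateAnnotation()].
#' @return A [TisTable-class], sorted and strictly increasing.
#' @export
simulateInsertions <- function(config, genome, truth) {
  methods::validObject(config)
  L <- genomeLength(genome)
  rates <- as.numeric(truthRates(truth))
  if (length(rates) != L)
    stop("truth rate vector does not match genome length")
  n <- as.integer(config@nInsertions)
  if (n > sum(rates > 0))
    stop("infeasible simulation: nInsertions exceeds positions with nonzero rate")
  set.seed(.stageSeed(config@seed, "insertions"))
  keys <- stats::rexp(L) / rates          # rate 0 -> Inf, never selected
  sel <- order(keys)[seq_len(n)]
  positions <- sort(sel) - 1              # back to 0-based
  set.seed(.stageSeed(config@seed, "counts"))
  counts <- 1L + stats::rnbinom(n, mu = config@readCountMu,
                                size = config@readCountSize)
  TisTable(genome = genome, positions = positions, readCounts = counts)
}

#' Write ground truth to a TSV file
#'
#' Two sections are written: per-gene true classes and the planted protected
#' intervals (as `protected` rows with empty gene fields).
#'
#' @param truth A [GroundTruth-class].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  g <- truthGenes(truth)
  p <- truthRegions(truth)
  rows <- rbind(
    if (nrow(g)) data.frame(record = "gene", id = g$gene_id, start = g$start,
                            end = g$end, strand = g$strand, class = g$class,
                            domain_start = g$domain_start,
                            domain_end = g$domain_end),
    if (nrow(p)) data.frame(record = "protected",
                            id = sprintf("prot%04d", seq_len(nrow(p))),
                            start = p$start, end = p$end, strand = ".",
                            class = "protected", domain_start = NA,
                            domain_end = NA))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write binding/protected regions as BED
#'
#' @param regions A [BindingRegionSet-class] or a data.frame with `start`,
#'   `end`.
#' @param genome The [GenomeModel-class] (provides the chromosome name).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, genome, path) {
  if (methods::is(regions, "BindingRegionSet")) regions <- regionTable(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = genomeName(genome),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
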