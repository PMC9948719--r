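#' Create a genome model
#'
#' Constructs the coordinate frame used by every other function: a single
#' (by default circular) replicon of known length, optionally carrying its
#' nucleotide sequence.
#'
#' @param name Replicon name; used as the chromosome field in all file
#'   output.
#' @param length Replicon length in bp. Inferred from `sequence` when one is
#'   given and `length` is missing.
#' @param circular Is the replicon circular? Default `TRUE` (bacterial
#'   chromosome).
#' @param sequence Optional sequence: a [Biostrings::DNAString], a character
#'   string, or `NULL`.
#' @return A [GenomeModel-class].
#' @examples
#' GenomeModel("toy", length = 1000)
#' GenomeModel("toy", sequence = strrep("ACGT", 25))
#' @export
GenomeModel <- function(name, length = NULL, circular = TRUE,
                        sequence = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is.null(length)) {
    if (is.null(sequence))
      stop("invalid config: either length or sequence must be given")
    length <- base::length(sequence)
  }
  if (length <= 0)
    stop("invalid config: genome length must be positive")
  methods::new("GenomeModel", name = name, length = as.numeric(length),
               circular = circular, sequence = sequence)
}

#' Read a genome from a FASTA file
#'
#' Loads the first (or named) record of a FASTA file as a [GenomeModel-class].
#'
#' @param path FASTA file.
#' @param circular Topology flag for the resulting model.
#' @param record Record name to pick; default the first record.
#' @return A [GenomeModel-class] with the sequence attached.
#' @export
readGenomeFasta <- function(path, circular = TRUE, record = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  idx <- 1L
  if (!is.null(record)) {
    idx <- match(record, sub("\\s.*$", "", names(set)))
    if (is.na(idx)) stop("record not found in FASTA: ", record)
  }
  GenomeModel(name = sub("\\s.*$", "", names(set)[idx]),
              sequence = set[[idx]], circular = circular)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [GenomeModel-class] with a materialised sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  if (is.null(genomeSequence(genome)))
    stop("missing data: genome has no sequence to write")
  set <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(set) <- genomeName(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Genome-wide GC content
#'
#' GC proportion of the full genome sequence, with `N` bases excluded from
#' numerator and denominator.
#'
#' @param genome A [GenomeModel-class] with a sequence.
#' @return GC proportion in `[0, 1]`.
#' @examples
#' g <- GenomeModel("toy", sequence = "GGCCAATT")
#' gcContent(g)  # 0.5
#' @export
gcContent <- function(genome) {
  seqn <- genomeSequence(genome)
  if (is.null(seqn)) stop("missing data: genome has no sequence")
  freq <- Biostrings::alphabetFrequency(seqn)
  gc <- freq[["G"]] + freq[["C"]]
  acgt <- gc + freq[["A"]] + freq[["T"]]
  if (acgt == 0) stop("sequence has no A/C/G/T bases")
  gc / acgt
}
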