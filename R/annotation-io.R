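#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 input uses feature type `gene` and recognizes the attributes
#' `essential=true|false` (the reference essential-gene label) and
#' `pseudo=true|false`; BED6 input carries only coordinates, name and
#' strand (labels default to `FALSE` and can be attached afterwards from a
#' gene-id list, see [readGeneIdList()]). Coordinates are returned 0-based
#' half-open.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param genome Optional [GenomeModel-class] for range validation.
#' @return data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `essential`, `pseudo`, `excluded`.
#' @export
readGeneAnnotation <- function(path, format = c("gff3", "bed"),
                               genome = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3"
                                           else "BED")
  if (format == "gff3" && "type" %in% names(GenomicRanges::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  md <- GenomicRanges::mcols(gr)
  ids <- if (format == "gff3" && "ID" %in% names(md)) as.character(gr$ID)
         else if ("name" %in% names(md)) as.character(gr$name)
         else sprintf("gene%05d", seq_along(gr))
  asFlag <- function(col) {
    if (col %in% names(md)) tolower(as.character(md[[col]])) %in%
      c("true", "1", "yes")
    else rep(FALSE, length(gr))
  }
  genes <- data.frame(
    gene_id = ids,
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    essential = asFlag("essential"),
    pseudo = asFlag("pseudo"),
    excluded = rep(FALSE, length(gr)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in annotation: ", path)
  if (any(genes$start >= genes$end))
    stop("invalid annotation: gene with start >= end in ", path)
  if (!is.null(genome)) {
    if (any(genes$start < 0))
      stop("range error: negative gene start in ", path)
    over <- genes$end > genomeLength(genome)
    if (any(over) && !isCircular(genome))
      stop("range error: gene beyond the end of a linear genome in ", path)
  }
  genes[order(genes$start), , drop = FALSE]
}

#' Write a gene annotation as GFF3 and/or BED6
#'
#' GFF3 output records each gene with attributes `ID`, `essential` and
#' `pseudo`; BED6 output carries `gene_id` in the name column.
#'
#' @param genes Gene data.frame (see [readGeneAnnotation()]).
#' @param genome A [GenomeModel-class] (chromosome name).
#' @param path Output file.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(genes, genome, path,
                                format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = genomeName(genome),
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$essential <- ifelse(genes$essential, "true", "false")
    gr$pseudo <- ifelse(genes$pseudo, "true", "false")
    gr$source <- "tnseqr"
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    gr$name <- genes$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Read a plain gene-id list
#'
#' One gene id per line, `#` comments and blank lines ignored. Used for
#' reference essential-gene sets and exclusion (phantom-gene) lists.
#'
#' @param path Text file.
#' @return Character vector of ids.
#' @export
readGeneIdList <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read protein-binding regions from BED or narrowPeak
#'
#' Columns beyond the first three are optional; in narrowPeak-dialect files
#' column 9 is taken as `-log10(q)` and stored as a `qvalue` column.
#' Coordinates are returned 0-based half-open and sorted by start.
#'
#' @param path BED / narrowPeak file.
#' @param proteinName Name for the resulting set; defaults to the file base
#'   name.
#' @param genome Optional [GenomeModel-class] for range validation.
#' @return A [BindingRegionSet-class].
#' @export
readBindingRegions <- function(path, proteinName = NULL, genome = NULL) {
  if (is.null(proteinName))
    proteinName <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L)
    stop("parse error: region file needs at least 3 BED columns: ", path)
  regions <- data.frame(start = as.numeric(tab[[2]]),
                        end = as.numeric(tab[[3]]))
  if (ncol(tab) >= 9L)
    regions$qvalue <- 10^(-as.numeric(tab[[9]]))
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  rownames(regions) <- NULL
  if (!is.null(genome) &&
      (any(regions$start < 0) || any(regions$end > genomeLength(genome))))
    stop("range error: region outside [0, genome length) in ", path)
  methods::new("BindingRegionSet", proteinName = proteinName,
               regions = regions)
}

#' Construct a binding-region set from coordinates
#'
#' @param proteinName Protein name.
#' @param start,end Regions in 0-based half-open coordinates.
#' @param qvalue Optional per-region q-values.
#' @return A [BindingRegionSet-class].
#' @export
bindingRegionSet <- function(proteinName, start, end, qvalue = NULL) {
  o <- order(start)
  regions <- data.frame(start = as.numeric(start)[o],
                        end = as.numeric(end)[o])
  if (!is.null(qvalue)) regions$qvalue <- qvalue[o]
  methods::new("BindingRegionSet", proteinName = proteinName,
               regions = regions)
}
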