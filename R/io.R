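## File readers/writers. The only functions in the package that touch disk.
## Internal coordinates are 1-based closed (GRanges convention); BED and
## BedGraph are converted from/to their native 0-based half-open form at this
## boundary, GFF3 is native 1-based closed.

#' Read a genome from FASTA
#'
#' Sequences are upper-cased and restricted to the alphabet A, C, G, T, N;
#' any other character is a format error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet}, one entry per contig, with unique names.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings first: the DNA reader silently drops characters
  # outside its alphabet, which must be a named format error instead
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("illegal characters (not A/C/G/T/N) in record: ",
         paste(names(seqs)[bad], collapse = ", "))
  checkGenome(DNAStringSet(setNames(chars, names(seqs))))
}

## Alphabet/zero-length validation shared by readGenome and the simulator.
checkGenome <- function(seqs) {
  if (any(width(seqs) < 1L))
    stop("zero-length contig: ",
         paste(names(seqs)[width(seqs) < 1L], collapse = ", "))
  freq <- letterFrequency(seqs, letters = "ACGTN")
  bad <- rowSums(freq) < width(seqs)
  if (any(bad))
    stop("illegal characters (not A/C/G/T/N) in record: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write a genome to FASTA
#' @param genome a \code{DNAStringSet}.
#' @param path output path.
#' @export
writeGenome <- function(genome, path) writeXStringSet(genome, path)

#' Read a gene annotation from GFF3
#'
#' Keeps \code{gene} features; the attributes \code{ID} (or
#' \code{locus_tag}), \code{operon_id} and \code{tss} populate the
#' \code{gene_id}, \code{unit_id} and \code{tss} metadata columns.  Genes
#' without an \code{operon_id} form singleton transcriptional units.
#'
#' @param path path to a GFF3 file.
#' @param genome optional \code{DNAStringSet}; if given, features on unknown
#'   contigs or beyond a contig end are an error.
#' @return a sorted \code{GRanges} with metadata columns \code{gene_id},
#'   \code{unit_id} and \code{tss}.
#' @export
readAnnotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  ids <- if (!is.null(gr$ID) && !all(is.na(gr$ID))) gr$ID else gr$locus_tag
  if (is.null(ids) || any(is.na(ids) | ids == ""))
    stop("every gene needs an ID or locus_tag attribute")
  op <- if (is.null(gr$operon_id)) rep(NA_character_, length(gr)) else
    as.character(gr$operon_id)
  tss <- if (is.null(gr$tss)) rep(NA_integer_, length(gr)) else
    suppressWarnings(as.integer(gr$tss))
  ann <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(ann) <- DataFrame(gene_id = as.character(ids),
                          unit_id = ifelse(is.na(op), as.character(ids), op),
                          tss = tss)
  checkAnnotation(sort(ann), genome)
}

checkAnnotation <- function(ann, genome = NULL) {
  if (any(!as.character(strand(ann)) %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids")
  if (!is.null(genome)) {
    unknown <- !(as.character(seqnames(ann)) %in% names(genome))
    if (any(unknown))
      stop("gene on contig absent from genome: ",
           paste(unique(as.character(seqnames(ann))[unknown]), collapse = ", "))
    lens <- width(genome)[match(as.character(seqnames(ann)), names(genome))]
    if (any(end(ann) > lens)) stop("gene extends beyond contig end")
  }
  ann
}

#' Write a gene annotation to GFF3
#' @param annotation a \code{GRanges} as returned by
#'   \code{\link{readAnnotation}}.
#' @param path output path.
#' @export
writeAnnotation <- function(annotation, path) {
  out <- annotation
  out$type <- "gene"
  out$source <- "sosmap"
  out$ID <- out$gene_id
  out$operon_id <- out$unit_id
  rtracklayer::export(out, path, format = "gff3")
}

#' First gene of every transcriptional unit
#'
#' A transcriptional unit (operon) is the set of genes sharing a
#' \code{unit_id}; its first gene is the 5'-most on the unit's strand and is
#' the gene whose promoter carries the unit's regulatory signal.
#'
#' @param annotation annotation \code{GRanges}.
#' @return a \code{GRanges} with one range per unit and metadata columns
#'   \code{gene_id}, \code{unit_id}, \code{tss} and \code{startCodon}
#'   (1-based genomic position of the first base of the start codon).
#' @export
firstGenes <- function(annotation) {
  sp <- split(seq_along(annotation), annotation$unit_id)
  idx <- vapply(sp, function(i) {
    s <- as.character(strand(annotation))[i[1]]
    if (s == "+") i[which.min(start(annotation)[i])]
    else i[which.max(end(annotation)[i])]
  }, integer(1))
  fg <- annotation[idx]
  fg$startCodon <- startCodonPos(fg)
  fg
}

## 1-based genomic position of the first base of a gene's start codon.
startCodonPos <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Read a coverage track
#'
#' BedGraph files are interpreted as per-base depth; BED files as read-start
#' positions, each read contributing depth 1 at its start coordinate.
#'
#' @param path path to a BedGraph (\code{.bedgraph}/\code{.bg}) or BED file.
#' @param genome \code{DNAStringSet} defining contigs and lengths.
#' @return an \code{RleList} of per-base depth, one element per contig of
#'   \code{genome} (zero where uncovered).
#' @export
readCoverage <- function(path, genome) {
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
    "bedGraph" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  lens <- setNames(width(genome), names(genome))
  if (length(gr)) {
    unknown <- !(as.character(seqnames(gr)) %in% names(lens))
    if (any(unknown)) stop("interval on unknown contig")
    if (any(end(gr) > lens[as.character(seqnames(gr))]) || any(start(gr) < 1L))
      stop("interval outside contig bounds")
  }
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- lens
  if (fmt == "bedGraph") {
    if (length(gr) > 1L) {
      hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                          drop.redundant = TRUE)
      if (length(hits))
        stop("overlapping BedGraph intervals give ambiguous depth")
    }
    cov <- coverage(gr, weight = gr$score)
  } else {
    starts <- GenomicRanges::resize(gr, width = 1L, fix = "start",
                                    ignore.strand = TRUE)
    cov <- coverage(starts)
  }
  cov[names(lens)]
}

#' Write a coverage track to BedGraph
#' @param cov an \code{RleList} of per-base depth.
#' @param path output path.
#' @export
writeCoverage <- function(cov, path) {
  gr <- GenomicRanges::bindAsGRanges(score = cov)
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' Write peaks to a BED-style file
#'
#' Columns: chrom, start (0-based), end, name, score (max log2 enrichment,
#' 6 significant digits), strand, summit (0-based), window count.  The
#' summit is in column 7.
#'
#' @param peaks peak \code{GRanges} from \code{\link{callPeaks}}.
#' @param path output path.
#' @export
writePeaks <- function(peaks, path) {
  if (length(peaks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L, end = end(peaks),
    name = if (length(peaks)) peaks$name else character(0),
    score = signif(peaks$maxLog2Enrichment, 6),
    strand = ".",
    summit = peaks$summit - 1L,
    windowCount = peaks$windowCount)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read peaks written by \code{\link{writePeaks}}
#' @param path path to the BED file.
#' @return a peak \code{GRanges}.
#' @export
readPeaks <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "summit",
            "windowCount")
  df <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               colClasses = c("character", "integer", "integer", "character",
                              "numeric", "character", "integer", "integer")),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L)
    return(GRanges(name = character(0), summit = integer(0),
                   maxLog2Enrichment = numeric(0), windowCount = integer(0)))
  GRanges(df$chrom, IRanges(df$start + 1L, df$end),
          name = df$name, summit = df$summit + 1L,
          maxLog2Enrichment = df$score, windowCount = df$windowCount)
}

#' Write/read a tab-separated table
#'
#' Tables carry a header row; numeric columns are rendered with 6
#' significant digits.
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
writeTable <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeTable
#' @export
readTable <- function(path) read.delim(path, check.names = FALSE)

#' Write a window grid as a SAF-style table
#'
#' Columns GeneID, Chr, Start, End, Strand with 1-based closed coordinates,
#' the format consumed by featureCounts-style quantifiers.
#'
#' @param grid window \code{GRanges} from \code{\link{makeWindows}}.
#' @param path output path.
#' @export
writeWindowTable <- function(grid, path) {
  df <- data.frame(
    GeneID = sprintf("%s_%d", as.character(seqnames(grid)), start(grid)),
    Chr = as.character(seqnames(grid)),
    Start = start(grid), End = end(grid), Strand = "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
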