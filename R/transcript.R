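#' Construct a transcript
#'
#' The universal currency of the package: a stranded chain of exons on one
#' sequence, with optional CDS boundaries.  All coordinates are 0-based
#' half-open ([start, end)); GTF conversion happens only at I/O time.
#'
#' @param transcript_id,gene_id identifier strings.
#' @param seqid sequence (chromosome/region) identifier.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of equal length; exons must
#'   be disjoint.  They are sorted by start internally.
#' @param cds_start,cds_end genomic offsets (0-based half-open) of the
#'   translated region, or `NULL` for a non-coding record.  Both or neither
#'   must be given, and both must fall inside the exon union.
#' @param source_tag one of `"KNOWN"`, `"PREDICTED"`, `"MIXTURE"` marking the
#'   annotation source (reference set, de novo prediction, or their merge).
#' @return an object of class `"transcript"`.
#' @export
transcript <- function(transcript_id, gene_id, seqid, strand,
                       exon_starts, exon_ends,
                       cds_start = NULL, cds_end = NULL,
                       source_tag = "KNOWN") {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!source_tag %in% c("KNOWN", "PREDICTED", "MIXTURE"))
    stop("unknown source_tag: ", source_tag, call. = FALSE)
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends   <- as.integer(exon_ends[o])
  if (any(exon_starts < 0L) || any(exon_ends <= exon_starts))
    stop("exons must satisfy 0 <= start < end", call. = FALSE)
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))
    stop("exons must be pairwise disjoint", call. = FALSE)
  if (is.null(cds_start) != is.null(cds_end))
    stop("cds_start and cds_end must be given together", call. = FALSE)
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
    if (cds_start >= cds_end)
      stop("cds_start must be < cds_end", call. = FALSE)
    inside <- function(p) any(exon_starts <= p & p < exon_ends)
    if (!inside(cds_start) || !inside(cds_end - 1L))
      stop("CDS boundaries must fall inside the exon union", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 seqid = seqid, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = cds_start, cds_end = cds_end,
                 source_tag = source_tag),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s:%s %d exon(s), span %d-%d%s>\n",
              x$transcript_id, x$gene_id, x$seqid, x$strand,
              length(x$exon_starts), min(x$exon_starts), max(x$exon_ends),
              if (is.null(x$cds_start)) "" else
                sprintf(", CDS %d-%d", x$cds_start, x$cds_end)))
  invisible(x)
}

n_exons <- function(tx) length(tx$exon_starts)

#' Introns of a transcript
#'
#' @param tx a [transcript()].
#' @return matrix with columns `start`, `end` (0-based half-open), one row
#'   per intron; zero rows for single-exon transcripts.
#' @export
tx_introns <- function(tx) {
  n <- n_exons(tx)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exon_ends[-n], end = tx$exon_starts[-1L])
}

#' Restrict exons to the CDS region
#'
#' Drops purely untranslated exons and trims partial ones, yielding the
#' exon chain of the coding region only.
#'
#' @param tx a coding [transcript()].
#' @return matrix with columns `start`, `end`.
#' @export
tx_cds_exons <- function(tx) {
  if (is.null(tx$cds_start))
    stop("transcript ", tx$transcript_id, " has no CDS", call. = FALSE)
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

# Internal CDS junctions as a character key vector "seqid:donor-acceptor:strand"
# where donor/acceptor are the genomic offsets of the intron boundaries
# between consecutive CDS exons.
tx_cds_junction_keys <- function(tx) {
  ce <- tx_cds_exons(tx)
  n <- nrow(ce)
  if (n < 2L) return(character(0))
  sprintf("%s:%d-%d:%s", tx$seqid, ce[-n, "end"], ce[-1L, "start"], tx$strand)
}

# Total exonic length / CDS length in nt.
tx_exonic_length <- function(tx) sum(tx$exon_ends - tx$exon_starts)
tx_cds_length <- function(tx) { ce <- tx_cds_exons(tx); sum(ce[, 2] - ce[, 1]) }

# Canonical string identifying the ordered CDS exon coordinates + strand,
# used for dedup and exact-match evaluation.
tx_cds_key <- function(tx) {
  ce <- tx_cds_exons(tx)
  paste0(tx$seqid, ":", tx$strand, ":",
         paste(ce[, 1], ce[, 2], sep = "-", collapse = ","))
}

#' Spliced CDS nucleotide sequence of a transcript
#'
#' Concatenates the CDS exon pieces in genomic order and
#' reverse-complements for minus-strand transcripts, so the result reads
#' 5'->3' starting at the start codon.
#'
#' @param tx a coding [transcript()].
#' @param genome named character vector (or list) of sequences.
#' @return single character string.
#' @export
tx_cds_seq <- function(tx, genome) {
  chrom <- genome[[tx$seqid]]
  if (is.null(chrom)) stop("sequence not in genome: ", tx$seqid, call. = FALSE)
  ce <- tx_cds_exons(tx)
  s <- paste(substring(chrom, ce[, 1] + 1L, ce[, 2]), collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Check for a complete open reading frame
#'
#' A complete ORF starts with ATG, ends with a stop codon, has length a
#' multiple of three and contains no in-frame internal stop.
#'
#' @param tx a coding [transcript()].
#' @param genome named character vector of sequences.
#' @return logical scalar.
#' @export
is_complete_orf <- function(tx, genome) {
  if (is.null(tx$cds_start)) return(FALSE)
  s <- tx_cds_seq(tx, genome)
  n <- nchar(s)
  if (n %% 3L != 0L || n < 6L) return(FALSE)
  if (substr(s, 1L, 3L) != "ATG") return(FALSE)
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  stops[length(codons)] && !any(stops[-length(codons)])
}
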