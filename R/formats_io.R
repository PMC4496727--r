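#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences; IUPAC ambiguity
#'   codes are preserved as-is.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read transcripts from a GTF file
#'
#' Consumes the GENCODE/RefSeq dialect: `exon` rows grouped by
#' `transcript_id`, `CDS` rows defining translation boundaries.  GTF is
#' 1-based closed; internal coordinates are 0-based half-open.
#'
#' @param path GTF file path.
#' @param source_tag source label stamped on every transcript
#'   (`"KNOWN"`, `"PREDICTED"`, `"MIXTURE"`).
#' @return list of [transcript()] objects, ordered by transcript_id.
#' @export
read_gtf <- function(path, source_tag = "KNOWN") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (length(gr) == 0L) return(list())
  if (is.null(md$transcript_id) || anyNA(md$transcript_id))
    stop("GTF feature without transcript_id attribute in ", path,
         call. = FALSE)
  gene_id <- if (is.null(md$gene_id)) md$transcript_id else md$gene_id
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(gene_id),
    stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cds  # CDS-only records: exons are the CDS
    transcript(ex$transcript_id[1L], ex$gene_id[1L], ex$seqid[1L],
               ex$strand[1L], ex$start, ex$end,
               cds_start = if (nrow(cds)) min(cds$start) else NULL,
               cds_end = if (nrow(cds)) max(cds$end) else NULL,
               source_tag = source_tag)
  })
  out[order(names(out))]
}

#' Write transcripts to a GTF file
#'
#' Emits `exon` and `CDS` rows in GENCODE attribute style, restoring
#' 1-based closed coordinates.
#'
#' @param transcripts list of [transcript()] objects.
#' @param path output path.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(transcripts, path, source = "isoscan") {
  lines <- unlist(lapply(transcripts, function(tx) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tx$gene_id, tx$transcript_id)
    row <- function(type, s, e)
      paste(tx$seqid, source, type, s + 1L, e, ".", tx$strand, ".",
            attr_str, sep = "\t")
    out <- row("exon", tx$exon_starts, tx$exon_ends)
    if (!is.null(tx$cds_start)) {
      ce <- tx_cds_exons(tx)
      out <- c(out, row("CDS", ce[, "start"], ce[, "end"]))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' @param path BED file (0-based half-open natively; no conversion needed).
#' @return data.frame with columns seqid, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("seqid", "start", "end",
                                       "name", "score", "strand")[1:6],
                         fill = TRUE)
  if (ncol(d) < 3L) stop("BED file needs at least 3 columns: ", path,
                         call. = FALSE)
  if (is.null(d$name)) d$name <- "."
  if (is.null(d$strand) || all(is.na(d$strand))) d$strand <- "*"
  d
}

#' Fraction of a transcript's exonic bases covered by a feature set
#'
#' Used e.g. to flag transcripts deriving more than half their exonic
#' sequence from repeat elements (L1 exonization analysis).
#'
#' @param tx a [transcript()].
#' @param features data.frame with columns `seqid`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @return fraction in `[0, 1]` of exonic bases inside the feature union.
#' @export
overlap_fraction <- function(tx, features) {
  if (length(tx$exon_starts) == 0L)
    stop("transcript has no exons", call. = FALSE)
  ex <- IRanges::IRanges(start = tx$exon_starts + 1L, end = tx$exon_ends)
  feats <- features[features$seqid == tx$seqid, , drop = FALSE]
  if (nrow(feats) == 0L) return(0)
  fr <- IRanges::reduce(IRanges::IRanges(start = feats$start + 1L,
                                         end = feats$end))
  covered <- sum(IRanges::width(IRanges::intersect(ex, fr)))
  covered / sum(IRanges::width(ex))
}

#' Read a minimal SAM subset of transcript-space alignments
#'
#' Reads are expected to have been aligned ungapped against spliced mature
#' transcripts, so only single-run match CIGARs (`<n>M`) are accepted;
#' records with any other CIGAR are dropped and counted.  Unmapped records
#' (FLAG 0x4) are skipped.
#'
#' @param path SAM file with `@SQ` header lines.
#' @return data.frame with columns `read_id`, `target_id`, `target_start`
#'   (0-based), `aligned_length`, `mismatches` (from the `NM:i` tag, NA if
#'   absent); attribute `n_rejected` counts non-`M` CIGAR records.
#' @export
read_sam_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
  targets <- sub("^.*\\tSN:([^\\t]+).*$", "\\1", sq, perl = TRUE)
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  empty <- data.frame(read_id = character(0), target_id = character(0),
                      target_start = integer(0), aligned_length = integer(0),
                      mismatches = integer(0))
  if (length(body) == 0L) { attr(empty, "n_rejected") <- 0L; return(empty) }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]
  if (length(f) == 0L) { attr(empty, "n_rejected") <- 0L; return(empty) }
  cigar <- vapply(f, `[`, character(1), 6L)
  ok <- grepl("^[0-9]+M$", cigar)
  n_rejected <- sum(!ok)
  f <- f[ok]
  rname <- vapply(f, `[`, character(1), 3L)
  missing <- setdiff(unique(rname), targets)
  if (length(missing))
    stop("alignment target(s) absent from @SQ header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(
    read_id = vapply(f, `[`, character(1), 1L),
    target_id = rname,
    target_start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    aligned_length = as.integer(sub("M$", "", cigar[ok])),
    mismatches = vapply(f, function(x) {
      nm <- grep("^NM:i:", x[-(1:11)], value = TRUE)
      if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else NA_integer_
    }, integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write transcript-space alignments as minimal SAM
#'
#' @param alignments data.frame as returned by [read_sam_subset()].
#' @param target_lengths named integer vector of mature-transcript lengths
#'   for the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(alignments, target_lengths, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                     as.integer(target_lengths)), con)
  if (nrow(alignments)) {
    nm <- ifelse(is.na(alignments$mismatches), 0L, alignments$mismatches)
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       alignments$read_id, alignments$target_id,
                       alignments$target_start + 1L,
                       alignments$aligned_length, nm), con)
  }
  invisible(path)
}
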