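# Published post-processing of raw k-best output: complete-ORF and
# short-intron filters, CDS-level dedup, locus clustering, and the
# gene/transcript-level sensitivity/specificity evaluation.

#' Filter and deduplicate decoded paths into candidate transcripts
#'
#' Keeps only transcripts with a complete ORF (ATG start, terminal stop,
#' no in-frame internal stop, coding length a multiple of three), removes
#' any transcript containing an intron shorter than `config$min_intron`,
#' and deduplicates by exact CDS coordinates keeping the highest-scoring
#' representative.
#'
#' @param paths list of scored paths from [kbest_decode()] (one region).
#' @param config a [decoder_config()].
#' @param genome named character vector covering the transcripts' seqids.
#' @return list of [transcript()]s, ordered by descending score.
#' @export
postfilter <- function(paths, config, genome) {
  txs <- list(); scores <- numeric(0)
  for (p in paths) {
    for (tx in p$transcripts) {
      txs[[length(txs) + 1L]] <- tx
      scores <- c(scores, p$log_score)
    }
  }
  if (!length(txs)) return(list())
  keep <- vapply(seq_along(txs), function(i) {
    tx <- txs[[i]]
    intr <- tx_introns(tx)
    if (nrow(intr) && any(intr[, "end"] - intr[, "start"] < config$min_intron))
      return(FALSE)
    is_complete_orf(tx, genome)
  }, logical(1))
  txs <- txs[keep]; scores <- scores[keep]
  if (!length(txs)) return(list())
  keys <- vapply(txs, tx_cds_key, character(1))
  o <- order(-scores)                      # highest score wins the dedup
  o <- o[!duplicated(keys[o])]
  txs[o]
}

#' Cluster transcripts into gene loci
#'
#' Single-linkage clustering of same-sequence, same-strand transcripts
#' sharing at least 1 bp of exonic overlap; a long transcript overlapping
#' two otherwise-separate clusters bridges them into one locus.  Locus
#' ids are deterministic, named by the leftmost exon coordinate.
#'
#' @param transcripts list of [transcript()]s.
#' @return named list mapping locus id to the transcripts it contains.
#' @export
cluster_loci <- function(transcripts) {
  if (!length(transcripts)) return(structure(list(), names = character(0)))
  ex <- do.call(rbind, lapply(seq_along(transcripts), function(i) {
    tx <- transcripts[[i]]
    data.frame(i = i, key = paste(tx$seqid, tx$strand),
               start = tx$exon_starts, end = tx$exon_ends)
  }))
  parent <- seq_along(transcripts)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[min(ra, rb)] <<- parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (key in unique(ex$key)) {
    sub <- ex[ex$key == key, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- sub$i[S4Vectors::queryHits(hits)]
    si <- sub$i[S4Vectors::subjectHits(hits)]
    for (h in which(qi != si)) union_(qi[h], si[h])
  }
  comp <- vapply(seq_along(transcripts), find, integer(1))
  out <- lapply(unique(comp), function(c) transcripts[comp == c])
  names(out) <- vapply(out, function(txl) {
    sprintf("%s:%s:%d", txl[[1]]$seqid, txl[[1]]$strand,
            min(vapply(txl, function(t) min(t$exon_starts), integer(1))))
  }, character(1))
  out[order(names(out))]
}

#' Gene- and transcript-level sensitivity/specificity
#'
#' A predicted transcript matches a reference transcript when their
#' ordered CDS exon coordinates and strand are identical; each predicted
#' transcript may match at most one reference transcript (greedy over
#' sorted coordinates).  A gene counts as matched when at least one of
#' its transcripts matches.  Sn = matched / reference,
#' Sp = matched / predicted, at each level.
#'
#' @param predicted,reference lists of coding [transcript()]s.
#' @return list with `transcript` and `gene` data.frames (columns
#'   `matched`, `n_reference`, `n_predicted`, `sn`, `sp`).
#' @export
evaluate_predictions <- function(predicted, reference) {
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  pk <- vapply(predicted, tx_cds_key, character(1))
  rk <- vapply(reference, tx_cds_key, character(1))
  # greedy 1-1 matching on exact keys
  pt <- table(pk); rt <- table(rk)
  common <- intersect(names(pt), names(rt))
  n_tx_match <- sum(pmin(pt[common], rt[common]))
  pg <- vapply(predicted, `[[`, "", "gene_id")
  rg <- vapply(reference, `[[`, "", "gene_id")
  ref_gene_matched <- unique(rg[rk %in% pk])
  pred_gene_matched <- unique(pg[pk %in% rk])
  list(
    transcript = data.frame(
      matched = as.integer(n_tx_match),
      n_reference = length(reference), n_predicted = length(predicted),
      sn = n_tx_match / length(reference),
      sp = if (length(predicted)) n_tx_match / length(predicted) else NA_real_),
    gene = data.frame(
      matched = length(ref_gene_matched),
      n_reference = length(unique(rg)), n_predicted = length(unique(pg)),
      sn = length(ref_gene_matched) / length(unique(rg)),
      sp = if (length(unique(pg)))
        length(pred_gene_matched) / length(unique(pg)) else NA_real_))
}

#' Predict transcripts over candidate regions of a genome
#'
#' Pads each region, decodes both strands with [kbest_decode()] (the
#' reverse strand via the reverse complement, coordinates mirrored back),
#' applies [postfilter()] and stamps genome coordinates.  Genes predicted
#' entirely inside the padding are kept.
#'
#' @param spec a [ghmm_spec()].
#' @param genome named character vector of sequences.
#' @param regions data.frame with columns `seqid`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param config a [decoder_config()].
#' @param strands strands to decode (default both).
#' @return list with `transcripts` (deduplicated, genome coordinates) and
#'   `n_paths` (per region x strand path counts).
#' @export
predict_transcripts <- function(spec, genome, regions,
                                config = decoder_config(),
                                strands = c("+", "-")) {
  all_tx <- list()
  n_paths <- NULL
  for (ri in seq_len(nrow(regions))) {
    seqid <- regions$seqid[ri]
    chrom <- genome[[seqid]]
    if (is.null(chrom)) stop("region sequence not in genome: ", seqid,
                             call. = FALSE)
    s <- max(0L, regions$start[ri] - config$padding)
    e <- min(nchar(chrom), regions$end[ri] + config$padding)
    sub <- substr(chrom, s + 1L, e)
    len <- e - s
    for (strand in strands) {
      seq_dec <- if (strand == "+") sub else revcomp(sub)
      paths <- kbest_decode(spec, seq_dec, config,
                            seqid = sprintf("r%d%s", ri, strand))
      n_paths <- rbind(n_paths, data.frame(region = ri, strand = strand,
                                           n_paths = length(paths)))
      # postfilter in region-local space, then lift to genome coordinates
      local_genome <- stats::setNames(seq_dec, sprintf("r%d%s", ri, strand))
      kept <- postfilter(paths, config, local_genome)
      for (tx in kept) {
        if (strand == "+") {
          es <- tx$exon_starts + s; ee <- tx$exon_ends + s
        } else {
          es <- s + len - rev(tx$exon_ends); ee <- s + len - rev(tx$exon_starts)
        }
        all_tx[[length(all_tx) + 1L]] <- transcript(
          transcript_id = sprintf("r%d%s.%s", ri, strand, tx$transcript_id),
          gene_id = sprintf("r%d%s.%s", ri, strand, tx$gene_id),
          seqid = seqid, strand = strand,
          exon_starts = es, exon_ends = ee,
          cds_start = min(es), cds_end = max(ee),
          source_tag = "PREDICTED")
      }
    }
  }
  # genome-level CDS dedup across overlapping regions
  if (length(all_tx)) {
    keys <- vapply(all_tx, tx_cds_key, character(1))
    all_tx <- all_tx[!duplicated(keys)]
  }
  list(transcripts = all_tx, n_paths = n_paths)
}
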