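# Classification of alternative-splicing events between coding isoforms
# of a gene into seven categories: exon skipping, alternative donor,
# alternative acceptor, intron retention, mutually exclusive exons, and
# alternative translation start/stop.  Comparison is restricted to the
# CDS region; events are identified by the set of distinguishing
# splice-site (or CDS-boundary) genomic offsets, which also supplies the
# dedup key and the per-category splice-site tally.

AS_CATEGORIES <- c("exon_skipping", "alt_donor", "alt_acceptor",
                   "intron_retention", "mutually_exclusive_exons",
                   "alt_translation_start", "alt_translation_stop")

sig_key <- function(offsets) paste(sort(unique(as.integer(offsets))),
                                   collapse = ",")

#' Classify alternative-splicing events between two isoforms
#'
#' Compares the CDS exon structures of two same-gene, same-strand
#' transcripts and emits one event per category instance:
#' \describe{
#'   \item{exon_skipping}{an internal CDS exon of one isoform absent
#'     from the other, whose flanking junctions are fused into a single
#'     junction there; signature = the skipped exon's two splice sites.}
#'   \item{alt_donor / alt_acceptor}{two junctions sharing one splice
#'     site while the other differs, the differing sites lying on
#'     overlapping exons (so exon-skipping pairs are not re-counted);
#'     donor/acceptor follow biological orientation on the strand.}
#'   \item{intron_retention}{an intron of one isoform entirely exonic in
#'     the other.}
#'   \item{mutually_exclusive_exons}{two non-overlapping internal exons,
#'     one per isoform, spliced between the same flanking sites and
#'     never co-occurring.}
#'   \item{alt_translation_start / alt_translation_stop}{differing CDS
#'     boundary; signature = the two boundary offsets.}
#' }
#'
#' @param t1,t2 coding [transcript()]s of the same gene and strand.
#' @return data.frame with columns `gene_id`, `category`, `signature`
#'   (comma-joined sorted offsets), `n_sites`, `t1`, `t2`; zero rows for
#'   identical structures.
#' @export
classify_pair <- function(t1, t2) {
  if (t1$strand != t2$strand)
    stop("cannot classify isoforms on different strands", call. = FALSE)
  ce1 <- tx_cds_exons(t1); ce2 <- tx_cds_exons(t2)
  minus <- t1$strand == "-"
  ev <- list()
  add <- function(category, offsets)
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = t1$gene_id, category = category,
      signature = sig_key(offsets), n_sites = length(unique(offsets)),
      t1 = t1$transcript_id, t2 = t2$transcript_id,
      stringsAsFactors = FALSE)

  juncs <- function(ce) {
    n <- nrow(ce)
    if (n < 2L) return(cbind(l = integer(0), r = integer(0)))
    cbind(l = ce[-n, "end"], r = ce[-1L, "start"])
  }
  j1 <- juncs(ce1); j2 <- juncs(ce2)
  has_junc <- function(j, l, r) any(j[, "l"] == l & j[, "r"] == r)
  has_exon <- function(ce, s, e) any(ce[, "start"] == s & ce[, "end"] == e)

  # --- exon skipping (checked in both directions) ---
  skip_dir <- function(ceA, jB) {
    n <- nrow(ceA)
    if (n < 3L) return()
    for (e in 2:(n - 1L)) {
      p <- ceA[e - 1L, "end"]; nx <- ceA[e + 1L, "start"]
      if (has_junc(jB, p, nx))
        add("exon_skipping", c(ceA[e, "start"], ceA[e, "end"]))
    }
  }
  skip_dir(ce1, j2); skip_dir(ce2, j1)

  # --- alt donor / acceptor ---
  # exon of A ending at l1 must overlap exon of B ending at l2 (this
  # excludes exon-skipping junction pairs); category by strand
  exon_ending <- function(ce, l) ce[ce[, "end"] == l, , drop = FALSE]
  exon_starting <- function(ce, r) ce[ce[, "start"] == r, , drop = FALSE]
  overlaps <- function(a, b)
    nrow(a) == 1L && nrow(b) == 1L && a[1, "start"] < b[1, "end"] &&
      b[1, "start"] < a[1, "end"]
  if (nrow(j1) && nrow(j2)) {
    for (a in seq_len(nrow(j1))) for (b in seq_len(nrow(j2))) {
      l1 <- j1[a, "l"]; r1 <- j1[a, "r"]
      l2 <- j2[b, "l"]; r2 <- j2[b, "r"]
      if (r1 == r2 && l1 != l2 &&
          overlaps(exon_ending(ce1, l1), exon_ending(ce2, l2)))
        add(if (minus) "alt_acceptor" else "alt_donor", c(l1, l2))
      if (l1 == l2 && r1 != r2 &&
          overlaps(exon_starting(ce1, r1), exon_starting(ce2, r2)))
        add(if (minus) "alt_donor" else "alt_acceptor", c(r1, r2))
    }
  }

  # --- intron retention (both directions) ---
  retention_dir <- function(jA, ceB) {
    for (a in seq_len(nrow(jA))) {
      l <- jA[a, "l"]; r <- jA[a, "r"]
      if (any(ceB[, "start"] <= l & r <= ceB[, "end"]))
        add("intron_retention", c(l, r))
    }
  }
  if (nrow(j1)) retention_dir(j1, ce2)
  if (nrow(j2)) retention_dir(j2, ce1)

  # --- mutually exclusive exons ---
  n1 <- nrow(ce1); n2 <- nrow(ce2)
  if (n1 >= 3L && n2 >= 3L) {
    for (e1 in 2:(n1 - 1L)) for (e2 in 2:(n2 - 1L)) {
      E1 <- ce1[e1, ]; E2 <- ce2[e2, ]
      if (E1["end"] <= E2["start"] || E2["end"] <= E1["start"]) {
        p1 <- ce1[e1 - 1L, "end"]; nx1 <- ce1[e1 + 1L, "start"]
        p2 <- ce2[e2 - 1L, "end"]; nx2 <- ce2[e2 + 1L, "start"]
        if (p1 == p2 && nx1 == nx2 &&
            !has_exon(ce2, E1["start"], E1["end"]) &&
            !has_exon(ce1, E2["start"], E2["end"]))
          add("mutually_exclusive_exons",
              c(E1["start"], E1["end"], E2["start"], E2["end"]))
      }
    }
  }

  # --- alternative translation start / stop ---
  start1 <- if (minus) max(ce1[, "end"]) else min(ce1[, "start"])
  start2 <- if (minus) max(ce2[, "end"]) else min(ce2[, "start"])
  stop1 <- if (minus) min(ce1[, "start"]) else max(ce1[, "end"])
  stop2 <- if (minus) min(ce2[, "start"]) else max(ce2[, "end"])
  if (start1 != start2) add("alt_translation_start", c(start1, start2))
  if (stop1 != stop2) add("alt_translation_stop", c(stop1, stop2))

  if (!length(ev))
    return(data.frame(gene_id = character(0), category = character(0),
                      signature = character(0), n_sites = integer(0),
                      t1 = character(0), t2 = character(0)))
  out <- do.call(rbind, ev)
  out[!duplicated(out[, c("category", "signature")]), , drop = FALSE]
}

#' Count alternative-splicing events per category across genes
#'
#' Unions [classify_pair()] over all isoform pairs within each gene and
#' deduplicates by (gene, category, signature), so the same event seen
#' in several pairs counts once.  Both the event count and the
#' splice-site tally (each event contributing its signature's site
#' count) are reported.
#'
#' @param transcripts list of coding [transcript()]s; isoforms are
#'   grouped by `gene_id`.
#' @return data.frame with one row per category: `category`, `n_events`,
#'   `n_sites`.
#' @export
count_events <- function(transcripts) {
  genes <- split(transcripts,
                 vapply(transcripts, `[[`, "", "gene_id"))
  ev <- list()
  for (txs in genes) {
    if (length(txs) < 2L) next
    for (a in seq_len(length(txs) - 1L)) for (b in (a + 1L):length(txs))
      ev[[length(ev) + 1L]] <- classify_pair(txs[[a]], txs[[b]])
  }
  all <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene_id = character(0), category = character(0),
               signature = character(0), n_sites = integer(0))
  all <- all[!duplicated(all[, c("gene_id", "category", "signature")]), ,
             drop = FALSE]
  out <- data.frame(category = AS_CATEGORIES, n_events = 0L, n_sites = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(all)) {
    tab <- table(factor(all$category, levels = AS_CATEGORIES))
    out$n_events <- as.integer(tab)
    sites <- tapply(all$n_sites, factor(all$category, levels = AS_CATEGORIES),
                    sum, default = 0L)
    out$n_sites <- as.integer(sites)
  }
  out
}

#' Transcripts-per-gene statistics
#'
#' @param transcripts list of [transcript()]s with locus-level gene ids
#'   (cluster first with [cluster_loci()] if needed).
#' @param cap histogram bucket cap: genes with more transcripts than
#'   `cap` are merged into a single `">cap"` bucket (default 20).
#' @return list with `histogram` (named counts `1`..`cap`, `">cap"`),
#'   `mean_per_gene`, and `single_isoform_multiexon_fraction` (fraction
#'   of multi-exon genes carrying a single transcript).
#' @export
transcripts_per_gene_stats <- function(transcripts, cap = 20L) {
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  per_gene <- table(gid)
  bucket <- ifelse(per_gene > cap, paste0(">", cap), as.character(per_gene))
  hist <- table(factor(bucket, levels = c(as.character(seq_len(cap)),
                                          paste0(">", cap))))
  multi <- vapply(split(transcripts, gid), function(txs)
    any(vapply(txs, function(tx) length(tx$exon_starts) > 1L, logical(1))),
    logical(1))
  n_tx <- as.integer(per_gene[names(multi)])
  list(histogram = hist,
       mean_per_gene = length(transcripts) / length(per_gene),
       single_isoform_multiexon_fraction =
         if (any(multi)) sum(multi & n_tx == 1L) / sum(multi) else NA_real_)
}
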