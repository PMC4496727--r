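# Deterministic generators for every input class the kit consumes: toy
# genomes sampled from the gene model, junction-spanning read alignments
# against mature transcripts, and peptide-identification tables.  All
# randomness flows from the seed in the fixture configuration, so fixed
# seed implies byte-identical outputs.

#' Fixture generator configuration
#'
#' @param seed integer seed driving every maker.
#' @param genome_length approximate genome length (nt).
#' @param n_genes number of gene loci to embed.
#' @param read_length simulated read length (nt; short-read scale).
#' @param coverage junction-spanning reads placed per splice junction.
#' @param min_overhang minimum nt a placed read leaves on each side of
#'   its junction (default 10, matching the standard validation L).
#' @param flank mature-transcript flank (nt).
#' @param background_coverage mean fold-coverage of plain CDS reads
#'   (gives single-exon transcripts read support).
#' @param error_rate per-base substitution rate recorded in the
#'   alignment mismatch field (0 = error-free; alignment coordinates are
#'   unaffected, mapping is assumed solved upstream).
#' @param both_strands alternate loci between + and - strands.
#' @param spec gene model to sample from (default [ghmm_default_spec()]).
#' @return list of class `"fixture_config"`.
#' @export
fixture_config <- function(seed = 1L, genome_length = 3000L, n_genes = 2L,
                           read_length = 50L, coverage = 10L,
                           min_overhang = 10L, flank = 100L,
                           background_coverage = 3,
                           error_rate = 0, both_strands = FALSE,
                           spec = ghmm_default_spec()) {
  stopifnot(seed == as.integer(seed), genome_length >= 200L, n_genes >= 1L)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 read_length = as.integer(read_length),
                 coverage = as.integer(coverage),
                 min_overhang = as.integer(min_overhang),
                 flank = as.integer(flank),
                 background_coverage = background_coverage,
                 error_rate = error_rate, both_strands = both_strands,
                 spec = spec), class = "fixture_config")
}

#' Generate a toy genome with embedded sampled genes
#'
#' Samples gene loci from the model until `n_genes` genes are collected,
#' concatenating the loci into one sequence.  Alternating loci are
#' reverse-complemented when `both_strands` is set, yielding
#' minus-strand genes.  Every truth transcript carries a complete ORF
#' and introns of at least 20 nt.
#'
#' @param config a [fixture_config()].
#' @param out_fasta,out_gtf optional paths; when given the genome and
#'   truth annotation are also written to disk.
#' @return list with `genome` (named character, sequence `chr1`),
#'   `transcripts` (truth annotation) and `paths` (per-locus true state
#'   segmentations, locus-local forward-strand coordinates).
#' @export
make_genome <- function(config, out_fasta = NULL, out_gtf = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  per_locus <- max(200L, config$genome_length %/% config$n_genes)
  seq_parts <- character(0)
  transcripts <- list()
  paths <- list()
  offset <- 0L
  gi <- 0L
  li <- 0L
  while (gi < config$n_genes) {
    li <- li + 1L
    # distinct deterministic sub-seed per locus (kept below 2^31)
    sub_seed <- (config$seed * 10007L + li) %% 2147483647L
    smp <- ghmm_sample(config$spec, per_locus, seed = sub_seed,
                       gene_prefix = sprintf("locus%d.g", li))
    if (!length(smp$transcripts)) next
    take <- seq_len(min(length(smp$transcripts), config$n_genes - gi))
    txs <- smp$transcripts[take]
    # leading pad guarantees room for mature-transcript flanks
    pad <- paste(sample(BASES, config$flank + 10L, replace = TRUE,
                        prob = config$spec$noncoding_marg), collapse = "")
    txs <- lapply(txs, function(tx) transcript(
      tx$transcript_id, tx$gene_id, tx$seqid, tx$strand,
      tx$exon_starts + nchar(pad), tx$exon_ends + nchar(pad),
      cds_start = tx$cds_start + nchar(pad),
      cds_end = tx$cds_end + nchar(pad), source_tag = tx$source_tag))
    # trim the locus shortly after the last used gene, padding the tail
    # if the sampled sequence ends too early for the downstream flank
    last_end <- max(vapply(txs, function(t) max(t$exon_ends), integer(1)))
    cut <- last_end + config$flank + 50L
    full <- paste0(pad, smp$sequence)
    if (nchar(full) < cut)
      full <- paste0(full, paste(sample(BASES, cut - nchar(full),
                                        replace = TRUE,
                                        prob = config$spec$noncoding_marg),
                                 collapse = ""))
    locus_seq <- substr(full, 1L, cut)
    minus <- config$both_strands && li %% 2L == 0L
    if (minus) {
      locus_seq <- revcomp(locus_seq)
      txs <- lapply(txs, function(tx) transcript(
        tx$transcript_id, tx$gene_id, "chr1", "-",
        cut - rev(tx$exon_ends), cut - rev(tx$exon_starts),
        cds_start = cut - tx$cds_end, cds_end = cut - tx$cds_start,
        source_tag = "KNOWN"))
    } else {
      txs <- lapply(txs, function(tx) transcript(
        tx$transcript_id, tx$gene_id, "chr1", "+",
        tx$exon_starts, tx$exon_ends,
        cds_start = tx$cds_start, cds_end = tx$cds_end,
        source_tag = "KNOWN"))
    }
    txs <- lapply(txs, function(tx) transcript(
      tx$transcript_id, tx$gene_id, "chr1", tx$strand,
      tx$exon_starts + offset, tx$exon_ends + offset,
      cds_start = tx$cds_start + offset, cds_end = tx$cds_end + offset,
      source_tag = "KNOWN"))
    seq_parts <- c(seq_parts, locus_seq)
    transcripts <- c(transcripts, txs)
    paths[[li]] <- smp$path
    offset <- offset + nchar(locus_seq)
    gi <- gi + length(txs)
  }
  genome <- stats::setNames(paste(seq_parts, collapse = ""), "chr1")
  if (!is.null(out_fasta)) write_fasta(genome, out_fasta)
  if (!is.null(out_gtf)) write_gtf(transcripts, out_gtf)
  list(genome = genome, transcripts = transcripts,
       paths = Filter(Negate(is.null), paths))
}

#' Simulate junction-spanning reads against mature transcripts
#'
#' Places `coverage` reads across every splice junction of every mature
#' transcript, with per-side overhangs of at least `min_overhang` nt,
#' plus background reads tiling the CDS.  Emits the alignments (SAM
#' convention, ungapped transcript space) together with a truth table of
#' per-junction read counts computed from the placements.
#'
#' @param transcripts truth transcripts (coding).
#' @param genome named character vector.
#' @param config a [fixture_config()].
#' @param out_sam optional path for a SAM file of the alignments.
#' @return list with `alignments` (data.frame as [read_sam_subset()]),
#'   `mature` (from [build_mature()]), `target_lengths`, and
#'   `truth` — a function `truth(L)` returning the per-junction JC
#'   data.frame at side-overhang threshold `L`.
#' @export
make_reads <- function(transcripts, genome, config, out_sam = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$read_length < 2L * config$min_overhang)
    stop("read_length must be at least 2 * min_overhang", call. = FALSE)
  set.seed((config$seed * 7919L + 13L) %% 2147483647L)
  mature <- build_mature(transcripts, genome, flank = config$flank)
  rl <- config$read_length
  reads <- list()
  ri <- 0L
  for (id in names(mature)) {
    m <- mature[[id]]
    tlen <- nchar(m$sequence)
    place <- function(s) {
      s <- max(0L, min(s, tlen - rl))
      ri <<- ri + 1L
      nm <- if (config$error_rate > 0)
        stats::rbinom(1L, rl, config$error_rate) else 0L
      reads[[ri]] <<- data.frame(
        read_id = sprintf("r%06d", ri), target_id = id,
        target_start = s, aligned_length = rl, mismatches = nm,
        stringsAsFactors = FALSE)
    }
    if (nrow(m$junctions) && config$coverage > 0L) {
      for (j in m$junctions$offset) {
        oh <- sample(seq2(config$min_overhang, rl - config$min_overhang),
                     config$coverage, replace = TRUE)
        for (o in oh) place(j - o)
      }
    }
    if (config$background_coverage > 0) {
      span <- m$cds_to - m$cds_from
      n_bg <- ceiling(config$background_coverage * span / rl)
      starts <- m$cds_from +
        floor(stats::runif(n_bg, -rl + 1, span))
      for (s in as.integer(starts)) place(s)
    }
  }
  alignments <- if (ri) do.call(rbind, reads) else
    data.frame(read_id = character(0), target_id = character(0),
               target_start = integer(0), aligned_length = integer(0),
               mismatches = integer(0))
  target_lengths <- vapply(mature, function(m) nchar(m$sequence), integer(1))
  truth <- function(L) {
    rows <- lapply(names(mature), function(id) {
      jn <- mature[[id]]$junctions
      if (nrow(jn) == 0L) return(NULL)
      sub <- alignments[alignments$target_id == id, , drop = FALSE]
      jc <- integer(nrow(jn))
      for (r in seq_len(nrow(sub))) {
        left <- jn$offset - sub$target_start[r]
        right <- sub$target_start[r] + sub$aligned_length[r] - jn$offset
        jc <- jc + as.integer(left >= L & right >= L)
      }
      data.frame(target_id = id, offset = jn$offset, key = jn$key, JC = jc,
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(NULL)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (!is.null(out_sam)) write_sam(alignments, target_lengths, out_sam)
  list(alignments = alignments, mature = mature,
       target_lengths = target_lengths, truth = truth)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a peptide-identification fixture with known truth
#'
#' Builds a hit table plus GENCODE/Swiss-Prot protein stand-ins so that
#' the candidate-call and annotation-filter outcomes are known by
#' construction.  The defaults reproduce the published worked example:
#' 61 candidate proteins of which 9 are annotated in both external
#' databases, 5 in GENCODE only and 11 in Swiss-Prot only, leaving 36
#' final novel proteins.
#'
#' @param n_candidates,n_both,n_gencode_only,n_swissprot_only candidate
#'   partition sizes.
#' @param n_noncandidates decoy VMC proteins failing the calling
#'   predicate (single unique peptide, or shared peptides only).
#' @param seed RNG seed.
#' @param out_tsv optional path for the hit TSV.
#' @return list with `hits` (data.frame), `gencode`, `swissprot`
#'   (protein sequence vectors) and `truth` (data.frame: accession,
#'   expected_candidate, expected_final).
#' @export
make_peptide_fixture <- function(n_candidates = 61L, n_both = 9L,
                                 n_gencode_only = 5L,
                                 n_swissprot_only = 11L,
                                 n_noncandidates = 10L, seed = 1L,
                                 out_tsv = NULL) {
  stopifnot(n_both + n_gencode_only + n_swissprot_only <= n_candidates)
  set.seed(seed)
  seen <- new.env(parent = emptyenv())
  rand_pep <- function(len = sample(9:12, 1L)) {
    repeat {
      p <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      if (is.null(seen[[p]])) { seen[[p]] <- TRUE; return(p) }
    }
  }
  hits <- list(); truth <- list(); gencode <- character(0)
  swissprot <- character(0)
  add_hit <- function(pep, accs)
    hits[[length(hits) + 1L]] <<- data.frame(
      peptide = pep, accessions = I(list(accs)),
      spectral_count = sample(1:20, 1L), stringsAsFactors = FALSE)
  embed <- function(peps) paste0(rand_pep(15), paste(peps, collapse = ""),
                                 rand_pep(15))
  for (i in seq_len(n_candidates)) {
    acc <- sprintf("VMC_P%03d", i)
    peps <- c(rand_pep(), rand_pep())
    for (p in peps) add_hit(p, paste0("VMC:", acc))
    in_g <- i <= n_both + n_gencode_only
    in_s <- i <= n_both || (i > n_both + n_gencode_only &&
                              i <= n_both + n_gencode_only + n_swissprot_only)
    if (in_g) gencode <- c(gencode, embed(peps))
    if (in_s) swissprot <- c(swissprot, embed(peps))
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, expected_candidate = TRUE,
      expected_final = !in_g && !in_s, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_noncandidates)) {
    acc <- sprintf("VMC_D%03d", i)
    if (i %% 2L == 0L) {
      add_hit(rand_pep(), paste0("VMC:", acc))   # one unique peptide only
    } else {
      # two peptides, both shared with a RefSeq protein (not unique)
      ref <- sprintf("REFSEQ_R%03d", i)
      add_hit(rand_pep(), c(paste0("VMC:", acc), paste0("REFSEQ:", ref)))
      add_hit(rand_pep(), c(paste0("VMC:", acc), paste0("REFSEQ:", ref)))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, expected_candidate = FALSE, expected_final = FALSE,
      stringsAsFactors = FALSE)
  }
  # filler sequences so the external DBs are non-trivial
  gencode <- c(gencode, replicate(5, rand_pep(40)))
  swissprot <- c(swissprot, replicate(5, rand_pep(40)))
  hits <- do.call(rbind, hits)
  if (!is.null(out_tsv)) {
    flat <- data.frame(peptide = hits$peptide,
                       accessions = vapply(hits$accessions, paste,
                                           character(1), collapse = ","),
                       spectral_count = hits$spectral_count)
    utils::write.table(flat, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(hits = hits, gencode = gencode, swissprot = swissprot,
       truth = do.call(rbind, truth))
}
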