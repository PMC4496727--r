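# RNA-seq validation of candidate transcripts: mature-transcript
# construction, two-sided splice-junction coverage tallies under an
# (M, L) rule, the novel-internal-junction (NIJ) filter, and tiering of
# novel transcripts into VHC / VMC / VLC across datasets.

#' Validation strategy configuration
#'
#' The standard strategy requires every internal junction to be covered
#' by at least `M = 1` read with at least `L = 10` nt on each side; the
#' stringent strategy raises the thresholds to `M >= 6` reads of
#' `L >= 8` nt (strict integer reading of "more than 5" / "more than 7").
#'
#' @param strategy `"standard"` or `"stringent"`.
#' @param L minimum nt a read must cover on each side of a junction;
#'   defaults to 10 (standard) or 8 (stringent).
#' @param M minimum number of such reads; defaults to 1 (standard) or 6
#'   (stringent).
#' @param flank nt of genomic context added around the CDS when building
#'   mature transcripts (default 100).
#' @param min_single_exon_coverage fraction of CDS bases that must be
#'   read-covered for a single-exon transcript to count as validated
#'   (default 0.9; single-exon transcripts have no junctions to test).
#' @param min_tc optional minimum fraction of CDS bases covered required
#'   of multi-exon transcripts in addition to the junction rule
#'   (default 0 = junction rule only).
#' @param max_mismatch maximum alignment mismatches tolerated (default
#'   `Inf`: records are trusted as given).
#' @return object of class `"validation_config"`.
#' @export
validation_config <- function(strategy = c("standard", "stringent"),
                              L = NULL, M = NULL, flank = 100L,
                              min_single_exon_coverage = 0.9,
                              min_tc = 0, max_mismatch = Inf) {
  strategy <- match.arg(strategy)
  if (is.null(L)) L <- if (strategy == "standard") 10L else 8L
  if (is.null(M)) M <- if (strategy == "standard") 1L else 6L
  if (strategy == "standard" && (L != 10L || M != 1L))
    stop("standard strategy fixes L = 10, M = 1", call. = FALSE)
  if (strategy == "stringent" && (M < 6L || L < 8L))
    stop("stringent strategy requires M >= 6 and L >= 8", call. = FALSE)
  stopifnot(flank >= 0L)
  structure(list(strategy = strategy, L = as.integer(L), M = as.integer(M),
                 flank = as.integer(flank),
                 min_single_exon_coverage = min_single_exon_coverage,
                 min_tc = min_tc, max_mismatch = max_mismatch),
            class = "validation_config")
}

#' Build mature transcripts (spliced CDS plus flanks)
#'
#' The alignment targets for junction validation: each coding
#' transcript's CDS is spliced and extended by `flank` nt of genomic
#' sequence upstream of the start codon and downstream of the stop codon,
#' reverse-complemented for minus-strand transcripts.  Flanks running
#' past a sequence end are truncated (their number is recorded in the
#' `n_truncated` attribute, with a warning).
#'
#' @param transcripts list of coding [transcript()]s.
#' @param genome named character vector of sequences.
#' @param flank flank length in nt (default 100).
#' @return named list (by transcript_id): each element has `sequence`,
#'   `junctions` (data.frame `offset` in mature coordinates, `key`
#'   genomic junction key), `cds_from`/`cds_to` (mature offsets of the
#'   CDS span, half-open).
#' @export
build_mature <- function(transcripts, genome, flank = 100L) {
  n_trunc <- 0L
  out <- lapply(transcripts, function(tx) {
    chrom <- genome[[tx$seqid]]
    if (is.null(chrom)) stop("sequence not in genome: ", tx$seqid,
                             call. = FALSE)
    ce <- tx_cds_exons(tx)
    up_s <- max(0L, tx$cds_start - flank)
    dn_e <- min(nchar(chrom), tx$cds_end + flank)
    if (up_s > tx$cds_start - flank || dn_e < tx$cds_end + flank)
      n_trunc <<- n_trunc + 1L
    has_up <- up_s < tx$cds_start
    pieces <- rbind(if (has_up) c(up_s, tx$cds_start), ce,
                    if (tx$cds_end < dn_e) c(tx$cds_end, dn_e))
    seq_fwd <- paste(substring(chrom, pieces[, 1] + 1L, pieces[, 2]),
                     collapse = "")
    # junction offsets in the plus-orientation mature string
    widths <- pieces[, 2] - pieces[, 1]
    # boundaries after each CDS exon except the last (skip the flank rows)
    cds_rows <- seq_len(nrow(ce)) + as.integer(has_up)
    joff <- cumsum(widths)[cds_rows[-length(cds_rows)]]
    keys <- tx_cds_junction_keys(tx)
    total <- sum(widths)
    cds_from <- if (pieces[1, 1] < tx$cds_start) widths[1] else 0L
    cds_to <- cds_from + sum(ce[, 2] - ce[, 1])
    if (tx$strand == "-") {
      seqm <- revcomp(seq_fwd)
      joff <- rev(total - joff)
      keys <- rev(keys)
      tmp <- cds_from
      cds_from <- total - cds_to
      cds_to <- total - tmp
    } else seqm <- seq_fwd
    list(sequence = seqm,
         junctions = data.frame(offset = as.integer(joff), key = keys,
                                stringsAsFactors = FALSE),
         cds_from = as.integer(cds_from), cds_to = as.integer(cds_to))
  })
  names(out) <- vapply(transcripts, `[[`, "", "transcript_id")
  if (n_trunc > 0L)
    warning(n_trunc, " mature flank(s) truncated at sequence ends",
            call. = FALSE)
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Tally splice-junction read coverage under the (M, L) rule
#'
#' A read aligned at `[s, s + len)` on a mature transcript counts for the
#' junction at mature offset `j` iff `s <= j - L` and `s + len >= j + L`,
#' i.e. it covers both adjacent exon sides with at least `L` nt each.
#' `JC` is the number of counting reads; a junction is covered iff
#' `JC >= M`.
#'
#' @param alignments data.frame from [read_sam_subset()].
#' @param mature named list from [build_mature()].
#' @param config a [validation_config()].
#' @param known_junction_keys optional character vector of junction keys
#'   present in known transcripts; when given, an `is_novel_internal`
#'   column is added.
#' @return data.frame with columns `target_id`, `offset`, `key`, `JC`,
#'   `covered` (and optionally `is_novel_internal`); attribute
#'   `n_skipped` counts alignments to unknown targets.
#' @export
tally_junctions <- function(alignments, mature, config,
                            known_junction_keys = NULL) {
  known_target <- alignments$target_id %in% names(mature)
  n_skipped <- sum(!known_target)
  if (n_skipped > 0L)
    message("tally_junctions: skipped ", n_skipped,
            " alignment(s) to unknown mature transcript ids")
  al <- alignments[known_target, , drop = FALSE]
  if (is.finite(config$max_mismatch))
    al <- al[is.na(al$mismatches) | al$mismatches <= config$max_mismatch, ,
             drop = FALSE]
  Lmin <- config$L
  rows <- lapply(names(mature), function(id) {
    jn <- mature[[id]]$junctions
    if (nrow(jn) == 0L) return(NULL)
    sub <- al[al$target_id == id, , drop = FALSE]
    jc <- vapply(jn$offset, function(j) {
      if (nrow(sub) == 0L) return(0L)
      sum(sub$target_start <= j - Lmin &
            sub$target_start + sub$aligned_length >= j + Lmin)
    }, integer(1))
    data.frame(target_id = id, offset = jn$offset, key = jn$key,
               JC = jc, covered = jc >= config$M, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(target_id = character(0), offset = integer(0),
               key = character(0), JC = integer(0), covered = logical(0))
  if (!is.null(known_junction_keys))
    out$is_novel_internal <- !(out$key %in% known_junction_keys)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fraction of CDS bases covered by at least one read
#'
#' @param alignments data.frame from [read_sam_subset()].
#' @param mature named list from [build_mature()].
#' @return named numeric vector, one fraction per mature transcript.
#' @export
cds_coverage <- function(alignments, mature) {
  vapply(names(mature), function(id) {
    m <- mature[[id]]
    span <- m$cds_to - m$cds_from
    if (span <= 0L) return(0)
    sub <- alignments[alignments$target_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) return(0)
    cov <- rep(FALSE, span)
    for (r in seq_len(nrow(sub))) {
      a <- max(sub$target_start[r], m$cds_from) - m$cds_from
      b <- min(sub$target_start[r] + sub$aligned_length[r], m$cds_to) -
        m$cds_from
      if (b > a) cov[(a + 1L):b] <- TRUE
    }
    mean(cov)
  }, numeric(1))
}

# all internal CDS junction keys of a transcript set
known_junction_set <- function(transcripts) {
  unique(unlist(lapply(transcripts, tx_cds_junction_keys)))
}

#' Tier transcripts by RNA-seq validation across datasets
#'
#' A multi-exon transcript is validated in a dataset iff all of its
#' internal CDS junctions are covered there; a single-exon transcript
#' iff at least `min_single_exon_coverage` of its CDS bases are read
#' covered (an explicit stand-in rule).  Novel transcripts (CDS absent
#' from the known set) are tiered: VHC when validated under the
#' stringent strategy in some dataset and carrying at least one novel
#' internal junction; VMC when validated under the standard strategy
#' with a novel internal junction; VLC when validated under the standard
#' strategy but single-exon or lacking novel junctions; UNVALIDATED
#' otherwise.  Known transcripts become KNOWN_VALIDATED or UNVALIDATED.
#'
#' @param transcripts list of [transcript()]s to tier.
#' @param known list of known [transcript()]s (defines known CDS keys and
#'   the known junction set).
#' @param evidence_standard,evidence_stringent lists over datasets of
#'   junction tallies from [tally_junctions()] under each strategy.
#' @param coverage_standard optional list over datasets of
#'   [cds_coverage()] vectors (needed to validate single-exon
#'   transcripts).
#' @param coverage_stringent like `coverage_standard`, for the stringent
#'   tier.
#' @param config_standard,config_stringent the [validation_config()]s the
#'   evidence was computed under.
#' @param tissue_specific_max a transcript validated in fewer than this
#'   many datasets (but at least one) is flagged tissue-specific
#'   (default 5).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `tier`, `n_datasets_validated`, `tissue_specific`, `has_nij`,
#'   `n_exons`, plus logical columns `validated_std.<i>` and
#'   `validated_str.<i>` per dataset.
#' @export
validate_transcripts <- function(transcripts, known,
                                 evidence_standard, evidence_stringent,
                                 coverage_standard = NULL,
                                 coverage_stringent = NULL,
                                 config_standard = validation_config("standard"),
                                 config_stringent = validation_config("stringent"),
                                 tissue_specific_max = 5L) {
  if (any(vapply(transcripts, function(tx) length(tx$exon_starts) == 0L,
                 logical(1))))
    stop("transcript with zero exons", call. = FALSE)
  known_keys <- vapply(known, tx_cds_key, character(1))
  known_juncs <- known_junction_set(known)
  n_ds <- length(evidence_standard)
  stopifnot(length(evidence_stringent) == n_ds)

  validated_in <- function(tx, ev, covg, cfg) {
    id <- tx$transcript_id
    keys <- tx_cds_junction_keys(tx)
    if (length(keys) == 0L) {  # single exon: coverage stand-in rule
      if (is.null(covg) || !id %in% names(covg)) return(FALSE)
      return(covg[[id]] >= cfg$min_single_exon_coverage)
    }
    sub <- ev[ev$target_id == id, , drop = FALSE]
    if (nrow(sub) < length(keys)) return(FALSE)
    ok <- all(keys %in% sub$key[sub$covered])
    if (ok && cfg$min_tc > 0) {
      if (is.null(covg) || !id %in% names(covg)) return(FALSE)
      ok <- covg[[id]] >= cfg$min_tc
    }
    ok
  }

  rows <- lapply(transcripts, function(tx) {
    keys <- tx_cds_junction_keys(tx)
    has_nij <- length(keys) > 0L && any(!keys %in% known_juncs)
    getcov <- function(lst, d) if (is.null(lst)) NULL else lst[[d]]
    v_std <- vapply(seq_len(n_ds), function(d)
      validated_in(tx, evidence_standard[[d]],
                   getcov(coverage_standard, d), config_standard), logical(1))
    v_str <- vapply(seq_len(n_ds), function(d)
      validated_in(tx, evidence_stringent[[d]],
                   getcov(coverage_stringent, d), config_stringent), logical(1))
    is_known <- tx_cds_key(tx) %in% known_keys
    tier <- if (is_known) {
      if (any(v_std)) "KNOWN_VALIDATED" else "UNVALIDATED"
    } else if (any(v_str) && has_nij) "VHC"
    else if (any(v_std) && has_nij) "VMC"
    else if (any(v_std)) "VLC"
    else "UNVALIDATED"
    n_val <- sum(v_std)
    out <- data.frame(transcript_id = tx$transcript_id, tier = tier,
                      n_datasets_validated = n_val,
                      tissue_specific = n_val >= 1L &&
                        n_val < tissue_specific_max,
                      has_nij = has_nij,
                      n_exons = length(tx$exon_starts),
                      stringsAsFactors = FALSE)
    for (d in seq_len(n_ds)) out[[paste0("validated_std.", d)]] <- v_std[d]
    for (d in seq_len(n_ds)) out[[paste0("validated_str.", d)]] <- v_str[d]
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Discovery saturation curve over dataset orderings
#'
#' Bootstraps random orderings of the datasets and reports, for each
#' prefix length, the mean number of transcripts newly validated by the
#' k-th added dataset.
#'
#' @param validated_sets list of character vectors: per dataset, the ids
#'   of transcripts validated there.
#' @param n_permutations number of random orderings (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of length `length(validated_sets)`: mean newly
#'   validated count at each position.
#' @export
saturation_curve <- function(validated_sets, n_permutations = 1000L,
                             seed = 1L) {
  n <- length(validated_sets)
  if (n < 2L) stop("need at least 2 datasets", call. = FALSE)
  set.seed(seed)
  acc <- numeric(n)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    seen <- character(0)
    for (k in seq_len(n)) {
      new <- setdiff(validated_sets[[ord[k]]], seen)
      acc[k] <- acc[k] + length(new)
      seen <- c(seen, new)
    }
  }
  acc / n_permutations
}

#' Per-tier PCR panel success rates
#'
#' @param outcomes data.frame with columns `transcript_id`, `tier` and
#'   logical `validated` (validated by at least one PCR sample).
#' @return data.frame per tier: `tier`, `assayed`, `validated`,
#'   `rate_percent`.
#' @export
pcr_panel_summary <- function(outcomes) {
  if (nrow(outcomes) == 0L) stop("empty outcome table", call. = FALSE)
  rows <- lapply(split(outcomes, outcomes$tier), function(d)
    data.frame(tier = d$tier[1L], assayed = nrow(d),
               validated = sum(d$validated),
               rate_percent = 100 * sum(d$validated) / nrow(d),
               stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
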