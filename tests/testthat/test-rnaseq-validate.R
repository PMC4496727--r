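test_that("validation strategies pin their thresholds", {
  std <- validation_config("standard")
  expect_equal(std$L, 10L); expect_equal(std$M, 1L)
  str <- validation_config("stringent")
  expect_equal(str$L, 8L); expect_equal(str$M, 6L)
  expect_error(validation_config("standard", L = 12), "standard")
  expect_error(validation_config("stringent", M = 3), "stringent")
  expect_equal(std$flank, 100L)
})

test_that("mature transcripts splice CDS plus flanks with junction offsets", {
  # two CDS exons of 60 + 90 nt, flank 100 -> mature 350, junction at 160
  set.seed(1)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  tx <- mk_tx("t1", list(c(200, 260), c(290, 380)))
  m <- build_mature(list(tx), genome, flank = 100L)[["t1"]]
  expect_equal(nchar(m$sequence), 350L)
  expect_equal(m$junctions$offset, 160L)
  expect_equal(m$cds_from, 100L)
  expect_equal(m$cds_to, 250L)
  # hand-spliced string
  expect_equal(m$sequence, paste0(substr(chrom, 101, 260),
                                  substr(chrom, 291, 380),
                                  substr(chrom, 381, 480)))

  # minus strand equals reverse complement of the plus construction
  txm <- mk_tx("t1m", list(c(200, 260), c(290, 380)), strand = "-")
  mm <- build_mature(list(txm), genome, flank = 100L)[["t1m"]]
  expect_equal(mm$sequence, isoscan:::revcomp(m$sequence))
  expect_equal(mm$junctions$offset, 350L - 160L)
  expect_equal(mm$junctions$key, sub(":\\+$", ":-", m$junctions$key))
})

test_that("junction tallies respect the two-sided (M, L) rule exactly", {
  set.seed(2)
  chrom <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  tx <- mk_tx("t1", list(c(100, 160), c(200, 290)))
  mature <- build_mature(list(tx), genome)
  j <- mature[["t1"]]$junctions$offset  # 160
  al <- function(starts, len = 50L)
    data.frame(read_id = paste0("r", seq_along(starts)), target_id = "t1",
               target_start = starts, aligned_length = len,
               mismatches = 0L, stringsAsFactors = FALSE)
  std <- validation_config("standard")
  # exactly 10 nt on each side counts; 9 on one side does not
  ev <- tally_junctions(al(c(j - 10L, j - 41L)), mature, std)
  expect_equal(ev$JC, 1L)   # second read leaves only 9 nt right of j
  ev2 <- tally_junctions(al(j - 40L), mature, std)
  expect_equal(ev2$JC, 1L)  # 40 left / 10 right: counts
  ev3 <- tally_junctions(al(j - 9L), mature, std)
  expect_equal(ev3$JC, 0L)  # 9 nt left: does not count
  expect_true(ev2$covered); expect_false(ev3$covered)

  # stringent: 5 reads with 8/8 overhang are not enough (M >= 6)
  strc <- validation_config("stringent")
  ev5 <- tally_junctions(al(rep(j - 8L, 5L), len = 16L), mature, strc)
  expect_equal(ev5$JC, 5L)
  expect_false(ev5$covered)
  ev6 <- tally_junctions(al(rep(j - 8L, 6L), len = 16L), mature, strc)
  expect_true(ev6$covered)
})

test_that("random tallies equal per-read brute force at several L", {
  for (seed in 1:6) {
    cfgf <- fixture_config(seed = seed, genome_length = 1400, n_genes = 2,
                           coverage = 4, background_coverage = 1)
    g <- make_genome(cfgf)
    rd <- make_reads(g$transcripts, g$genome, cfgf)
    for (L in c(8L, 10L, 15L)) {
      cfg <- if (L == 10L) validation_config("standard") else
        validation_config("stringent", L = L, M = 6L)
      ev <- tally_junctions(rd$alignments, rd$mature, cfg)
      # brute force: loop reads x junctions
      for (row in seq_len(nrow(ev))) {
        sub <- rd$alignments[rd$alignments$target_id == ev$target_id[row], ]
        jc <- 0L
        for (r in seq_len(nrow(sub))) {
          left <- ev$offset[row] - sub$target_start[r]
          right <- sub$target_start[r] + sub$aligned_length[r] -
            ev$offset[row]
          if (left >= L && right >= L) jc <- jc + 1L
        }
        expect_identical(ev$JC[row], jc)
      }
      # and the generator's own truth table agrees
      tr <- rd$truth(L)
      expect_equal(ev$JC, tr$JC)
    }
  }
})

make_validation_world <- function(seed, n_datasets = 3L, coverage = 8L) {
  cfgf <- fixture_config(seed = seed, genome_length = 1800, n_genes = 2,
                         coverage = coverage, background_coverage = 4)
  g <- make_genome(cfgf)
  mature <- build_mature(g$transcripts, g$genome)
  ds <- lapply(seq_len(n_datasets), function(d)
    make_reads(g$transcripts, g$genome,
               fixture_config(seed = seed * 100L + d,
                              genome_length = cfgf$genome_length,
                              coverage = coverage, background_coverage = 4)))
  list(genome = g, mature = mature, datasets = ds)
}

test_that("tier assignment matches its three defining predicates", {
  w <- make_validation_world(3)
  std <- validation_config("standard"); strc <- validation_config("stringent")
  ev_std <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, std))
  ev_str <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, strc))
  cov_std <- lapply(w$datasets, function(d)
    cds_coverage(d$alignments, d$mature))
  # treat gene 1 as known, everything as candidate -> gene 2 has NIJ
  known <- w$genome$transcripts[1]
  verd <- validate_transcripts(w$genome$transcripts, known,
                               ev_std, ev_str, cov_std, cov_std)
  expect_equal(nrow(verd), length(w$genome$transcripts))
  # known transcript can only be KNOWN_VALIDATED or UNVALIDATED
  expect_true(verd$tier[1] %in% c("KNOWN_VALIDATED", "UNVALIDATED"))

  # brute-force re-evaluation of the predicates per transcript
  kj <- isoscan:::known_junction_set(known)
  for (i in seq_along(w$genome$transcripts)) {
    tx <- w$genome$transcripts[[i]]
    keys <- isoscan:::tx_cds_junction_keys(tx)
    val_in <- function(evl, covl) vapply(seq_along(evl), function(d) {
      if (length(keys) == 0L)
        return(covl[[d]][[tx$transcript_id]] >= 0.9)
      sub <- evl[[d]]
      all(vapply(keys, function(k)
        any(sub$target_id == tx$transcript_id & sub$key == k & sub$covered),
        logical(1)))
    }, logical(1))
    v_std <- val_in(ev_std, cov_std)
    v_str <- val_in(ev_str, cov_std)
    nij <- length(keys) > 0L && any(!keys %in% kj)
    is_known <- i == 1L
    want <- if (is_known) {
      if (any(v_std)) "KNOWN_VALIDATED" else "UNVALIDATED"
    } else if (any(v_str) && nij) "VHC"
    else if (any(v_std) && nij) "VMC"
    else if (any(v_std)) "VLC"
    else "UNVALIDATED"
    expect_identical(verd$tier[i], want)
    expect_identical(verd$n_datasets_validated[i], sum(v_std))
    expect_identical(verd$tissue_specific[i],
                     sum(v_std) >= 1 && sum(v_std) < 5)
  }
})

test_that("novel multi-exon transcripts without novel junctions are VLC", {
  w <- make_validation_world(7)
  std <- validation_config("standard"); strc <- validation_config("stringent")
  ev_std <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, std))
  ev_str <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, strc))
  # knowledge contains every junction: candidates identical to known but
  # with new ids, so their CDS keys differ from nothing -- instead use a
  # structurally identical copy under a new id and a known list that
  # shares all junctions but not the CDS key (trimmed terminal exon)
  multi <- Filter(function(t) length(t$exon_starts) >= 2, w$genome$transcripts)
  tx <- multi[[1]]
  n <- length(tx$exon_starts)
  trimmed <- transcript("known_variant", tx$gene_id, tx$seqid, tx$strand,
                        tx$exon_starts, c(tx$exon_ends[-n],
                                          tx$exon_ends[n] - 3L),
                        cds_start = tx$cds_start,
                        cds_end = tx$cds_end - 3L, source_tag = "KNOWN")
  verd <- validate_transcripts(list(tx), list(trimmed), ev_std, ev_str)
  # all junctions of tx are in the known set -> no NIJ -> at best VLC
  expect_true(verd$tier %in% c("VLC", "UNVALIDATED"))
  expect_false(verd$has_nij)
  if (any(unlist(verd[grep("validated_std", names(verd))])))
    expect_identical(verd$tier, "VLC")
})

test_that("raising L or M never grows the validated set (monotonicity)", {
  for (seed in c(11, 12)) {
    w <- make_validation_world(seed, n_datasets = 2L, coverage = 6L)
    std <- validation_config("standard")
    strc <- validation_config("stringent")
    ev_std <- lapply(w$datasets, function(d)
      tally_junctions(d$alignments, d$mature, std))
    ev_str <- lapply(w$datasets, function(d)
      tally_junctions(d$alignments, d$mature, strc))
    for (d in seq_along(ev_std)) {
      # per-junction: stringent covered implies standard covered
      merged <- merge(ev_std[[d]], ev_str[[d]],
                      by = c("target_id", "offset", "key"))
      expect_true(all(!merged$covered.y | merged$covered.x))
    }
    verd <- validate_transcripts(w$genome$transcripts,
                                 w$genome$transcripts[1],
                                 ev_std, ev_str)
    v_std <- as.matrix(verd[grep("validated_std", names(verd))])
    v_str <- as.matrix(verd[grep("validated_str", names(verd))])
    expect_true(all(!v_str | v_std))   # stringent subset of standard
  }
})

test_that("verdicts depend only on own junctions and the known set", {
  w <- make_validation_world(13)
  std <- validation_config("standard"); strc <- validation_config("stringent")
  ev_std <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, std))
  ev_str <- lapply(w$datasets, function(d)
    tally_junctions(d$alignments, d$mature, strc))
  known <- w$genome$transcripts[1]
  tx <- w$genome$transcripts[2]
  alone <- validate_transcripts(tx, known, ev_std, ev_str)
  together <- validate_transcripts(w$genome$transcripts, known,
                                   ev_std, ev_str)
  i <- match(tx[[1]]$transcript_id, together$transcript_id)
  expect_identical(alone$tier, together$tier[i])
  expect_identical(alone$n_datasets_validated,
                   together$n_datasets_validated[i])
})

test_that("saturation curve handles degenerate and exhaustive cases", {
  same <- replicate(4, c("a", "b", "c"), simplify = FALSE)
  expect_equal(saturation_curve(same, 50, seed = 1), c(3, 0, 0, 0))
  disjoint <- list(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_equal(saturation_curve(disjoint, 50, seed = 1), c(2, 2, 2))

  # 4 datasets: Monte-Carlo mean matches the exhaustive 24-ordering mean
  set.seed(42)
  sets <- lapply(1:4, function(i)
    sample(letters, sample(5:12, 1)))
  got <- saturation_curve(sets, 400, seed = 7)
  perms <- all_perms(4)
  exact <- Reduce(`+`, lapply(perms, function(ord) {
    seen <- character(0); out <- numeric(4)
    for (k in 1:4) {
      new <- setdiff(sets[[ord[k]]], seen)
      out[k] <- length(new); seen <- c(seen, new)
    }
    out
  })) / length(perms)
  expect_equal(got, exact, tolerance = 0.15)
  expect_equal(sum(got), sum(exact), tolerance = 1e-9)  # totals are exact
  expect_error(saturation_curve(sets[1]), "at least 2")
})

test_that("PCR panel rates are computed per tier", {
  outcomes <- data.frame(
    transcript_id = paste0("t", 1:10),
    tier = rep(c("VMC", "VHC"), each = 5),
    validated = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, FALSE))
  s <- pcr_panel_summary(outcomes)
  expect_equal(s$rate_percent[s$tier == "VMC"], 60)
  expect_equal(s$rate_percent[s$tier == "VHC"], 80)
  none <- data.frame(transcript_id = "x", tier = "VMC", validated = FALSE)
  expect_equal(pcr_panel_summary(none)$rate_percent, 0)
  expect_error(pcr_panel_summary(outcomes[0, ]), "empty")
})
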