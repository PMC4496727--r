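# Maximum-likelihood training of the gene model from an annotated corpus,
# plus the versioned text serialization of a trained spec.

#' Bundle sequences and annotations into a training corpus
#'
#' @param sequences named character vector of genomic sequences.
#' @param transcripts list of coding [transcript()]s; every one must carry
#'   a complete ORF (checked).
#' @return object of class `"training_corpus"`.
#' @export
training_corpus <- function(sequences, transcripts) {
  if (length(transcripts) == 0L) stop("empty corpus", call. = FALSE)
  genome <- sequences
  bad <- vapply(transcripts, function(tx) !is_complete_orf(tx, genome),
                logical(1))
  if (any(bad))
    stop("training transcript(s) without a complete ORF: ",
         paste(vapply(transcripts[bad], `[[`, "", "transcript_id"),
               collapse = ", "), call. = FALSE)
  structure(list(sequences = sequences, transcripts = transcripts),
            class = "training_corpus")
}

#' Train the gene-structure GHMM
#'
#' Estimates content chains, signal PWMs, duration histograms and
#' transition probabilities by maximum likelihood with additive
#' pseudocounts.  Hard consensus columns (GT/AG, ATG, the stop triplet)
#' are imposed after counting so that illegal sites remain impossible.
#' Signal windows that would extend beyond the sequence bounds are
#' skipped; their number is recorded in the `n_skipped_signals` attribute.
#'
#' @param corpus a [training_corpus()].
#' @param order content-chain Markov order (default 2).
#' @param pseudocount additive smoothing mass (default 1).
#' @param max_intron,max_exon duration support caps; defaults cover the
#'   observed lengths with head-room.
#' @return a [ghmm_spec()].
#' @export
ghmm_train <- function(corpus, order = 2L, pseudocount = 1,
                       max_intron = NULL, max_exon = NULL) {
  stopifnot(inherits(corpus, "training_corpus"))
  nctx <- 4L^order
  cod_cnt <- lapply(1:3, function(i) matrix(0, nctx, 4))
  cod_marg_cnt <- lapply(1:3, function(i) rep(0, 4))
  nc_cnt <- matrix(0, nctx, 4)
  nc_marg_cnt <- rep(0, 4)
  sig_cnt <- list(start = matrix(0, 4, 6), donor_exonic = matrix(0, 4, 3),
                  donor_intronic = matrix(0, 4, 6),
                  acceptor_intronic = matrix(0, 4, 13),
                  acceptor_exonic = matrix(0, 4, 2))
  stop_cnt <- c(TAA = 0, TAG = 0, TGA = 0)
  dur_obs <- list(Einit = integer(0), Eint = integer(0), Eterm = integer(0),
                  Esingle = integer(0), I = integer(0))
  n_single <- 0L; n_multi <- 0L; n_introns <- 0L
  intergenic_bases <- 0
  n_skipped <- 0L

  tally_chain <- function(enc, ctx, pos, cnt, marg) {
    # pos: 1-based positions to count; returns updated list(cnt, marg)
    pos <- pos[!is.na(enc[pos])]
    full <- pos[!is.na(ctx[pos])]
    if (length(full)) {
      t <- table(factor(ctx[full], levels = seq_len(nctx)),
                 factor(enc[full], levels = 1:4))
      cnt <- cnt + unclass(t)
    }
    marg <- marg + tabulate(enc[pos], nbins = 4L)
    list(cnt, marg)
  }
  add_pwm <- function(nm, enc, i0) {
    w <- ncol(sig_cnt[[nm]])
    if (i0 < 0L || i0 + w > length(enc)) { n_skipped <<- n_skipped + 1L; return() }
    b <- enc[(i0 + 1L):(i0 + w)]
    for (c in seq_len(w)) if (!is.na(b[c]))
      sig_cnt[[nm]][b[c], c] <<- sig_cnt[[nm]][b[c], c] + 1
  }

  # group transcripts by (seqid, strand); minus-strand genes are counted on
  # the reverse complement with mirrored coordinates (forward-only model)
  for (key in unique(vapply(corpus$transcripts, function(tx)
      paste(tx$seqid, tx$strand), character(1)))) {
    txs <- Filter(function(tx) paste(tx$seqid, tx$strand) == key,
                  corpus$transcripts)
    seqid <- txs[[1]]$seqid; strand <- txs[[1]]$strand
    chrom <- corpus$sequences[[seqid]]
    if (is.null(chrom)) stop("sequence not in corpus: ", seqid, call. = FALSE)
    L <- nchar(chrom)
    if (strand == "-") {
      chrom <- revcomp(chrom)
      txs <- lapply(txs, function(tx) {
        transcript(tx$transcript_id, tx$gene_id, seqid, "+",
                   L - rev(tx$exon_ends), L - rev(tx$exon_starts),
                   cds_start = L - tx$cds_end, cds_end = L - tx$cds_start,
                   source_tag = tx$source_tag)
      })
    }
    enc <- seq_encode(chrom)
    ctx <- context_index(enc, order)
    genic <- rep(FALSE, L)
    for (tx in txs) {
      ce <- tx_cds_exons(tx)
      n <- nrow(ce)
      genic[seq2(min(ce) + 1L, max(ce))] <- TRUE
      if (n == 1L) n_single <- n_single + 1L else {
        n_multi <- n_multi + 1L
        n_introns <- n_introns + (n - 1L)
      }
      phase <- 0L
      for (e in seq_len(n)) {
        i <- ce[e, 1]; j <- ce[e, 2]; d <- j - i
        kind <- if (n == 1L) "Esingle"
          else if (e == 1L) "Einit"
          else if (e == n) "Eterm" else "Eint"
        dur_obs[[kind]] <- c(dur_obs[[kind]], d)
        cod_from <- i; cod_to <- j
        if (kind %in% c("Einit", "Esingle")) {
          add_pwm("start", enc, i); cod_from <- i + 6L
        } else {
          add_pwm("acceptor_exonic", enc, i); cod_from <- i + 2L
        }
        if (kind %in% c("Einit", "Eint")) {
          add_pwm("donor_exonic", enc, j - 3L); cod_to <- j - 3L
        } else {
          codon <- substr(chrom, j - 2L, j)
          if (codon %in% names(stop_cnt))
            stop_cnt[codon] <- stop_cnt[codon] + 1
          cod_to <- j - 3L
        }
        pos <- seq2(cod_from + 1L, cod_to)       # 1-based coding positions
        if (length(pos)) {
          cp <- (phase + (pos - 1L) - i) %% 3L   # codon position 0..2
          for (c in 1:3) {
            res <- tally_chain(enc, ctx, pos[cp == c - 1L],
                               cod_cnt[[c]], cod_marg_cnt[[c]])
            cod_cnt[[c]] <- res[[1]]; cod_marg_cnt[[c]] <- res[[2]]
          }
        }
        phase <- (phase + d) %% 3L
        if (e < n) {                              # the following intron
          a <- ce[e, 2]; b <- ce[e + 1L, 1]
          dur_obs$I <- c(dur_obs$I, b - a)
          add_pwm("donor_intronic", enc, a)
          add_pwm("acceptor_intronic", enc, b - 13L)
          pos <- seq2(a + 6L + 1L, b - 13L)
          res <- tally_chain(enc, ctx, pos, nc_cnt, nc_marg_cnt)
          nc_cnt <- res[[1]]; nc_marg_cnt <- res[[2]]
        }
      }
    }
    pos <- which(!genic)
    res <- tally_chain(enc, ctx, pos, nc_cnt, nc_marg_cnt)
    nc_cnt <- res[[1]]; nc_marg_cnt <- res[[2]]
    intergenic_bases <- intergenic_bases + sum(!genic)
  }

  norm_rows <- function(cnt) {
    m <- cnt + pseudocount
    m / rowSums(m)
  }
  norm_marg <- function(v) (v + pseudocount) / sum(v + pseudocount)
  hard <- list(start = list(cols = 1:3, base = c("A", "T", "G")),
               donor_intronic = list(cols = 1:2, base = c("G", "T")),
               acceptor_intronic = list(cols = 12:13, base = c("A", "G")))
  signals <- lapply(names(sig_cnt), function(nm) {
    m <- sig_cnt[[nm]] + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    if (nm %in% names(hard)) {
      h <- hard[[nm]]
      for (ci in seq_along(h$cols)) {
        m[, h$cols[ci]] <- 0
        m[match(h$base[ci], BASES), h$cols[ci]] <- 1
      }
    }
    rownames(m) <- BASES
    m
  })
  names(signals) <- names(sig_cnt)
  signals$stop <- (stop_cnt + pseudocount) / sum(stop_cnt + pseudocount)

  n_genes <- n_single + n_multi
  mins <- c(Einit = MIN_EINIT, Eint = MIN_EINT, Eterm = MIN_ETERM,
            Esingle = MIN_ESINGLE)
  if (is.null(max_exon))
    max_exon <- max(unlist(dur_obs[names(mins)]), 60L) + 60L
  if (is.null(max_intron)) max_intron <- max(dur_obs$I, 40L) + 60L
  durations <- c(
    lapply(names(mins), function(nm)
      dur_histogram(dur_obs[[nm]], mins[[nm]], max_exon, pseudocount)),
    list(dur_histogram(dur_obs$I, 20L, max_intron, pseudocount)))
  names(durations) <- c(names(mins), "I")

  spec <- ghmm_spec(
    order = order,
    coding = lapply(cod_cnt, norm_rows),
    noncoding = norm_rows(nc_cnt),
    coding_marg = lapply(cod_marg_cnt, norm_marg),
    noncoding_marg = norm_marg(nc_marg_cnt),
    signals = signals,
    durations = durations,
    transitions = list(
      p_stay = intergenic_bases / (intergenic_bases + n_genes),
      p_single = (n_single + pseudocount) / (n_genes + 2 * pseudocount),
      p_term = (n_multi + pseudocount) / (n_introns + 2 * pseudocount)),
    min_intron = 20L)
  attr(spec, "n_skipped_signals") <- n_skipped
  if (n_skipped > 0L)
    message("ghmm_train: skipped ", n_skipped,
            " signal window(s) extending beyond sequence bounds")
  spec
}

# ---- serialization ----------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a GHMM spec to a versioned text artifact
#'
#' Key-value sections with deterministic field order, so that two specs
#' can be diffed line by line.
#'
#' @param spec a [ghmm_spec()].
#' @param path output path.
#' @export
write_ghmm <- function(spec, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# ", spec$version)
  w("order\t", spec$order)
  w("min_intron\t", spec$min_intron)
  tr <- spec$transitions
  w("transitions\t", fmt_num(tr$p_stay), "\t", fmt_num(tr$p_single), "\t",
    fmt_num(tr$p_term))
  wm <- function(tag, m) for (r in seq_len(nrow(m)))
    w(tag, "\t", r, "\t", paste(fmt_num(m[r, ]), collapse = "\t"))
  w("noncoding_marg\t", paste(fmt_num(spec$noncoding_marg), collapse = "\t"))
  for (c in 1:3)
    w("coding_marg\t", c, "\t",
      paste(fmt_num(spec$coding_marg[[c]]), collapse = "\t"))
  wm("noncoding", spec$noncoding)
  for (c in 1:3) wm(paste0("coding", c), spec$coding[[c]])
  for (nm in c("start", "donor_exonic", "donor_intronic",
               "acceptor_intronic", "acceptor_exonic"))
    wm(paste0("pwm.", nm), spec$signals[[nm]])
  w("stop\t", paste(fmt_num(spec$signals$stop), collapse = "\t"))
  for (nm in c("Einit", "Eint", "Eterm", "Esingle", "I")) {
    d <- spec$durations[[nm]]
    w("duration.", nm, "\t", d$min, "\t", d$cap, "\t",
      paste(fmt_num(d$logp), collapse = "\t"))
  }
  invisible(path)
}

#' Read a GHMM spec written by [write_ghmm()]
#'
#' @param path file path.
#' @return a [ghmm_spec()].
#' @export
read_ghmm <- function(path) {
  lines <- readLines(path)
  if (!grepl("isoscan-ghmm/1", lines[1]))
    stop("not an isoscan GHMM artifact: ", path, call. = FALSE)
  f <- strsplit(lines[-1], "\t", fixed = TRUE)
  tag <- vapply(f, `[`, character(1), 1L)
  get1 <- function(t) f[[which(tag == t)]][-1]
  getm <- function(t, ncol) {
    rows <- f[tag == t]
    m <- do.call(rbind, lapply(rows, function(x)
      as.numeric(x[-(1:2)])))[order(as.integer(vapply(rows, `[`, "", 2L))), ,
                              drop = FALSE]
    m
  }
  order_k <- as.integer(get1("order"))
  tr <- as.numeric(get1("transitions"))
  signals <- lapply(c("start", "donor_exonic", "donor_intronic",
                      "acceptor_intronic", "acceptor_exonic"), function(nm) {
    m <- getm(paste0("pwm.", nm))
    rownames(m) <- BASES
    m
  })
  names(signals) <- c("start", "donor_exonic", "donor_intronic",
                      "acceptor_intronic", "acceptor_exonic")
  stopv <- as.numeric(get1("stop"))
  names(stopv) <- STOP_CODONS
  signals$stop <- stopv
  cm_rows <- f[tag == "coding_marg"]
  coding_marg <- lapply(order(vapply(cm_rows, `[`, "", 2L)), function(i)
    as.numeric(cm_rows[[i]][-(1:2)]))
  durations <- lapply(c("Einit", "Eint", "Eterm", "Esingle", "I"),
                      function(nm) {
    x <- get1(paste0("duration.", nm))
    list(min = as.integer(x[1]), cap = as.integer(x[2]),
         logp = as.numeric(x[-(1:2)]))
  })
  names(durations) <- c("Einit", "Eint", "Eterm", "Esingle", "I")
  ghmm_spec(order = order_k,
            coding = lapply(1:3, function(c) getm(paste0("coding", c))),
            noncoding = getm("noncoding"),
            coding_marg = coding_marg,
            noncoding_marg = as.numeric(get1("noncoding_marg")),
            signals = signals, durations = durations,
            transitions = list(p_stay = tr[1], p_single = tr[2],
                               p_term = tr[3]),
            min_intron = as.integer(get1("min_intron")))
}
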