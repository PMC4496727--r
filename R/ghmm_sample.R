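# Generative counterpart of the gene model: samples a sequence plus the
# true gene structures (and the underlying state path), enabling
# closed-loop tests of the decoder and the downstream pipeline.

#' Sample a sequence and its true gene structures from the model
#'
#' Walks the state topology left to right, sampling durations from the
#' duration models and bases from the signal PWMs / content chains.  Exon
#' emissions are rejection-sampled so the coding frame contains no
#' internal stop codon (the decoder assigns such paths probability zero),
#' and whole genes are resampled if a stop codon arises split across a
#' junction.  Deterministic under a fixed seed.
#'
#' @param spec a [ghmm_spec()].
#' @param target_length minimum sequence length (nt); the sequence ends at
#'   the end of the intergenic run that first reaches it.
#' @param seed integer seed.
#' @param gene_prefix prefix for generated gene/transcript ids.
#' @return list with elements `sequence` (character), `transcripts` (list
#'   of [transcript()], forward strand, CDS = exon span) and `path`
#'   (data.frame state/start/end of the true segmentation).
#' @export
ghmm_sample <- function(spec, target_length, seed = 1L,
                        gene_prefix = "g") {
  stopifnot(target_length >= 50L)
  rng <- local({ set.seed(seed); NULL })
  tr <- spec$transitions
  sg <- spec$signals
  k <- spec$order

  sample_base_chain <- function(probs, marg, ctx_bases) {
    if (length(ctx_bases) < k || anyNA(ctx_bases)) {
      sample.int(4L, 1L, prob = marg)
    } else {
      idx <- 1L
      for (j in seq_len(k))
        idx <- idx + (ctx_bases[length(ctx_bases) - j + 1L] - 1L) * 4L^(j - 1L)
      sample.int(4L, 1L, prob = probs[idx, ])
    }
  }
  sample_pwm <- function(pwm) {
    vapply(seq_len(ncol(pwm)), function(c)
      sample.int(4L, 1L, prob = pwm[, c]), integer(1))
  }
  sample_stop <- function() {
    codon <- sample(STOP_CODONS, 1L, prob = sg$stop)
    match(strsplit(codon, "")[[1]], BASES)
  }

  # sample one exon's bases given context; returns NULL if the in-frame
  # stop constraint could not be met (caller retries the gene)
  sample_exon <- function(kind, d, c0, ctx) {
    for (try in 1:200) {
      out <- integer(0)
      cc <- ctx
      emit_chain_cod <- function(n, at0) {
        for (u in seq_len(n)) {
          cp <- (c0 + at0 + u - 1L) %% 3L
          b <- sample_base_chain(spec$coding[[cp + 1L]],
                                 spec$coding_marg[[cp + 1L]], cc)
          out <<- c(out, b); cc <<- c(cc, b)
        }
      }
      if (kind %in% c("Einit", "Esingle")) {
        b <- sample_pwm(sg$start); out <- c(out, b); cc <- c(cc, b)
        lead <- 6L
      } else {
        b <- sample_pwm(sg$acceptor_exonic); out <- c(out, b); cc <- c(cc, b)
        lead <- 2L
      }
      emit_chain_cod(d - lead - 3L, lead)
      if (kind %in% c("Einit", "Eint")) {
        b <- sample_pwm(sg$donor_exonic); out <- c(out, b)
      } else {
        out <- c(out, sample_stop())
      }
      # reject on internal in-frame stop (terminal stop excluded)
      lim <- if (kind %in% c("Eterm", "Esingle")) d - 3L else d
      ok <- TRUE
      u <- seq2(0L, lim - 3L)
      u <- u[(c0 + u) %% 3L == 0L]
      for (p in u) {
        codon <- paste(BASES[out[(p + 1L):(p + 3L)]], collapse = "")
        if (codon %in% STOP_CODONS) { ok <- FALSE; break }
      }
      if (ok) return(out)
    }
    NULL
  }

  sample_dur_cong <- function(dur, c0) {
    # duration congruent to -c0 mod 3 (complete codon count), for
    # Eterm/Esingle; rejection with bounded tries then deterministic scan
    for (try in 1:100) {
      d <- sample_duration(dur)
      if ((c0 + d) %% 3L == 0L) return(d)
    }
    supp <- dur$min:dur$cap
    supp <- supp[(c0 + supp) %% 3L == 0L]
    supp[sample.int(length(supp), 1L)]
  }

  sample_gene <- function(ctx) {
    # returns list(bases, exons (rel. coords), path rows) or NULL
    single <- stats::runif(1) < tr$p_single
    kinds <- if (single) "Esingle" else {
      n_int <- stats::rgeom(1, tr$p_term)
      c("Einit", rep("Eint", n_int), "Eterm")
    }
    for (gene_try in 1:50) {
      bases <- integer(0); cc <- ctx
      exon_rel <- NULL; path_rows <- NULL
      pos <- 0L; c0 <- 0L; ok <- TRUE
      for (e in seq_along(kinds)) {
        kind <- kinds[e]
        d <- if (kind %in% c("Eterm", "Esingle"))
          sample_dur_cong(spec$durations[[kind]],
                          if (kind == "Esingle") 0L else c0)
        else sample_duration(spec$durations[[kind]])
        eb <- sample_exon(kind, d, if (kind %in% c("Einit", "Esingle")) 0L
                          else c0, cc)
        if (is.null(eb)) { ok <- FALSE; break }
        bases <- c(bases, eb); cc <- c(cc, eb)
        exon_rel <- rbind(exon_rel, c(pos, pos + d))
        path_rows <- rbind(path_rows,
                           data.frame(state = kind, start = pos,
                                      end = pos + d))
        c0 <- (c0 + d) %% 3L
        pos <- pos + d
        if (e < length(kinds)) {
          di <- sample_duration(spec$durations$I)
          ib <- c(sample_pwm(sg$donor_intronic),
                  integer(0), # chain below
                  integer(0))
          cc2 <- c(cc, ib)
          chain_n <- di - 6L - 13L
          for (u in seq_len(chain_n)) {
            b <- sample_base_chain(spec$noncoding, spec$noncoding_marg, cc2)
            ib <- c(ib, b); cc2 <- c(cc2, b)
          }
          ib <- c(ib, sample_pwm(sg$acceptor_intronic))
          bases <- c(bases, ib); cc <- c(cc, ib)
          path_rows <- rbind(path_rows,
                             data.frame(state = "I", start = pos,
                                        end = pos + di))
          pos <- pos + di
        }
      }
      if (!ok) next
      # reject genes whose spliced CDS contains a split-codon stop
      cds <- unlist(lapply(seq_len(nrow(exon_rel)), function(e)
        bases[(exon_rel[e, 1] + 1L):(exon_rel[e, 2])]))
      ncod <- length(cds) %/% 3L
      codons <- vapply(seq_len(ncod), function(ci)
        paste(BASES[cds[(3L * ci - 2L):(3L * ci)]], collapse = ""), "")
      if (!any(codons[-ncod] %in% STOP_CODONS))
        return(list(bases = bases, exons = exon_rel, path = path_rows))
    }
    NULL
  }

  chunks <- list()
  total <- 0L
  ctx <- integer(0)    # last k emitted bases, the only context needed
  push <- function(v) {
    chunks[[length(chunks) + 1L]] <<- v
    total <<- total + length(v)
    ctx <<- utils::tail(c(ctx, v), k)
  }
  emit_noncoding <- function(g) {
    v <- integer(g)
    cc <- ctx
    for (u in seq_len(g)) {
      b <- sample_base_chain(spec$noncoding, spec$noncoding_marg, cc)
      v[u] <- b
      cc <- utils::tail(c(cc, b), k)
    }
    push(v)
  }
  path <- NULL
  transcripts <- list()
  gi <- 0L
  repeat {
    # intergenic run: geometric (>=1) stay/leave walk
    g <- 1L + stats::rgeom(1, 1 - tr$p_stay)
    run_start <- total
    if (total + g >= target_length) {
      emit_noncoding(max(1L, target_length - total))  # path must end in N
      path <- rbind(path, data.frame(state = "N", start = run_start,
                                     end = total))
      break
    }
    emit_noncoding(g)
    path <- rbind(path, data.frame(state = "N", start = run_start,
                                   end = total))
    gene <- sample_gene(ctx)
    if (is.null(gene)) next    # extremely unlikely; just extend intergenic
    gi <- gi + 1L
    off <- total
    gene$path$start <- gene$path$start + off
    gene$path$end <- gene$path$end + off
    path <- rbind(path, gene$path)
    push(gene$bases)
    transcripts[[gi]] <- transcript(
      transcript_id = paste0(gene_prefix, gi, ".t1"),
      gene_id = paste0(gene_prefix, gi),
      seqid = "seq", strand = "+",
      exon_starts = gene$exons[, 1] + off,
      exon_ends = gene$exons[, 2] + off,
      cds_start = gene$exons[1, 1] + off,
      cds_end = gene$exons[nrow(gene$exons), 2] + off,
      source_tag = "KNOWN")
  }
  list(sequence = paste(BASES[unlist(chunks)], collapse = ""),
       transcripts = transcripts, path = path)
}
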