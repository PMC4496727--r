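# k-best (list) Viterbi decoding of the gene-structure GHMM.
#
# The dynamic program keeps, for every (position, state[, phase]) cell, a
# list of the top-N highest-scoring distinct partial state paths, merged
# by score with a deterministic tie-break.  Intergenic N advances per
# base; exons and introns enter as explicit-duration arcs whose emission
# terms are O(1) after cumulative-sum precomputation, so a full decode is
# O(L * (max segment length) * N).
#
# Cells: 1 N (per-base), 2 Esingle, 3 Eterm, 4-6 Einit (out-phase 0-2),
# 7-9 Eint (out-phase 0-2), 10-12 intron (phase 0-2).  "Phase" is the
# codon position at which coding resumes after the segment.

CELL_STATE <- c("N", "Esingle", "Eterm", "Einit", "Einit", "Einit",
                "Eint", "Eint", "Eint", "I", "I", "I")

#' Decoder configuration
#'
#' @param top_n number of highest-scoring state paths to return per
#'   region (default 250).
#' @param padding nt added on each side of a candidate region before
#'   decoding (default 5000).
#' @param min_intron minimum intron length retained by [postfilter()]
#'   (default 20 nt).
#' @return object of class `"decoder_config"`.
#' @export
decoder_config <- function(top_n = 250L, padding = 5000L, min_intron = 20L) {
  stopifnot(top_n >= 1L, padding >= 0L)
  structure(list(top_n = as.integer(top_n), padding = as.integer(padding),
                 min_intron = as.integer(min_intron)),
            class = "decoder_config")
}

# emission/signal precomputation shared by all arcs of one decode
decode_tables <- function(spec, enc) {
  L <- length(enc)
  ctx <- context_index(enc, spec$order)
  logN <- chain_logp_positions(enc, ctx, spec$noncoding, spec$noncoding_marg)
  logC <- vapply(1:3, function(c)
    chain_logp_positions(enc, ctx, spec$coding[[c]], spec$coding_marg[[c]]),
    numeric(L))
  cumN <- c(0, cumsum(logN))
  cumC <- matrix(0, 3, L + 1L)
  cumS <- matrix(0L, 3, L + 1L)
  stopv <- vapply(seq_len(L), function(u) is_stop_at(enc, u - 1L), logical(1))
  u <- seq_len(L) - 1L
  for (r in 0:2) {
    cp <- (u + r) %% 3L
    cumC[r + 1L, ] <- c(0, cumsum(logC[cbind(seq_len(L), cp + 1L)]))
    cumS[r + 1L, ] <- c(0L, cumsum(as.integer(stopv & cp == 0L)))
  }
  pwm_vec <- function(pwm) {
    # value at 1-based index s+1 = PWM score of window starting at s
    w <- ncol(pwm)
    out <- rep(-Inf, L + 1L)
    if (L >= w) {
      s <- 0:(L - w)
      acc <- numeric(length(s))
      for (c in seq_len(w)) {
        b <- enc[s + c]
        v <- ifelse(is.na(b), log(0.25),
                    log(pwm[cbind(ifelse(is.na(b), 1L, b), c)]))
        acc <- acc + v
      }
      out[s + 1L] <- acc
    }
    out
  }
  sg <- spec$signals
  stopS <- rep(-Inf, L + 1L)              # index j+1, codon [j-3, j)
  if (L >= 3L) {
    jj <- 3:L
    stopS[jj + 1L] <- vapply(jj, function(j)
      stop_logp(sg$stop, enc, j - 3L), numeric(1))
  }
  list(L = L, logN = logN, cumN = cumN, cumC = cumC, cumS = cumS,
       startS = pwm_vec(sg$start),        # index i+1, window [i, i+6)
       dEx = pwm_vec(sg$donor_exonic),    # index s+1, window [s, s+3)
       dIn = pwm_vec(sg$donor_intronic),  # index s+1, window [s, s+6)
       aIn = pwm_vec(sg$acceptor_intronic),  # [s, s+13)
       aEx = pwm_vec(sg$acceptor_exonic),    # [s, s+2)
       stopS = stopS)
}

#' Decode the top-N gene-structure paths of a sequence
#'
#' Extended Viterbi: the top N partial values are kept in each dynamic
#' programming cell, so the N highest-scoring complete state paths are
#' recovered rather than only the optimum.  Entry 1 equals the standard
#' Viterbi path; scores are non-increasing with rank; ties are broken
#' deterministically (predecessor cell, then segment start, then
#' predecessor rank).  Paths start and end in the intergenic state, so a
#' sequence shorter than 2 nt plus the minimum gene span can only carry
#' all-intergenic paths.
#'
#' @param spec a [ghmm_spec()].
#' @param sequence character scalar (forward strand; decode the reverse
#'   complement for the minus strand).
#' @param config a [decoder_config()].
#' @param seqid sequence id stamped on result transcripts.
#' @return list of scored paths, each
#'   `list(rank, log_score, path, transcripts, is_suboptimal)` where
#'   `path` is a state/start/end data.frame and `transcripts` the gene
#'   structures on the path (possibly none); empty list if no legal path
#'   exists.
#' @export
kbest_decode <- function(spec, sequence, config = decoder_config(),
                         seqid = "seq") {
  K <- config$top_n
  enc <- seq_encode(sequence)
  L <- length(enc)
  if (L < 2L) return(list())
  tb <- decode_tables(spec, enc)
  tr <- spec$transitions
  log_stay <- log(tr$p_stay)
  log_init <- log(1 - tr$p_stay) + log(1 - tr$p_single)
  log_single <- log(1 - tr$p_stay) + log(tr$p_single)
  dur <- spec$durations

  cells <- lapply(1:12, function(i)
    list(score = matrix(-Inf, L + 1L, K),
         bp_cell = matrix(0L, L + 1L, K),
         bp_pos = matrix(0L, L + 1L, K),
         bp_rank = matrix(0L, L + 1L, K)))

  put <- function(cell, j, cand) {
    if (is.null(cand)) return()
    sc <- cand$score
    keep <- is.finite(sc)
    if (!any(keep)) return()
    sc <- sc[keep]
    bc <- cand$bp_cell[keep]; bp <- cand$bp_pos[keep]; br <- cand$bp_rank[keep]
    o <- order(-sc, bc, bp, br)
    o <- o[seq_len(min(K, length(o)))]
    n <- length(o)
    cells[[cell]]$score[j + 1L, seq_len(n)] <<- sc[o]
    cells[[cell]]$bp_cell[j + 1L, seq_len(n)] <<- bc[o]
    cells[[cell]]$bp_pos[j + 1L, seq_len(n)] <<- bp[o]
    cells[[cell]]$bp_rank[j + 1L, seq_len(n)] <<- br[o]
  }
  arc_cand <- function(src, i_vec, arc) {
    # arc sources: cell `src` at 0-based starts `i_vec`, per-start scores
    ok <- is.finite(arc)
    i_vec <- i_vec[ok]; arc <- arc[ok]
    if (!length(i_vec)) return(NULL)
    S <- cells[[src]]$score[i_vec + 1L, , drop = FALSE] + arc
    list(score = as.vector(S),
         bp_cell = rep.int(src, length(S)),
         bp_pos = rep.int(i_vec, K),
         bp_rank = rep(seq_len(K), each = length(i_vec)))
  }
  cat_cand <- function(cands) {
    cands <- Filter(Negate(is.null), cands)
    if (!length(cands)) return(NULL)
    list(score = unlist(lapply(cands, `[[`, "score"), use.names = FALSE),
         bp_cell = unlist(lapply(cands, `[[`, "bp_cell"), use.names = FALSE),
         bp_pos = unlist(lapply(cands, `[[`, "bp_pos"), use.names = FALSE),
         bp_rank = unlist(lapply(cands, `[[`, "bp_rank"), use.names = FALSE))
  }
  nstops <- function(r_vec, a_vec, b_vec) {
    # stop codons fully inside [a, b) at frame class r (vectorized)
    ifelse(b_vec - a_vec >= 3L,
           tb$cumS[cbind(r_vec + 1L, pmax(b_vec - 1L, 1L))] -
             tb$cumS[cbind(r_vec + 1L, a_vec + 1L)],
           0L)
  }
  cspan <- function(r_vec, from_vec, to_vec) {
    tb$cumC[cbind(r_vec + 1L, to_vec + 1L)] -
      tb$cumC[cbind(r_vec + 1L, from_vec + 1L)]
  }

  # seed: first base is intergenic
  put(1L, 1L, list(score = tb$logN[1L], bp_cell = 0L, bp_pos = 0L,
                   bp_rank = 0L))

  for (j in 2:L) {
    # --- N, per base ---
    prev <- function(cell, add)
      list(score = cells[[cell]]$score[j, ] + add,
           bp_cell = rep.int(cell, K), bp_pos = rep.int(j - 1L, K),
           bp_rank = seq_len(K))
    put(1L, j, cat_cand(list(prev(1L, log_stay + tb$logN[j]),
                             prev(2L, tb$logN[j]),
                             prev(3L, tb$logN[j]))))
    # --- Esingle <- N ---
    i_vec <- seq2(max(1L, j - dur$Esingle$cap), j - dur$Esingle$min)
    i_vec <- i_vec[(j - i_vec) %% 3L == 0L]
    if (length(i_vec) && is.finite(tb$stopS[j + 1L])) {
      d <- j - i_vec; r <- (-i_vec) %% 3L
      arc <- log_single + dur_logp(dur$Esingle, d) + tb$startS[i_vec + 1L] +
        cspan(r, i_vec + 6L, j - 3L) + tb$stopS[j + 1L]
      arc[nstops(r, i_vec, j - 3L) > 0L] <- -Inf
      put(2L, j, arc_cand(1L, i_vec, arc))
    }
    # --- Einit_p <- N ---
    donor_j <- if (j + 6L <= L) tb$dEx[j - 3L + 1L] else -Inf
    i_vec <- seq2(max(1L, j - dur$Einit$cap), j - dur$Einit$min)
    if (length(i_vec) && is.finite(donor_j)) {
      d <- j - i_vec; r <- (-i_vec) %% 3L
      arc <- log_init + dur_logp(dur$Einit, d) + tb$startS[i_vec + 1L] +
        cspan(r, i_vec + 6L, j - 3L) + donor_j
      arc[nstops(r, i_vec, j) > 0L] <- -Inf
      for (p in 0:2) {
        sel <- d %% 3L == p
        if (any(sel)) put(4L + p, j, arc_cand(1L, i_vec[sel], arc[sel]))
      }
    }
    # --- I_q <- Einit_q | Eint_q ---
    acc_j <- tb$aIn[j - 13L + 1L]
    i_vec <- seq2(max(1L, j - dur$I$cap), j - max(dur$I$min, spec$min_intron))
    if (length(i_vec) && is.finite(acc_j)) {
      d <- j - i_vec
      arc <- dur_logp(dur$I, d) + tb$dIn[i_vec + 1L] +
        (tb$cumN[j - 13L + 1L] - tb$cumN[i_vec + 6L + 1L]) + acc_j
      for (q in 0:2)
        put(10L + q, j, cat_cand(list(arc_cand(4L + q, i_vec, arc),
                                      arc_cand(7L + q, i_vec, arc))))
    }
    # --- Eint_p <- I_q ---
    i_vec <- seq2(max(1L, j - dur$Eint$cap), j - dur$Eint$min)
    if (length(i_vec) && is.finite(donor_j)) {
      d <- j - i_vec
      base_arc <- log(1 - tr$p_term) + dur_logp(dur$Eint, d) +
        tb$aEx[i_vec + 1L] + donor_j
      acc <- vector("list", 3L)  # per target phase p
      for (q in 0:2) {
        r <- (q - i_vec) %% 3L
        arc <- base_arc + cspan(r, i_vec + 2L, j - 3L)
        arc[nstops(r, i_vec, j) > 0L] <- -Inf
        p_out <- (q + d) %% 3L
        for (p in 0:2) {
          sel <- p_out == p
          if (any(sel))
            acc[[p + 1L]] <- c(acc[[p + 1L]],
                               list(arc_cand(10L + q, i_vec[sel], arc[sel])))
        }
      }
      for (p in 0:2) put(7L + p, j, cat_cand(acc[[p + 1L]]))
    }
    # --- Eterm <- I_q ---
    i_vec <- seq2(max(1L, j - dur$Eterm$cap), j - dur$Eterm$min)
    if (length(i_vec) && is.finite(tb$stopS[j + 1L])) {
      d <- j - i_vec
      base_arc <- log(tr$p_term) + dur_logp(dur$Eterm, d) +
        tb$aEx[i_vec + 1L] + tb$stopS[j + 1L]
      acc <- list()
      for (q in 0:2) {
        sel <- (q + d) %% 3L == 0L
        if (!any(sel)) next
        iq <- i_vec[sel]
        r <- (q - iq) %% 3L
        arc <- base_arc[sel] + cspan(r, iq + 2L, j - 3L)
        arc[nstops(r, iq, j - 3L) > 0L] <- -Inf
        acc <- c(acc, list(arc_cand(10L + q, iq, arc)))
      }
      put(3L, j, cat_cand(acc))
    }
  }

  # read off the top-K complete paths (ending in N at position L)
  fin <- cells[[1L]]
  out <- list()
  for (k in seq_len(K)) {
    sc <- fin$score[L + 1L, k]
    if (!is.finite(sc)) break
    segs <- backtrack(cells, 1L, L, k)
    txs <- path_transcripts(segs, seqid, paste0("p", k))
    out[[k]] <- structure(list(rank = k, log_score = sc, path = segs,
                               transcripts = txs,
                               is_suboptimal = k > 1L),
                          class = "scored_path")
  }
  out
}

backtrack <- function(cells, cell, pos, rank) {
  states <- character(0); starts <- integer(0); ends <- integer(0)
  repeat {
    ce <- cells[[cell]]
    bc <- ce$bp_cell[pos + 1L, rank]
    bp <- ce$bp_pos[pos + 1L, rank]
    br <- ce$bp_rank[pos + 1L, rank]
    states <- c(CELL_STATE[cell], states)
    starts <- c(bp, starts); ends <- c(pos, ends)
    if (bc == 0L) break
    cell <- bc; pos <- bp; rank <- br
  }
  df <- data.frame(state = states, start = starts, end = ends,
                   stringsAsFactors = FALSE)
  # merge per-base N rows into runs
  runs <- cumsum(c(TRUE, df$state[-1L] != "N" | df$state[-nrow(df)] != "N"))
  data.frame(state = tapply(df$state, runs, `[`, 1L),
             start = as.integer(tapply(df$start, runs, min)),
             end = as.integer(tapply(df$end, runs, max)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# gene structures on a decoded path -> transcript objects (CDS = exon span)
path_transcripts <- function(path, seqid, id_prefix) {
  ex <- path$state %in% c("Einit", "Eint", "Eterm", "Esingle")
  if (!any(ex)) return(list())
  gene_break <- cumsum(path$state == "N")[ex]
  idx <- which(ex)
  txs <- list()
  for (g in unique(gene_break)) {
    rows <- idx[gene_break == g]
    gid <- paste0(id_prefix, ".g", length(txs) + 1L)
    txs[[length(txs) + 1L]] <- transcript(
      transcript_id = paste0(gid, ".t1"), gene_id = gid,
      seqid = seqid, strand = "+",
      exon_starts = path$start[rows], exon_ends = path$end[rows],
      cds_start = path$start[rows[1L]], cds_end = path$end[rows[length(rows)]],
      source_tag = "PREDICTED")
  }
  txs
}
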