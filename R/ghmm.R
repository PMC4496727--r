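# Generalized (explicit-duration) HMM of protein-coding gene structure.
#
# State topology (forward strand; reverse strand is decoded on the
# reverse complement):
#
#   N --> Esingle --> N
#   N --> Einit --> I --> (Eint --> I)* --> Eterm --> N
#
# Intergenic N emits per base with a geometric stay/leave decision; exons
# and introns are explicit-duration segments.  Splice/translation signals
# are position weight matrices owned entirely by the segment containing
# their bases, split at the exon|intron boundary (PWMs factorise per
# column, so the donor site contributes its 3 exonic columns to the exon
# segment and its 6 intronic columns to the intron segment):
#
#   exon  [... coding ...|donor 3nt]  intron [donor 6nt|chain|acceptor 13nt]
#   exon  [acceptor 2nt|coding ...]
#   start-of-CDS signal: 6 columns (ATG + 3), inside the first exon
#   stop: categorical over TAA/TAG/TGA, the last 3 exon bases
#
# Hard consensus bases (GT..AG, ATG, the stop triplet) have probability 1
# in their columns, so illegal splice sites score -Inf rather than merely
# low.  Coding emissions are a 3-periodic k-order Markov chain over the
# *genomic* context; noncoding (intergenic + intron interiors) a
# homogeneous k-order chain.

BASES <- c("A", "C", "G", "T")

# minimum segment lengths implied by the signal carve-outs
MIN_EINIT   <- 9L   # start signal 6 + donor-exonic 3
MIN_EINT    <- 5L   # acceptor-exonic 2 + donor-exonic 3
MIN_ETERM   <- 5L   # acceptor-exonic 2 + stop 3
MIN_ESINGLE <- 9L   # start signal 6 + stop 3
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a gene-structure GHMM specification
#'
#' Normally produced by [ghmm_train()] or [ghmm_default_spec()]; exposed
#' so alternative parameterisations can be assembled by hand.
#'
#' @param order Markov order of the content chains.
#' @param coding list of three `4^order x 4` probability matrices (one per
#'   codon position) plus attribute handling is done internally.
#' @param noncoding a `4^order x 4` probability matrix.
#' @param coding_marg list of three length-4 marginal base distributions
#'   (one per codon position) used where the full context is unavailable
#'   (sequence start, ambiguity); `noncoding_marg` is a single length-4
#'   marginal for the noncoding chain.
#' @param noncoding_marg length-4 marginal base distribution.
#' @param signals list with PWMs `start` (4x6), `donor_exonic` (4x3),
#'   `donor_intronic` (4x6), `acceptor_intronic` (4x13),
#'   `acceptor_exonic` (4x2) and `stop` (length-3 over TAA/TAG/TGA).
#' @param durations list of duration models for `Einit`, `Eint`, `Eterm`,
#'   `Esingle`, `I`, each `list(min, cap, logp)` with `logp` over
#'   `min:cap`.
#' @param transitions list with `p_stay` (intergenic per-base stay
#'   probability), `p_single` (single-exon gene probability at gene
#'   start) and `p_term` (terminal-exon probability at intron end).
#' @param min_intron hard minimum intron length (nt).
#' @return object of class `"ghmm_spec"`.
#' @export
ghmm_spec <- function(order, coding, noncoding, coding_marg, noncoding_marg,
                      signals, durations, transitions, min_intron = 20L) {
  spec <- structure(list(version = "isoscan-ghmm/1", order = as.integer(order),
                         coding = coding, noncoding = noncoding,
                         coding_marg = coding_marg,
                         noncoding_marg = noncoding_marg,
                         signals = signals, durations = durations,
                         transitions = transitions,
                         min_intron = as.integer(min_intron)),
                    class = "ghmm_spec")
  validate_ghmm_spec(spec)
  spec
}

validate_ghmm_spec <- function(spec) {
  tol <- 1e-9
  chk_rows <- function(m, what) {
    if (any(abs(rowSums(m) - 1) > tol))
      stop("probability rows of ", what, " do not sum to 1", call. = FALSE)
  }
  chk_rows(spec$noncoding, "noncoding chain")
  for (c in 1:3) chk_rows(spec$coding[[c]], paste0("coding chain pos ", c))
  for (nm in c("start", "donor_exonic", "donor_intronic",
               "acceptor_intronic", "acceptor_exonic")) {
    if (any(abs(colSums(spec$signals[[nm]]) - 1) > tol))
      stop("PWM columns of ", nm, " do not sum to 1", call. = FALSE)
  }
  if (abs(sum(spec$signals$stop) - 1) > tol)
    stop("stop codon probabilities do not sum to 1", call. = FALSE)
  for (nm in names(spec$durations)) {
    d <- spec$durations[[nm]]
    if (abs(sum(exp(d$logp)) - 1) > 1e-6)
      stop("duration distribution for ", nm, " not normalized", call. = FALSE)
    if (length(d$logp) != d$cap - d$min + 1L)
      stop("duration support length mismatch for ", nm, call. = FALSE)
  }
  if (spec$durations$I$min < 20L || spec$min_intron < 20L)
    stop("minimum intron length must be >= 20 nt", call. = FALSE)
  tr <- spec$transitions
  if (any(c(tr$p_stay, tr$p_single, tr$p_term) <= 0) ||
      any(c(tr$p_stay, tr$p_single, tr$p_term) >= 1))
    stop("transition probabilities must lie strictly in (0, 1)", call. = FALSE)
  invisible(spec)
}

#' @export
print.ghmm_spec <- function(x, ...) {
  cat(sprintf(paste0("<ghmm_spec order=%d min_intron=%d p_stay=%.4f ",
                     "p_single=%.3f p_term=%.3f>\n"),
              x$order, x$min_intron, x$transitions$p_stay,
              x$transitions$p_single, x$transitions$p_term))
  invisible(x)
}

# ---- duration helpers -------------------------------------------------

# truncated (shifted) geometric duration over [min, cap]
dur_geometric <- function(min, cap, p) {
  d <- min:cap
  w <- p * (1 - p)^(d - min)
  list(min = as.integer(min), cap = as.integer(cap), logp = log(w / sum(w)))
}

# empirical histogram over [min, cap] with additive smoothing; beyond the
# largest observation the smoothed mass decays geometrically (tail shape)
dur_histogram <- function(lengths, min, cap, pseudocount = 1) {
  d <- min:cap
  cnt <- tabulate(lengths - min + 1L, nbins = length(d))
  mx <- if (length(lengths)) max(lengths) else min
  mean_len <- if (length(lengths)) mean(lengths) else (min + cap) / 2
  q <- 1 / max(mean_len - min + 1, 1.5)
  tail_shape <- ifelse(d > mx, (1 - q)^(d - mx), 1)
  w <- (cnt + pseudocount / length(d)) * tail_shape
  list(min = as.integer(min), cap = as.integer(cap), logp = log(w / sum(w)))
}

dur_logp <- function(dur, d) {
  out <- rep(-Inf, length(d))
  ok <- d >= dur$min & d <= dur$cap
  out[ok] <- dur$logp[d[ok] - dur$min + 1L]
  out
}

sample_duration <- function(dur, n = 1L) {
  sample.int(dur$cap - dur$min + 1L, n, replace = TRUE,
             prob = exp(dur$logp)) + dur$min - 1L
}

# ---- sequence encoding & chain scoring --------------------------------

seq_encode <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], BASES)
}

# context index at each position (1-based t): product code of the k
# preceding bases, NA where unavailable
context_index <- function(enc, k) {
  L <- length(enc)
  if (k == 0L) return(rep(1L, L))
  idx <- rep(1L, L)
  bad <- rep(FALSE, L)
  for (j in seq_len(k)) {  # j-th previous base
    prev <- c(rep(NA_integer_, j), enc[seq_len(L - j)])
    idx <- idx + (prev - 1L) * 4L^(j - 1L)
    bad <- bad | is.na(prev)
  }
  idx[bad] <- NA_integer_
  idx
}

# per-position log emission under a chain (matrix probs, marginal fallback)
chain_logp_positions <- function(enc, ctx, probs, marg) {
  L <- length(enc)
  out <- numeric(L)
  known <- !is.na(enc)
  full <- known & !is.na(ctx)
  out[full] <- log(probs[cbind(ctx[full], enc[full])])
  out[known & is.na(ctx)] <- log(marg[enc[known & is.na(ctx)]])
  out[!known] <- log(0.25)
  out
}

# PWM window score starting at 0-based position i0 (scalar helper);
# ambiguity bases contribute log(1/4)
pwm_logp_at <- function(pwm, enc, i0) {
  w <- ncol(pwm)
  if (i0 < 0L || i0 + w > length(enc)) return(-Inf)
  b <- enc[(i0 + 1L):(i0 + w)]
  known <- !is.na(b)
  sum(log(pwm[cbind(b[known], seq_len(w)[known])])) + sum(!known) * log(0.25)
}

# ---- default (untrained) model ---------------------------------------

#' A hand-specified default gene model
#'
#' Desk-scale parameterisation used by the simulators and tests: moderate
#' coding/noncoding compositional contrast, hard splice/start/stop
#' consensus bases, short exon/intron durations.  Not a claim about any
#' particular genome.
#'
#' @param order content-chain Markov order (default 2).
#' @param max_intron,max_exon duration support caps (nt).
#' @param mean_intergenic mean intergenic run length (nt).
#' @return a [ghmm_spec()].
#' @export
ghmm_default_spec <- function(order = 2L, max_intron = 200L, max_exon = 180L,
                              mean_intergenic = 200) {
  nctx <- 4L^order
  rowmat <- function(p) matrix(rep(p, each = nctx), nrow = nctx)
  noncoding_marg <- c(0.28, 0.22, 0.22, 0.28)
  coding_marg <- list(c(0.35, 0.17, 0.35, 0.13),   # codon pos 1: purine-rich
                      c(0.30, 0.27, 0.14, 0.29),   # codon pos 2
                      c(0.13, 0.34, 0.36, 0.17))   # codon pos 3: GC-leaning
  pwm <- function(cols) {
    m <- vapply(cols, function(col) {
      if (length(col) == 1L && col %in% BASES) {
        p <- rep(0, 4); p[match(col, BASES)] <- 1; p
      } else col
    }, numeric(4))
    rownames(m) <- BASES
    m
  }
  soft <- function(fav, w = 0.55) {  # favoured base gets w, rest uniform
    p <- rep((1 - w) / 3, 4); p[match(fav, BASES)] <- w; p
  }
  # signal information content is kept near real splice-site levels
  # (donor/acceptor ~7-9 bits) so gene structures are identifiable
  signals <- list(
    start = pwm(list("A", "T", "G", soft("G", 0.7), soft("C", 0.6),
                     soft("G", 0.6))),
    donor_exonic = pwm(list(soft("A", 0.6), soft("A", 0.7), soft("G", 0.8))),
    donor_intronic = pwm(list("G", "T", soft("A", 0.8), soft("A", 0.8),
                              soft("G", 0.75), soft("T", 0.7))),
    acceptor_intronic = pwm(c(replicate(9, soft("T", 0.65), simplify = FALSE),
                              list(soft("C", 0.65), soft("C", 0.7), "A", "G"))),
    acceptor_exonic = pwm(list(soft("G", 0.7), soft("A", 0.5))),
    stop = c(TAA = 0.45, TAG = 0.2, TGA = 0.35))
  durations <- list(
    Einit = dur_geometric(MIN_EINIT, max_exon, 1 / 45),
    Eint = dur_geometric(MIN_EINT + 1L, max_exon, 1 / 60),
    Eterm = dur_geometric(MIN_ETERM + 1L, max_exon, 1 / 50),
    Esingle = dur_geometric(30L, max_exon + 120L, 1 / 90),
    I = dur_geometric(20L, max_intron, 1 / 35))
  ghmm_spec(order = order,
            coding = lapply(coding_marg, rowmat),
            noncoding = rowmat(noncoding_marg),
            coding_marg = coding_marg,
            noncoding_marg = noncoding_marg,
            signals = signals, durations = durations,
            transitions = list(p_stay = 1 - 1 / mean_intergenic,
                               p_single = 0.25, p_term = 0.45),
            min_intron = 20L)
}

# ---- path scoring (scalar reference implementation) -------------------

#' Log-probability of a full state/duration segmentation
#'
#' The scalar scoring kernel: sums transition, duration and emission
#' log-terms segment by segment, directly from the model tables.  Returns
#' `-Inf` for any forbidden component (in-frame stop inside coding, intron
#' below the minimum, broken consensus, unsupported duration); an illegal
#' state adjacency is a caller bug and raises an error instead.
#'
#' @param spec a [ghmm_spec()].
#' @param sequence character scalar (DNA).
#' @param path data.frame with columns `state` (one of `N`, `Einit`,
#'   `Eint`, `Eterm`, `Esingle`, `I`), `start`, `end` (0-based half-open),
#'   contiguous and covering the whole sequence.
#' @return log-probability (finite or `-Inf`).
#' @export
log_score_path <- function(spec, sequence, path) {
  enc <- seq_encode(sequence)
  L <- length(enc)
  check_path_legal(path, L)
  ctx <- context_index(enc, spec$order)
  logNC <- chain_logp_positions(enc, ctx, spec$noncoding, spec$noncoding_marg)
  logCC <- vapply(1:3, function(c)
    chain_logp_positions(enc, ctx, spec$coding[[c]], spec$coding_marg[[c]]),
    numeric(L))  # L x 3 matrix, column = codon position
  tr <- spec$transitions
  log_stay <- log(tr$p_stay); log_leave <- log(1 - tr$p_stay)
  sg <- spec$signals
  score <- 0
  phase <- 0L  # codon position of the next coding base
  for (si in seq_len(nrow(path))) {
    st <- path$state[si]; i <- path$start[si]; j <- path$end[si]
    d <- j - i
    nxt <- if (si < nrow(path)) path$state[si + 1L] else NA
    if (st == "N") {
      score <- score + sum(logNC[(i + 1L):j]) + (d - 1L) * log_stay
      if (!is.na(nxt)) {
        score <- score + log_leave +
          log(if (nxt == "Esingle") tr$p_single else 1 - tr$p_single)
      }
    } else if (st %in% c("Einit", "Esingle")) {
      c0 <- 0L
      score <- score + dur_logp(spec$durations[[st]], d) +
        pwm_logp_at(sg$start, enc, i)
      body_end <- j - 3L
      cod_from <- i + 6L
      score <- score + coding_span_logp(logCC, cod_from, body_end, i, c0)
      if (st == "Einit") {
        score <- score + pwm_logp_at(sg$donor_exonic, enc, j - 3L)
        if (has_inframe_stop(enc, i, j, i, c0)) score <- -Inf
        phase <- (c0 + d) %% 3L
      } else {
        if (d %% 3L != 0L) score <- -Inf
        score <- score + stop_logp(sg$stop, enc, j - 3L)
        if (has_inframe_stop(enc, i, j - 3L, i, c0)) score <- -Inf
      }
    } else if (st == "Eint") {
      c0 <- phase
      score <- score + log(1 - tr$p_term) +
        dur_logp(spec$durations$Eint, d) +
        pwm_logp_at(sg$acceptor_exonic, enc, i) +
        coding_span_logp(logCC, i + 2L, j - 3L, i, c0) +
        pwm_logp_at(sg$donor_exonic, enc, j - 3L)
      if (has_inframe_stop(enc, i, j, i, c0)) score <- -Inf
      phase <- (c0 + d) %% 3L
    } else if (st == "Eterm") {
      c0 <- phase
      if ((c0 + d) %% 3L != 0L) score <- -Inf
      score <- score + log(tr$p_term) +
        dur_logp(spec$durations$Eterm, d) +
        pwm_logp_at(sg$acceptor_exonic, enc, i) +
        coding_span_logp(logCC, i + 2L, j - 3L, i, c0) +
        stop_logp(sg$stop, enc, j - 3L)
      if (has_inframe_stop(enc, i, j - 3L, i, c0)) score <- -Inf
    } else if (st == "I") {
      if (d < spec$min_intron) return(-Inf)
      score <- score + dur_logp(spec$durations$I, d) +
        pwm_logp_at(sg$donor_intronic, enc, i) +
        sum(logNC[seq2(i + 6L + 1L, j - 13L)]) +
        pwm_logp_at(sg$acceptor_intronic, enc, j - 13L)
    }
    if (!is.finite(score)) return(-Inf)
  }
  score
}

# seq() that returns integer(0) when from > to (1-based inclusive)
seq2 <- function(from, to) if (from > to) integer(0) else from:to

# sum of coding-chain log emissions over genomic span [from, to) where the
# exon started at `exon_start` with codon position `c0`
coding_span_logp <- function(logCC, from, to, exon_start, c0) {
  if (from >= to) return(0)
  u <- from:(to - 1L)
  cp <- (c0 + u - exon_start) %% 3L
  sum(logCC[cbind(u + 1L, cp + 1L)])
}

# any stop codon fully inside [from, to) at a codon start?
has_inframe_stop <- function(enc, from, to, exon_start, c0) {
  if (to - from < 3L) return(FALSE)
  u <- from:(to - 3L)
  u <- u[(c0 + u - exon_start) %% 3L == 0L]
  if (!length(u)) return(FALSE)
  any(vapply(u, function(p) is_stop_at(enc, p), logical(1)))
}

is_stop_at <- function(enc, p) {
  if (p + 3L > length(enc)) return(FALSE)
  b <- enc[(p + 1L):(p + 3L)]
  if (anyNA(b)) return(FALSE)
  paste(BASES[b], collapse = "") %in% STOP_CODONS
}

stop_logp <- function(stop_probs, enc, p) {
  if (p < 0L || p + 3L > length(enc)) return(-Inf)
  b <- enc[(p + 1L):(p + 3L)]
  if (anyNA(b)) return(-Inf)
  codon <- paste(BASES[b], collapse = "")
  if (!codon %in% STOP_CODONS) return(-Inf)
  log(stop_probs[[codon]])
}

check_path_legal <- function(path, L) {
  stopifnot(is.data.frame(path), all(c("state", "start", "end") %in% names(path)))
  if (nrow(path) == 0L) stop("empty path", call. = FALSE)
  if (path$start[1L] != 0L || path$end[nrow(path)] != L ||
      any(path$start[-1L] != path$end[-nrow(path)]))
    stop("path must tile [0, L) contiguously", call. = FALSE)
  if (any(path$end <= path$start)) stop("empty segment in path", call. = FALSE)
  st <- path$state
  if (st[1L] != "N" || st[length(st)] != "N")
    stop("path must start and end in intergenic state N", call. = FALSE)
  allowed <- list(N = c("Einit", "Esingle", "N"),
                  Einit = "I", Esingle = "N",
                  I = c("Eint", "Eterm"), Eint = "I", Eterm = "N")
  for (si in seq_len(length(st) - 1L)) {
    if (!st[si + 1L] %in% allowed[[st[si]]])
      stop("illegal state adjacency: ", st[si], " -> ", st[si + 1L],
           call. = FALSE)
  }
  # N -> N adjacency would be two segments of the same run; forbid for
  # canonical form
  if (any(st[-1L] == "N" & st[-length(st)] == "N"))
    stop("illegal state adjacency: N -> N (merge the run)", call. = FALSE)
  invisible(TRUE)
}
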