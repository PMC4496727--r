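# Shared fixtures and independent oracles.  Everything here is written
# deliberately naively (enumeration, per-base loops) and stays
# independent of the package's dynamic-programming / cumulative-sum
# implementations.

# A reduced gene model whose duration supports fit toy sequences: only
# intergenic runs and single-exon genes are geometrically possible on
# <= 30 nt (a multi-exon gene needs >= 36 nt with the 20 nt intron
# minimum), which keeps exhaustive path enumeration cheap.
tiny_spec <- function() {
  base <- ghmm_default_spec(order = 1L)
  base$durations$Esingle <- isoscan:::dur_geometric(9L, 15L, 1 / 4)
  base$durations$Einit <- isoscan:::dur_geometric(9L, 12L, 1 / 4)
  base$durations$Eint <- isoscan:::dur_geometric(5L, 8L, 1 / 4)
  base$durations$Eterm <- isoscan:::dur_geometric(5L, 8L, 1 / 4)
  base$durations$I <- isoscan:::dur_geometric(20L, 24L, 1 / 3)
  base$transitions <- list(p_stay = 0.9, p_single = 0.5, p_term = 0.5)
  base
}

# random test sequence; with probability 1/2 an ATG + downstream in-frame
# stop is planted so legal gene paths exist reasonably often
random_test_seq <- function(L, seed) {
  set.seed(seed)
  b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (stats::runif(1) < 0.5 && L >= 12) {
    at <- sample(seq_len(L - 11L), 1L)
    b[at:(at + 2L)] <- c("A", "T", "G")
    d <- 3L * sample(2:((L - at - 2L) %/% 3L), 1L)
    if (at + d + 2L <= L)
      b[(at + d):(at + d + 2L)] <- unlist(strsplit(
        sample(c("TAA", "TAG", "TGA"), 1L), ""))
  }
  paste(b, collapse = "")
}

# exhaustive enumeration of every legal segmentation under the model
# topology (N runs >= 1 at both ends, genes per the state grammar with
# durations inside the spec's supports); returns a list of path
# data.frames.  Purely recursive -- no dynamic programming.
enumerate_paths <- function(spec, L) {
  dur <- spec$durations
  supp <- function(nm) dur[[nm]]$min:dur[[nm]]$cap
  genes_from <- function(s) {
    # all gene segmentations starting at position s; list of data.frames
    out <- list()
    for (d in supp("Esingle")) {
      if (d %% 3L != 0L || s + d > L) next
      out[[length(out) + 1L]] <- data.frame(state = "Esingle", start = s,
                                            end = s + d)
    }
    for (d1 in supp("Einit")) {
      if (s + d1 > L) next
      head_df <- data.frame(state = "Einit", start = s, end = s + d1)
      tails <- tails_from(s + d1)
      for (tl in tails)
        out[[length(out) + 1L]] <- rbind(head_df, tl)
    }
    out
  }
  tails_from <- function(p) {
    # intron followed by (Eint ... | Eterm)
    out <- list()
    for (di in supp("I")) {
      if (p + di > L) next
      idf <- data.frame(state = "I", start = p, end = p + di)
      for (dt in supp("Eterm")) {
        if (p + di + dt > L) next
        out[[length(out) + 1L]] <- rbind(idf, data.frame(
          state = "Eterm", start = p + di, end = p + di + dt))
      }
      for (de in supp("Eint")) {
        if (p + di + de > L) next
        edf <- rbind(idf, data.frame(state = "Eint", start = p + di,
                                     end = p + di + de))
        for (tl in tails_from(p + di + de))
          out[[length(out) + 1L]] <- rbind(edf, tl)
      }
    }
    out
  }
  paths <- list()
  walk <- function(prefix, pos) {
    # `pos` is the end of the last N run (>= 1 bases); either stop here
    # or start a gene and continue
    if (pos == L) { paths[[length(paths) + 1L]] <<- prefix; return() }
    for (g in genes_from(pos)) {
      gend <- g$end[nrow(g)]
      for (nlen in seq_len(L - gend)) {
        walk(rbind(prefix, g, data.frame(state = "N", start = gend,
                                         end = gend + nlen)),
             gend + nlen)
      }
    }
  }
  for (nlen in seq_len(L))
    walk(data.frame(state = "N", start = 0L, end = nlen), nlen)
  paths
}

# canonical string form of a path for set comparison
path_string <- function(path)
  paste(sprintf("%s:%d-%d", path$state, path$start, path$end),
        collapse = ";")

# score every enumerated path and return them sorted by descending score
enumerated_ranking <- function(spec, sequence) {
  L <- nchar(sequence)
  paths <- enumerate_paths(spec, L)
  scores <- vapply(paths, function(p) log_score_path(spec, sequence, p),
                   numeric(1))
  keep <- is.finite(scores)
  paths <- paths[keep]; scores <- scores[keep]
  o <- order(-scores)
  list(paths = paths[o], scores = scores[o])
}

# per-base brute force for overlap_fraction
bruteforce_overlap_fraction <- function(tx, features) {
  covered <- 0L; total <- 0L
  for (e in seq_along(tx$exon_starts)) {
    for (p in tx$exon_starts[e]:(tx$exon_ends[e] - 1L)) {
      total <- total + 1L
      hit <- FALSE
      for (f in seq_len(nrow(features))) {
        if (features$seqid[f] == tx$seqid &&
            features$start[f] <= p && p < features$end[f]) hit <- TRUE
      }
      if (hit) covered <- covered + 1L
    }
  }
  covered / total
}

# connected components of the pairwise exon-overlap graph, brute force
bruteforce_clusters <- function(transcripts) {
  n <- length(transcripts)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    ta <- transcripts[[a]]; tb <- transcripts[[b]]
    if (ta$seqid != tb$seqid || ta$strand != tb$strand) next
    for (i in seq_along(ta$exon_starts)) for (j in seq_along(tb$exon_starts))
      if (ta$exon_starts[i] < tb$exon_ends[j] &&
          tb$exon_starts[j] < ta$exon_ends[i]) adj[a, b] <- TRUE
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# simple deterministic multi-exon transcript builder for unit tests
mk_tx <- function(id, exons, strand = "+", gene = paste0(id, "g"),
                  seqid = "chr1", cds = NULL, source_tag = "KNOWN") {
  es <- vapply(exons, `[`, numeric(1), 1L)
  ee <- vapply(exons, `[`, numeric(1), 2L)
  if (is.null(cds)) cds <- c(min(es), max(ee))
  transcript(id, gene, seqid, strand, es, ee,
             cds_start = cds[1], cds_end = cds[2], source_tag = source_tag)
}

# all permutations of 1..n (for the exhaustive saturation oracle)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}
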