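# Novel-peptide / novel-protein set logic downstream of a spectral
# search against a combined RefSeq + predicted-isoform (VMC) protein
# database.  The search engine and FDR control are upstream; hits are
# taken as given.

#' Read a peptide-hit table
#'
#' Tab-separated columns: `peptide`, `accessions` (comma-separated
#' `DB:accession` entries with DB one of REFSEQ/VMC), `spectral_count`.
#'
#' @param path TSV path.
#' @return data.frame with columns `peptide`, `accessions` (list column
#'   of `DB:accession` strings), `spectral_count`.
#' @export
read_peptide_hits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "accessions", "spectral_count") %in% names(d)))
  d$accessions <- strsplit(d$accessions, ",", fixed = TRUE)
  d
}

hit_dbs <- function(accs) sub(":.*$", "", accs)

#' Preliminary novel peptides
#'
#' Peptides scoring against at least one predicted-isoform (VMC) protein
#' but against no RefSeq protein.
#'
#' @param hits data.frame as from [read_peptide_hits()].
#' @return character vector of novel peptide sequences.
#' @export
find_preliminary_novel <- function(hits) {
  sel <- vapply(hits$accessions, function(a) {
    dbs <- hit_dbs(a)
    any(dbs == "VMC") && !any(dbs == "REFSEQ")
  }, logical(1))
  unique(hits$peptide[sel])
}

#' Candidate novel-protein calls
#'
#' A VMC protein is called when it is mapped by at least two unique
#' peptides (a peptide is unique iff it maps to exactly one protein in
#' the combined database) including at least one novel peptide.
#'
#' @param hits data.frame as from [read_peptide_hits()].
#' @param novel_peptides from [find_preliminary_novel()].
#' @return data.frame with columns `accession`, `n_unique_peptides`,
#'   `n_novel_peptides`, `peptides` (list column of the supporting
#'   unique peptides), `novel` (list column of the novel subset).
#' @export
call_candidate_proteins <- function(hits, novel_peptides) {
  uniq <- lengths(hits$accessions) == 1L
  vmc <- uniq & vapply(hits$accessions, function(a)
    hit_dbs(a)[1] == "VMC", logical(1))
  sub <- hits[vmc, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(accession = character(0),
                      n_unique_peptides = integer(0),
                      n_novel_peptides = integer(0)))
  acc <- sub(".*:", "", vapply(sub$accessions, `[`, "", 1L))
  rows <- lapply(split(seq_len(nrow(sub)), acc), function(idx) {
    peps <- unique(sub$peptide[idx])
    nov <- intersect(peps, novel_peptides)
    if (length(peps) >= 2L && length(nov) >= 1L) {
      out <- data.frame(accession = acc[idx[1L]],
                        n_unique_peptides = length(peps),
                        n_novel_peptides = length(nov),
                        stringsAsFactors = FALSE)
      out$peptides <- list(peps); out$novel <- list(nov)
      out
    }
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(accession = character(0),
                      n_unique_peptides = integer(0),
                      n_novel_peptides = integer(0))
  out
}

#' Filter candidate proteins against external annotation databases
#'
#' A candidate counts as annotated in a database iff all of its novel
#' peptides occur as exact substrings of some protein sequence there (a
#' deterministic stand-in for a blastp search, conservative at tryptic
#' peptide lengths).  The final novel set is the candidates annotated in
#' neither database.
#'
#' @param calls data.frame from [call_candidate_proteins()].
#' @param gencode_proteins,swissprot_proteins character vectors of
#'   protein sequences (e.g. from [read_fasta()]).
#' @return list with `calls` (input plus logical `in_gencode`,
#'   `in_swissprot`, `final_novel`), `final_novel` (accessions) and
#'   `crosstab` (counts: candidates, both, gencode_only,
#'   swissprot_only, neither).
#' @export
external_annotation_filter <- function(calls, gencode_proteins,
                                       swissprot_proteins) {
  in_db <- function(peptides, db) {
    if (length(db) == 0L) return(FALSE)
    all(vapply(peptides, function(p)
      any(grepl(p, db, fixed = TRUE)), logical(1)))
  }
  calls$in_gencode <- vapply(calls$novel, in_db, logical(1),
                             db = gencode_proteins)
  calls$in_swissprot <- vapply(calls$novel, in_db, logical(1),
                               db = swissprot_proteins)
  calls$final_novel <- !calls$in_gencode & !calls$in_swissprot
  list(calls = calls,
       final_novel = calls$accession[calls$final_novel],
       crosstab = c(candidates = nrow(calls),
                    both = sum(calls$in_gencode & calls$in_swissprot),
                    gencode_only = sum(calls$in_gencode & !calls$in_swissprot),
                    swissprot_only = sum(!calls$in_gencode & calls$in_swissprot),
                    neither = sum(calls$final_novel)))
}

#' Flag calls whose novel peptides span a novel splice junction
#'
#' Maps each novel peptide back to CDS coordinates of its VMC transcript
#' and checks whether the peptide's codon span crosses a junction absent
#' from the known junction set.
#'
#' @param calls data.frame from [call_candidate_proteins()]; accessions
#'   must equal transcript ids of `transcripts`.
#' @param transcripts list of coding [transcript()]s.
#' @param genome named character vector of sequences.
#' @param known list of known [transcript()]s.
#' @return `calls` with an added logical `covers_novel_junction`.
#' @export
flag_novel_junction_coverage <- function(calls, transcripts, genome, known) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  known_juncs <- known_junction_set(known)
  calls$covers_novel_junction <- vapply(seq_len(nrow(calls)), function(i) {
    tx <- transcripts[ids == calls$accession[i]]
    if (length(tx) != 1L) return(FALSE)
    tx <- tx[[1L]]
    keys <- tx_cds_junction_keys(tx)
    novel_j <- which(!keys %in% known_juncs)
    if (!length(novel_j)) return(FALSE)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(tx_cds_seq(tx, genome))))
    # CDS offsets (nt, transcript space) of novel junctions
    ce <- tx_cds_exons(tx)
    w <- ce[, "end"] - ce[, "start"]
    joff <- cumsum(w)[-length(w)]
    if (tx$strand == "-") joff <- rev(sum(w) - joff)
    any(vapply(calls$novel[[i]], function(pep) {
      at <- as.integer(regexpr(pep, prot, fixed = TRUE))
      if (at < 1L) return(FALSE)
      nt_from <- (at - 1L) * 3L          # 0-based nt span of the peptide
      nt_to <- nt_from + nchar(pep) * 3L
      any(joff[novel_j] > nt_from & joff[novel_j] < nt_to)
    }, logical(1)))
  }, logical(1))
  calls
}
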