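# Translated homology search: six-frame translation, affine-gap local
# alignment (Smith-Waterman via Biostrings), Karlin-Altschul statistics and
# mapping of protein-level hits back to genome nucleotide coordinates.

#' Reverse complement of a nucleotide sequence
#'
#' @param dna Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement (an involution; `N` maps to `N`).
#' @export
reverse_complement <- function(dna) {
  .assert_scalar_string(dna, "dna")
  dna <- toupper(dna)
  .validate_alphabet(dna, "nucleotide", "(input)")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Translate a contig in all six reading frames
#'
#' Frames +1..+3 read the forward strand starting at offsets 0..2; frames
#' -1..-3 read the reverse complement the same way. The standard genetic code
#' is used; stop codons translate to `*` (kept in-sequence, never split) and
#' any codon containing `N` translates to `X`. Trailing partial codons are
#' dropped. Contigs shorter than a frame's first codon yield an empty
#' translation for that frame.
#'
#' @param contig Nucleotide string over `{A,C,G,T,N}`.
#' @return A data.frame with columns `frame` (+1..+3, -1..-3), `offset`
#'   (0-based offset of the frame's first codon on its own strand) and
#'   `protein`.
#' @export
translate_six_frames <- function(contig) {
  .assert_scalar_string(contig, "contig")
  contig <- toupper(contig)
  .validate_alphabet(contig, "nucleotide", "(input)")
  n <- nchar(contig)
  strands <- list(fwd = contig, rev = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(contig))))
  out <- lapply(1:3, function(f) {
    vapply(strands, function(s) {
      ncod <- (n - f + 1L) %/% 3L
      if (n < f || ncod < 1L) return("")
      sub <- substr(s, f, f + 3L * ncod - 1L)
      as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                         if.fuzzy.codon = "X", no.init.codon = TRUE))
    }, "")
  })
  data.frame(
    frame = c(1L, -1L, 2L, -2L, 3L, -3L),
    offset = rep(0:2, each = 2L),
    protein = unlist(out, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# Optimal affine-gap alignments of many named queries against one target.
# type "local" (Smith-Waterman) or "global" (Needleman-Wunsch).
.align_many <- function(queries, target, scoring, type = "local") {
  stopifnot(inherits(scoring, "phac_scoring"), length(queries) >= 1L,
            nzchar(target))
  pat <- Biostrings::AAStringSet(queries)
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::AAString(target), type = type,
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend)
  ins <- Biostrings::insertion(Biostrings::nindel(aln))
  del <- Biostrings::deletion(Biostrings::nindel(aln))
  data.frame(
    query = names(queries) %||% as.character(seq_along(queries)),
    raw_score = Biostrings::score(aln),
    q_start = BiocGenerics::start(Biostrings::pattern(aln)),
    q_end = BiocGenerics::end(Biostrings::pattern(aln)),
    t_start = BiocGenerics::start(Biostrings::subject(aln)),
    t_end = BiocGenerics::end(Biostrings::subject(aln)),
    align_length = Biostrings::nchar(aln),
    nmatch = Biostrings::nmatch(aln),
    mismatches = Biostrings::nmismatch(aln),
    gap_opens = ins[, 1L] + del[, 1L],
    stringsAsFactors = FALSE)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under the affine gap model of `scoring` (a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`). A best local score
#' that is not strictly positive is reported as "no alignment" (`NULL`).
#'
#' @param query,target Nonempty protein strings.
#' @param scoring A [scoring_model()].
#' @return `NULL`, or a list with `raw_score`, `q_start`, `q_end`, `t_start`,
#'   `t_end`, `align_length`, `identity_fraction` (identities / alignment
#'   columns, gap columns included), `mismatches`, `gap_opens`.
#' @export
align_local <- function(query, target, scoring = scoring_model()) {
  .assert_scalar_string(query, "query"); .assert_scalar_string(target, "target")
  r <- .align_many(c(q = query), target, scoring, type = "local")
  if (r$raw_score[1L] <= 0) return(NULL)
  list(raw_score = r$raw_score[1L],
       q_start = r$q_start[1L], q_end = r$q_end[1L],
       t_start = r$t_start[1L], t_end = r$t_end[1L],
       align_length = r$align_length[1L],
       identity_fraction = r$nmatch[1L] / r$align_length[1L],
       mismatches = r$mismatches[1L], gap_opens = r$gap_opens[1L])
}

.hits_frame <- function(df, m_len, n_db, scoring, evalue_cutoff, target_id,
                        frame = 0L) {
  bits <- bitscore(df$raw_score, scoring)
  ev <- evalue(bits, m_len, n_db)
  out <- data.frame(
    query = df$query, target = target_id,
    pct_identity = 100 * df$nmatch / df$align_length,
    align_length = df$align_length, mismatches = df$mismatches,
    gap_opens = df$gap_opens,
    q_start = df$q_start, q_end = df$q_end,
    t_start = df$t_start, t_end = df$t_end,
    evalue = ev, bitscore = bits, frame = frame,
    stringsAsFactors = FALSE)
  out[df$raw_score > 0 & ev <= evalue_cutoff, , drop = FALSE]
}

#' Protein-vs-protein search (BlastP-style)
#'
#' Aligns every query against every target and reports at most one hit per
#' (query, target) pair -- the optimal local alignment -- with bitscore and
#' E-value, filtered to `E <= evalue_cutoff`. The effective database length
#' `n` is the total residue count of `targets`.
#'
#' @param queries,targets Sequence tables as from [read_fasta()] (columns
#'   `accession`, `sequence`).
#' @param scoring A [scoring_model()].
#' @param evalue_cutoff Maximum E-value of a reported hit.
#' @return A 13-column hit table (see [write_hits_table()]); `frame` is 0.
#' @export
search_protein_vs_proteins <- function(queries, targets,
                                       scoring = scoring_model(),
                                       evalue_cutoff = 1e-10) {
  stopifnot(is.data.frame(queries), is.data.frame(targets))
  if (nrow(queries) == 0L || nrow(targets) == 0L) return(.empty_hits())
  n_db <- sum(nchar(targets$sequence))
  qseqs <- setNames(queries$sequence, queries$accession)
  m_len <- setNames(nchar(queries$sequence), queries$accession)
  hits <- lapply(seq_len(nrow(targets)), function(j) {
    df <- .align_many(qseqs, targets$sequence[j], scoring, "local")
    .hits_frame(df, m_len[df$query], n_db, scoring, evalue_cutoff,
                targets$accession[j])
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$query, hits$evalue, -hits$bitscore, hits$target), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Map an aligned span on a frame translation back to 1-based forward-strand
# nucleotide coordinates. ps/pe are 1-based residue positions in the frame's
# protein; f in +1..+3/-1..-3; len is the contig length.
.frame_span_to_nt <- function(ps, pe, f, len) {
  off <- abs(f) - 1L
  a <- off + 3L * (ps - 1L) + 1L
  b <- off + 3L * pe
  if (f > 0L) c(a, b) else c(len - b + 1L, len - a + 1L)
}

#' Translated search of a protein query set against one genome (TblastN-style)
#'
#' Each contig is translated in all six frames ([translate_six_frames()]);
#' every query is locally aligned against every frame translation, scored
#' with Karlin-Altschul statistics (`n` = total translated residues of the
#' genome) and filtered to `E <= evalue_cutoff`. Aligned spans are mapped
#' back to 1-based inclusive nucleotide coordinates on the forward strand;
#' spans are reported `min..max` with the frame sign carrying the strand.
#'
#' @param queries Protein sequence table (columns `accession`, `sequence`).
#' @param genome Data.frame with columns `genome_id`, `contig_id`, `sequence`
#'   (one row per contig, single genome).
#' @param scoring A [scoring_model()].
#' @param evalue_cutoff Maximum E-value of a reported hit.
#' @return A 13-column hit table; `target` is `genome_id:contig_id` and
#'   `frame` is in `{-3..-1, 1..3}`.
#' @export
search_protein_vs_genome <- function(queries, genome,
                                     scoring = scoring_model(),
                                     evalue_cutoff = 1e-10) {
  stopifnot(is.data.frame(queries), is.data.frame(genome),
            all(c("genome_id", "contig_id", "sequence") %in% names(genome)))
  if (length(unique(genome$genome_id)) != 1L) {
    stop("genome must contain exactly one genome_id", call. = FALSE)
  }
  trs <- lapply(seq_len(nrow(genome)), function(i) {
    tr <- translate_six_frames(genome$sequence[i])
    tr$contig_id <- genome$contig_id[i]
    tr$contig_len <- nchar(genome$sequence[i])
    tr
  })
  trs <- do.call(rbind, trs)
  trs <- trs[nchar(trs$protein) > 0L, , drop = FALSE]
  n_db <- sum(nchar(trs$protein))
  if (n_db == 0L) return(.empty_hits())
  if (nrow(queries) == 0L) return(.empty_hits())
  qseqs <- setNames(queries$sequence, queries$accession)
  m_len <- setNames(nchar(queries$sequence), queries$accession)
  gid <- genome$genome_id[1L]
  hits <- lapply(seq_len(nrow(trs)), function(i) {
    df <- .align_many(qseqs, trs$protein[i], scoring, "local")
    h <- .hits_frame(df, m_len[df$query], n_db, scoring, evalue_cutoff,
                     paste0(gid, ":", trs$contig_id[i]), frame = trs$frame[i])
    if (nrow(h)) {
      nt <- t(mapply(.frame_span_to_nt, h$t_start, h$t_end,
                     MoreArgs = list(f = trs$frame[i], len = trs$contig_len[i])))
      h$t_start <- nt[, 1L]; h$t_end <- nt[, 2L]
    }
    h
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$evalue, -hits$bitscore, hits$query, hits$target,
                     hits$t_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(query = character(), target = character(),
             pct_identity = numeric(), align_length = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(),
             t_start = numeric(), t_end = numeric(),
             evalue = numeric(), bitscore = numeric(), frame = numeric(),
             stringsAsFactors = FALSE)
}
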