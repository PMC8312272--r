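# Class transfer onto unclassified references and per-genome genotype
# calling with explicit tie-break rules, plus GOLD metadata appending.

# deterministic best-hit selection: lowest E, then highest bitscore, then
# lexicographically smallest accession in `by`, then target/position.
.best_hit <- function(hits, by = "query") {
  ord <- order(hits$evalue, -hits$bitscore, hits[[by]], hits$target,
               hits$t_start)
  hits[ord[1L], , drop = FALSE]
}

#' Transfer PhaC classes onto unclassified references by best protein hit
#'
#' Every classified reference is aligned against every unclassified sequence
#' (BlastP-style, [search_protein_vs_proteins()]). Each unclassified
#' sequence adopts the class of the classified query with the lowest
#' E-value; among equal E-values the highest bitscore wins, and any residual
#' tie is broken by the lexicographically smallest query accession. A
#' sequence with no hit at `E <= evalue_cutoff` stays `Unknown`.
#'
#' @param unclassified Reference table of sequences with unknown class.
#' @param classified Reference table with a populated `phac_class` column
#'   (classes in I/II/III/IV).
#' @param scoring A [scoring_model()].
#' @param evalue_cutoff Transfer E-value cutoff.
#' @return A data.frame with one row per unclassified sequence: `accession`,
#'   `assigned_class`, `source_query` (`NA` if Unknown), `evalue`, `bitscore`.
#' @export
classify_unknowns <- function(unclassified, classified,
                              scoring = scoring_model(),
                              evalue_cutoff = 1e-10) {
  stopifnot(is.data.frame(unclassified))
  blank <- data.frame(accession = unclassified$accession,
                      assigned_class = "Unknown",
                      source_query = NA_character_,
                      evalue = NA_real_, bitscore = NA_real_,
                      stringsAsFactors = FALSE)
  if (is.null(classified) || nrow(classified) == 0L) {
    warning("no classified references supplied; all sequences stay Unknown")
    return(blank)
  }
  stopifnot(all(classified$phac_class %in% c("I", "II", "III", "IV")))
  if (nrow(unclassified) == 0L) return(blank)
  hits <- search_protein_vs_proteins(classified, unclassified, scoring,
                                     evalue_cutoff)
  cls_of <- setNames(classified$phac_class, classified$accession)
  for (i in seq_len(nrow(unclassified))) {
    h <- hits[hits$target == unclassified$accession[i], , drop = FALSE]
    if (!nrow(h)) next
    b <- .best_hit(h, by = "query")
    blank$assigned_class[i] <- unname(cls_of[b$query])
    blank$source_query[i] <- b$query
    blank$evalue[i] <- b$evalue
    blank$bitscore[i] <- b$bitscore
  }
  blank
}

#' Call one representative PhaC genotype per genome
#'
#' For each genome, hits from *all* queries are pooled
#' ([search_protein_vs_genome()]) and a single best hit is selected: lowest
#' E-value, then highest bitscore, then lexicographically smallest query
#' accession. The call carries the class of the matched query. Genomes with
#' no hit at `E <= evalue_cutoff` are absent from the output, so there is at
#' most one call per genome.
#'
#' @param queries Classified reference table (`accession`, `sequence`,
#'   `phac_class`).
#' @param genomes Data.frame of contigs (`genome_id`, `contig_id`,
#'   `sequence`), possibly many genomes.
#' @param scoring A [scoring_model()].
#' @param evalue_cutoff Mining E-value cutoff.
#' @param all_hits If `TRUE`, the full pooled hit table is attached as
#'   attribute `"hits"` (multi-locus detection escape hatch; off by default).
#' @return A data.frame with one row per called genome: `genome_id`,
#'   `query_accession`, `phac_class`, plus the winning hit's columns.
#' @export
call_genotypes <- function(queries, genomes, scoring = scoring_model(),
                           evalue_cutoff = 1e-10, all_hits = FALSE) {
  stopifnot(is.data.frame(queries), "phac_class" %in% names(queries),
            is.data.frame(genomes))
  gids <- unique(genomes$genome_id)
  cls_of <- setNames(queries$phac_class, queries$accession)
  pool <- list(); calls <- list()
  for (g in gids) {
    h <- search_protein_vs_genome(queries,
                                  genomes[genomes$genome_id == g, , drop = FALSE],
                                  scoring, evalue_cutoff)
    if (all_hits && nrow(h)) pool[[g]] <- h
    if (!nrow(h)) next
    b <- .best_hit(h, by = "query")
    calls[[g]] <- cbind(
      data.frame(genome_id = g, query_accession = b$query,
                 phac_class = unname(cls_of[b$query]),
                 stringsAsFactors = FALSE),
      b[, setdiff(names(b), "query"), drop = FALSE])
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    cbind(data.frame(genome_id = character(), query_accession = character(),
                     phac_class = character(), stringsAsFactors = FALSE),
          .empty_hits()[, -1L, drop = FALSE])
  rownames(out) <- NULL
  if (all_hits) {
    attr(out, "hits") <- if (length(pool)) do.call(rbind, pool) else .empty_hits()
  }
  out
}

#' Append GOLD taxonomy/ecosystem metadata to genotype calls
#'
#' @param calls Genotype calls from [call_genotypes()].
#' @param gold GOLD metadata table ([read_metadata_table()] with
#'   `schema = "gold"`). Every call's `genome_id` must be present.
#' @return One row per call: the GOLD columns plus `query_accession` and
#'   `phac_class`.
#' @export
append_metadata <- function(calls, gold) {
  stopifnot(is.data.frame(calls), is.data.frame(gold),
            "genome_id" %in% names(gold))
  missing_ids <- setdiff(calls$genome_id, gold$genome_id)
  if (length(missing_ids)) {
    stop("no GOLD metadata for genome '", missing_ids[1L], "'", call. = FALSE)
  }
  gold_cols <- c("genome_id", "domain", "phylum", "ecosystem",
                 "ecosystem_category", "ecosystem_type", "ecosystem_subtype",
                 "habitat")
  idx <- match(calls$genome_id, gold$genome_id)
  out <- cbind(gold[idx, gold_cols, drop = FALSE],
               calls[, c("query_accession", "phac_class"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Excise and translate the protein sequence under a genotype call
#'
#' Cuts the called nucleotide span out of its contig, reverse-complements it
#' for negative-frame hits, and translates it (frame +1) -- the predicted
#' PhaC protein used for downstream phylogenetics.
#'
#' @param calls Genotype calls from [call_genotypes()].
#' @param genomes Contig table the calls were made on.
#' @return Character vector of predicted proteins, named by `genome_id`.
#' @export
predicted_proteins <- function(calls, genomes) {
  stopifnot(is.data.frame(calls), is.data.frame(genomes))
  key <- paste(genomes$genome_id, genomes$contig_id, sep = ":")
  out <- vapply(seq_len(nrow(calls)), function(i) {
    ctg <- genomes$sequence[match(calls$target[i], key)]
    seg <- substr(ctg, calls$t_start[i], calls$t_end[i])
    if (calls$frame[i] < 0) seg <- reverse_complement(seg)
    seg <- substr(seg, 1L, 3L * (nchar(seg) %/% 3L))
    sub("\\*+$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(seg), if.fuzzy.codon = "X", no.init.codon = TRUE)))
  }, "")
  setNames(out, calls$genome_id)
}
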