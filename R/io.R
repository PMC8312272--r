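# Readers and writers for every external format the pipeline touches:
# FASTA, tab-separated metadata, the 13-column tabular hit format and Newick.

#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased and validated against a strict alphabet:
#' `{A,C,G,T,N}` for nucleotide input, the 20 amino acids plus `{X,*,B,Z,U}`
#' for protein input. The accession is the first whitespace-delimited token of
#' the header line and must be unique within the file.
#'
#' @param path Path to a FASTA file. An empty file yields a zero-row table.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A data.frame with columns `accession`, `sequence`, `length`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  .assert_scalar_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(accession = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(empty)
  acc <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  if (any(!nzchar(acc))) stop("empty accession in FASTA header", call. = FALSE)
  dup <- acc[duplicated(acc)]
  if (length(dup)) stop("duplicate FASTA id: '", dup[1L], "'", call. = FALSE)
  seqs <- toupper(as.character(set))
  .validate_alphabet(seqs, alphabet, acc)
  data.frame(accession = acc, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a sequence table as FASTA
#'
#' Round-trips through [read_fasta()]: `read(write(x))` recovers `x`, and a
#' write-read-write cycle is byte-identical.
#'
#' @param records Data.frame with `accession` and `sequence` columns.
#' @param path Output path.
#' @param wrap Sequence line width (residues per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.data.frame(records), all(c("accession", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$accession))
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a tab-separated metadata table
#'
#' Two schemas are supported. `"reference"` describes candidate PhaC query
#' proteins (columns `accession`, `protein_name`, `tigrfam_ids`,
#' `taxon_domain`; `tigrfam_ids` is a `";"`-separated, possibly empty list).
#' `"gold"` describes per-genome taxonomy and the GOLD ecosystem path
#' (columns `genome_id`, `domain`, `phylum`, `ecosystem`, `ecosystem_category`,
#' `ecosystem_type`, `ecosystem_subtype`, `habitat`). Missing cells become the
#' literal token `"unclassified"`, except an empty `tigrfam_ids` cell, which
#' stays `""` (an empty identifier list, not missing information).
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param schema `"reference"` or `"gold"`.
#' @return A data.frame with the schema's columns, all character.
#' @export
read_metadata_table <- function(path, schema = c("reference", "gold")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- switch(schema,
    reference = c("accession", "protein_name", "tigrfam_ids", "taxon_domain"),
    gold = c("genome_id", "domain", "phylum", "ecosystem", "ecosystem_category",
             "ecosystem_type", "ecosystem_subtype", "habitat"))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("metadata table lacks required column '", missing_cols[1L], "'",
         call. = FALSE)
  }
  tab <- tab[, required, drop = FALSE]
  fill <- setdiff(required, "tigrfam_ids")
  for (col in fill) {
    blank <- is.na(tab[[col]]) | !nzchar(trimws(tab[[col]]))
    tab[[col]][blank] <- "unclassified"
  }
  if ("tigrfam_ids" %in% names(tab)) {
    tab$tigrfam_ids[is.na(tab$tigrfam_ids)] <- ""
  }
  tab
}

#' Split a `";"`-separated TIGRFAM field into identifiers
#' @param x Character vector of `";"`-separated identifier lists.
#' @return A list of character vectors (empty vector for empty cells).
#' @export
split_tigrfam_ids <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

.HITS_COLS <- c("query", "target", "pct_identity", "align_length", "mismatches",
                "gap_opens", "q_start", "q_end", "t_start", "t_end",
                "evalue", "bitscore", "frame")

.format_evalue <- function(e) {
  ifelse(e == 0, "0.0", sprintf("%.1e", e))
}

#' Write alignment hits as a 13-column tab-separated table
#'
#' The layout follows the common 12-column tabular hit dialect (query, target,
#' percent identity, alignment length, mismatches, gap opens, query/target
#' spans, E-value, bitscore) plus a 13th `frame` column; frame `0` encodes
#' "none" (protein-vs-protein hits). E-values are serialized in scientific
#' notation with two significand digits (`0.0` for exact zero).
#'
#' @param hits Hit table as produced by the search functions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  stopifnot(is.data.frame(hits), all(.HITS_COLS %in% names(hits)))
  out <- hits[, .HITS_COLS, drop = FALSE]
  out$pct_identity <- sprintf("%.3f", out$pct_identity)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  out$evalue <- .format_evalue(out$evalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tabular hit file written by [write_hits_table()]
#'
#' @param path Path to a 13-column tab-separated hit table with header.
#' @return A data.frame with the 13 hit columns, numerics parsed.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("hit table is empty (missing header)", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .HITS_COLS)) {
    stop("malformed hit table header at line 1", call. = FALSE)
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 13L)) {
    stop("malformed hit row at line ", which(nf != 13L)[1L] + 1L, call. = FALSE)
  }
  col <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, line_off = 1L) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("malformed numeric field at line ",
           which(is.na(v))[1L] + line_off, call. = FALSE)
    }
    v
  }
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character()), 13L), .HITS_COLS),
                         stringsAsFactors = FALSE)
    for (i in 3:13) out[[i]] <- numeric()
    return(out)
  }
  data.frame(query = col(1), target = col(2),
             pct_identity = num(3), align_length = num(4),
             mismatches = num(5), gap_opens = num(6),
             q_start = num(7), q_end = num(8),
             t_start = num(9), t_end = num(10),
             evalue = num(11), bitscore = num(12),
             frame = num(13), stringsAsFactors = FALSE)
}

#' Write a tree in Newick format
#'
#' Accepts an `ape::phylo` object, or a single character label for the
#' degenerate one-leaf case (written as `label;`). Labels containing any of
#' `(),;:` or whitespace are single-quoted.
#'
#' @param tree An `ape` `phylo` object or a single leaf label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  quote_label <- function(x) {
    needs <- grepl("[(),;:[:space:]]", x)
    x[needs] <- paste0("'", gsub("'", "_", x[needs]), "'")
    x
  }
  if (is.character(tree) && length(tree) == 1L) {
    writeLines(paste0(quote_label(tree), ";"), path)
    return(invisible(path))
  }
  stopifnot(inherits(tree, "phylo"))
  # serialize with placeholder labels, then substitute the (possibly quoted)
  # originals -- ape sanitizes labels in place, which would corrupt them
  labels <- tree$tip.label
  placeholders <- sprintf("PHACTIP%06d", seq_along(labels))
  tree$tip.label <- placeholders
  nwk <- ape::write.tree(tree)
  for (i in seq_along(labels)) {
    nwk <- sub(placeholders[i], quote_label(labels[i]), nwk, fixed = TRUE)
  }
  writeLines(nwk, path)
  invisible(path)
}
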