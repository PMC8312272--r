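# Reference curation: name-based exclusions, domain-specific length filters,
# duplicate removal and class assignment from protein-name / TIGRFAM metadata.

.PHAC_CLASSES <- c("I", "II", "III", "IV", "Unknown")

#' Default curation rules for PhaC reference sets
#'
#' The shipped rules reconstruct, as reproducible patterns, the manual
#' curation of UniProtKB PhaC exports: four ordered name-exclusion groups
#' (non-PhaC names, ambiguous names, putative entries, explicit fragments),
#' domain-specific minimum lengths (fragments are anything below 328 residues
#' in bacteria or 100 in archaea), word-boundary class patterns on the
#' protein name (`class I`..`class IV`, plus the `PhaC1`/`PhaC2` subunit
#' names that imply Class II) and a TIGRFAM-to-class map. All patterns match
#' case-insensitively and every component is user-overridable.
#'
#' @param name_exclusions Data.frame with columns `pattern` (plain substring,
#'   matched case-insensitively) and `reason` (one of `not_phac`,
#'   `ambiguous`, `putative`, `fragment_name`); first match in row order wins.
#' @param min_length Named numeric vector with elements `bacteria`, `archaea`.
#' @param class_name_patterns Named character vector: regular expression ->
#'   class label.
#' @param tigrfam_class_map Named character vector: TIGRFAM id -> class label.
#' @return A list of class `phac_rules`.
#' @export
curation_rules <- function(
    name_exclusions = data.frame(
      pattern = c("depolymerase", "phasin", "regulator",
                  "uncharacterized", "hypothetical", "domain-containing protein",
                  "putative", "fragment"),
      reason = c("not_phac", "not_phac", "not_phac",
                 "ambiguous", "ambiguous", "ambiguous",
                 "putative", "fragment_name"),
      stringsAsFactors = FALSE),
    min_length = c(bacteria = 328, archaea = 100),
    class_name_patterns = c(
      "class[ _-]?IV\\b" = "IV",
      "class[ _-]?III\\b" = "III",
      "class[ _-]?II\\b" = "II",
      "class[ _-]?I\\b" = "I",
      "\\bphac1\\b" = "II",
      "\\bphac2\\b" = "II"),
    tigrfam_class_map = c(TIGR01838 = "I", TIGR01839 = "II", TIGR01836 = "III")) {
  stopifnot(is.data.frame(name_exclusions),
            all(c("pattern", "reason") %in% names(name_exclusions)),
            all(name_exclusions$reason %in%
                  c("not_phac", "ambiguous", "putative", "fragment_name")),
            all(min_length > 0),
            all(c("bacteria", "archaea") %in% names(min_length)),
            all(class_name_patterns %in% .PHAC_CLASSES),
            all(tigrfam_class_map %in% .PHAC_CLASSES))
  structure(list(name_exclusions = name_exclusions, min_length = min_length,
                 class_name_patterns = class_name_patterns,
                 tigrfam_class_map = tigrfam_class_map),
            class = "phac_rules")
}

.curation_result <- function(kept, removed) {
  stopifnot(!anyDuplicated(c(kept$accession, removed$accession)))
  list(kept = kept, removed = removed)
}

.empty_removed <- function(refs) {
  cbind(refs[0L, , drop = FALSE], data.frame(reason = character()))
}

#' Remove references whose protein name matches an exclusion pattern
#'
#' A reference is removed with the reason of the *first* matching pattern in
#' rule order; unmatched references are kept. Empty rules keep everything.
#'
#' @param refs Reference table with a `protein_name` column.
#' @param rules A [curation_rules()] object.
#' @return A list with `kept` and `removed` (removed rows gain a `reason`
#'   column); row counts add up to the input.
#' @export
apply_name_exclusions <- function(refs, rules = curation_rules()) {
  stopifnot(is.data.frame(refs), "protein_name" %in% names(refs))
  reason <- rep(NA_character_, nrow(refs))
  lname <- tolower(refs$protein_name)
  for (i in rev(seq_len(nrow(rules$name_exclusions)))) {
    hit <- grepl(tolower(rules$name_exclusions$pattern[i]), lname, fixed = TRUE)
    reason[hit] <- rules$name_exclusions$reason[i]
  }
  rm_idx <- !is.na(reason)
  removed <- refs[rm_idx, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[rm_idx] else removed <- .empty_removed(refs)
  .curation_result(refs[!rm_idx, , drop = FALSE], removed)
}

#' Remove references below the domain's minimum length
#'
#' Fragments are references shorter than `min_length[taxon_domain]`
#' (328 residues for bacteria, 100 for archaea by default); they are removed
#' with reason `fragment_length`.
#'
#' @param refs Reference table with a `length` column.
#' @param rules A [curation_rules()] object.
#' @param taxon_domain `"bacteria"` or `"archaea"`.
#' @return A list with `kept` and `removed` as in [apply_name_exclusions()].
#' @export
apply_length_filter <- function(refs, rules = curation_rules(),
                                taxon_domain = c("bacteria", "archaea")) {
  taxon_domain <- match.arg(taxon_domain)
  stopifnot(is.data.frame(refs), "length" %in% names(refs))
  rm_idx <- refs$length < rules$min_length[[taxon_domain]]
  removed <- refs[rm_idx, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "fragment_length" else removed <- .empty_removed(refs)
  .curation_result(refs[!rm_idx, , drop = FALSE], removed)
}

#' Remove byte-identical duplicate sequences (keep-first)
#'
#' Among references with identical sequences the first in input order is
#' kept; later ones are removed with reason `duplicate`.
#'
#' @param refs Reference table with a `sequence` column.
#' @return A list with `kept` and `removed`.
#' @export
deduplicate_refs <- function(refs) {
  stopifnot(is.data.frame(refs), "sequence" %in% names(refs))
  rm_idx <- duplicated(refs$sequence)
  removed <- refs[rm_idx, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "duplicate" else removed <- .empty_removed(refs)
  .curation_result(refs[!rm_idx, , drop = FALSE], removed)
}

#' Assign PhaC classes from protein-name and TIGRFAM metadata
#'
#' For each reference: if a class-name pattern matches the protein name, that
#' class is assigned with provenance `name_field` (two patterns naming
#' *different* classes is an error); otherwise, if any TIGRFAM id (first in
#' listed order) is in the TIGRFAM map, the mapped class is assigned with
#' provenance `tigrfam_field`; otherwise the class is `Unknown` with
#' provenance `unassigned`. Deterministic and idempotent.
#'
#' @param refs Reference table with `protein_name` and `tigrfam_ids`
#'   (`";"`-separated) columns.
#' @param rules A [curation_rules()] object.
#' @return `refs` with `phac_class` and `provenance` columns set.
#' @export
assign_class_from_metadata <- function(refs, rules = curation_rules()) {
  stopifnot(is.data.frame(refs),
            all(c("protein_name", "tigrfam_ids") %in% names(refs)))
  pats <- rules$class_name_patterns
  tmap <- rules$tigrfam_class_map
  tids <- split_tigrfam_ids(refs$tigrfam_ids)
  cls <- character(nrow(refs)); prov <- character(nrow(refs))
  for (i in seq_len(max(nrow(refs), 0L))) {
    hit <- vapply(names(pats), function(p)
      grepl(p, refs$protein_name[i], ignore.case = TRUE, perl = TRUE), NA)
    classes <- unique(unname(pats[hit]))
    if (length(classes) > 1L) {
      stop(sprintf("protein name '%s' matches contradictory classes: %s",
                   refs$protein_name[i], paste(classes, collapse = ", ")),
           call. = FALSE)
    }
    if (length(classes) == 1L) {
      cls[i] <- classes; prov[i] <- "name_field"
    } else {
      mapped <- tmap[tids[[i]]]
      mapped <- mapped[!is.na(mapped)]
      if (length(mapped)) {
        cls[i] <- mapped[[1L]]; prov[i] <- "tigrfam_field"
      } else {
        cls[i] <- "Unknown"; prov[i] <- "unassigned"
      }
    }
  }
  refs$phac_class <- cls
  refs$provenance <- prov
  refs
}

#' Curate a PhaC reference set
#'
#' Runs the full curation pipeline in order: name exclusions, length filter,
#' duplicate removal, then class assignment on the survivors. Every input
#' row ends up exactly once in `kept` or `removed`.
#'
#' @param refs Reference table: `accession`, `sequence`, `length`,
#'   `protein_name`, `tigrfam_ids` (and optionally `taxon_domain`).
#' @param rules A [curation_rules()] object.
#' @param taxon_domain `"bacteria"` or `"archaea"` (sets the length cutoff).
#' @return A list with `kept` (classes assigned), `removed` (with `reason`)
#'   and `report`: counts per removal reason plus per-class totals.
#' @export
curate_references <- function(refs, rules = curation_rules(),
                              taxon_domain = c("bacteria", "archaea")) {
  taxon_domain <- match.arg(taxon_domain)
  n_in <- nrow(refs)
  s1 <- apply_name_exclusions(refs, rules)
  s2 <- apply_length_filter(s1$kept, rules, taxon_domain)
  s3 <- deduplicate_refs(s2$kept)
  removed <- rbind(s1$removed, s2$removed, s3$removed)
  kept <- assign_class_from_metadata(s3$kept, rules)
  stopifnot(nrow(kept) + nrow(removed) == n_in)
  reasons <- c("not_phac", "ambiguous", "putative", "fragment_name",
               "fragment_length", "duplicate")
  report <- rbind(
    data.frame(metric = paste0("removed_", reasons),
               value = vapply(reasons, function(r) sum(removed$reason == r), 0L),
               stringsAsFactors = FALSE),
    data.frame(metric = paste0("kept_class_", .PHAC_CLASSES),
               value = vapply(.PHAC_CLASSES,
                              function(k) sum(kept$phac_class == k), 0L),
               stringsAsFactors = FALSE),
    data.frame(metric = c("input", "kept", "removed"),
               value = c(n_in, nrow(kept), nrow(removed)),
               stringsAsFactors = FALSE))
  rownames(report) <- NULL
  list(kept = kept, removed = removed, report = report)
}
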