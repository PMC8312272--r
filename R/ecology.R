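# Environmental filtering, relative-abundance tabulation, phylum/ecosystem
# cross-tabs and extreme-environment flagging and subtotals.

#' Keep genotype rows from classified environmental genomes
#'
#' Retains rows whose GOLD ecosystem is `Environmental` *and* whose ecosystem
#' category is `Aquatic` or `Terrestrial` (both conditions; in the GOLD
#' hierarchy Aquatic/Terrestrial are children of Environmental), and drops
#' any row whose ecosystem, category or ecosystem type is the missing-value
#' token `unclassified`. Matching is case-insensitive.
#'
#' @param rows Annotated table ([append_metadata()]).
#' @return The retained rows.
#' @export
filter_environmental <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("ecosystem", "ecosystem_category", "ecosystem_type")
                %in% names(rows)))
  eco <- tolower(rows$ecosystem)
  cat <- tolower(rows$ecosystem_category)
  typ <- tolower(rows$ecosystem_type)
  keep <- eco == "environmental" & cat %in% c("aquatic", "terrestrial") &
    eco != "unclassified" & cat != "unclassified" & typ != "unclassified"
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative abundance as a one-decimal percentage (half-up)
#'
#' `100 * count / total`, rounded *half-up* to one decimal place using exact
#' integer arithmetic (no floating-point rounding artifacts): 27.45 rounds
#' to 27.5.
#'
#' @param count Nonnegative integer count(s), `count <= total`.
#' @param total Positive integer total(s).
#' @return Numeric percentage(s) with one decimal.
#' @export
relative_abundance <- function(count, total) {
  if (any(total < 1)) stop("total must be >= 1", call. = FALSE)
  if (any(count < 0) || any(count > total)) {
    stop("need 0 <= count <= total", call. = FALSE)
  }
  if (any(count != floor(count)) || any(total != floor(total))) {
    stop("count and total must be whole numbers", call. = FALSE)
  }
  q <- (1000 * count) %/% total
  r <- (1000 * count) %% total
  (q + (2 * r >= total)) / 10
}

#' Tabulate genotype counts and relative abundances
#'
#' Groups annotated rows and reports counts with one-decimal relative
#' abundances. Denominators follow the grouping: for `"class"` the whole
#' table; for `"class_ecosystem_type"` each class's total (percentages per
#' class sum to 100 up to rounding); for `"phylum_ecosystem_type"` each
#' phylum's total. Row order is deterministic: class (or phylum), then
#' descending count, then label.
#'
#' @param rows Annotated table with `phac_class` (and `phylum`,
#'   `ecosystem_type` as needed).
#' @param group_by Grouping: `"class"`, `"class_ecosystem_type"` or
#'   `"phylum_ecosystem_type"`.
#' @return A data.frame with group columns, `count` and
#'   `relative_abundance_pct`.
#' @export
tabulate_genotypes <- function(rows,
                               group_by = c("class", "class_ecosystem_type",
                                            "phylum_ecosystem_type")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(rows))
  cols <- switch(group_by,
                 class = "phac_class",
                 class_ecosystem_type = c("phac_class", "ecosystem_type"),
                 phylum_ecosystem_type = c("phylum", "ecosystem_type"))
  if (!nrow(rows)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    out$count <- integer(); out$relative_abundance_pct <- numeric()
    return(out)
  }
  key <- interaction(rows[cols], drop = TRUE, sep = "\r")
  counts <- as.integer(table(key))
  labels <- do.call(rbind, strsplit(names(table(key)), "\r", fixed = TRUE))
  out <- as.data.frame(labels, stringsAsFactors = FALSE)
  names(out) <- cols
  out$count <- counts
  denom_col <- cols[[1L]]
  denom <- tapply(out$count, out[[denom_col]], sum)
  out$relative_abundance_pct <-
    relative_abundance(out$count, as.integer(denom[out[[denom_col]]]))
  ord <- if (length(cols) == 1L) order(out[[1L]]) else
    order(out[[1L]], -out$count, out[[2L]])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default extreme-environment descriptor table
#'
#' One row per (ecosystem type, subtype-or-habitat pattern) combination that
#' marks an extreme physicochemical setting: hydrothermal and deep-sea
#' marine habitats; all of the "Non-marine saline and alkaline", "Thermal
#' springs", "Oil reservoir" and "Mud volcano" ecosystem types; acid-mine
#' and salt "Geologic" settings; halite-pinnacle "Rock-dwelling"; and
#' creosote-contaminated, desert, permafrost or saline soils. The pattern
#' `"*"` matches every subtype/habitat; other patterns are case-insensitive
#' substrings matched against both the ecosystem subtype and the habitat.
#'
#' @return Data.frame with columns `ecosystem_type`, `pattern`, `label`.
#' @export
extreme_descriptors <- function() {
  d <- rbind(
    c("Marine", "deep oceanic"), c("Marine", "deep-sea"),
    c("Marine", "basalt-hosted"), c("Marine", "hydrothermal"),
    c("Non-marine saline and alkaline", "*"),
    c("Thermal springs", "*"),
    c("Oil reservoir", "*"),
    c("Mud volcano", "*"),
    c("Geologic", "acid mine"), c("Geologic", "saline water"),
    c("Geologic", "salt"),
    c("Rock-dwelling", "halite"),
    c("Soil", "creosote"), c("Soil", "desert"),
    c("Soil", "permafrost"), c("Soil", "saline"))
  data.frame(ecosystem_type = d[, 1L], pattern = d[, 2L], label = "extreme",
             stringsAsFactors = FALSE)
}

#' Flag genotypes from extreme physicochemical environments
#'
#' A row is flagged iff some descriptor row has the same ecosystem type
#' (case-insensitive) and its pattern is `"*"` or a case-insensitive
#' substring of the row's ecosystem subtype or habitat. Subtotals and
#' relative abundances are computed per class against each class's
#' environmental total, so flagged + unflagged partition the input.
#'
#' @param rows Environmentally filtered annotated table
#'   ([filter_environmental()]).
#' @param descriptors Descriptor table ([extreme_descriptors()]).
#' @return A list: `rows` (input plus logical `extreme` column) and
#'   `subtotals` (per class: `count`, `total`, `relative_abundance_pct`).
#' @export
flag_extreme <- function(rows, descriptors = extreme_descriptors()) {
  stopifnot(is.data.frame(rows), is.data.frame(descriptors))
  flag <- rep(FALSE, nrow(rows))
  typ <- tolower(rows$ecosystem_type)
  sub <- tolower(rows$ecosystem_subtype %||% rep("", nrow(rows)))
  hab <- tolower(rows$habitat %||% rep("", nrow(rows)))
  for (i in seq_len(nrow(descriptors))) {
    same_type <- typ == tolower(descriptors$ecosystem_type[i])
    pat <- tolower(descriptors$pattern[i])
    m <- if (pat == "*") same_type else
      same_type & (grepl(pat, sub, fixed = TRUE) | grepl(pat, hab, fixed = TRUE))
    flag <- flag | m
  }
  rows$extreme <- flag
  classes <- sort(unique(rows$phac_class))
  subtotals <- data.frame(
    phac_class = classes,
    count = vapply(classes, function(k) sum(flag & rows$phac_class == k), 0L),
    total = vapply(classes, function(k) sum(rows$phac_class == k), 0L),
    stringsAsFactors = FALSE)
  subtotals$relative_abundance_pct <-
    relative_abundance(subtotals$count, pmax(subtotals$total, 1L))
  rownames(subtotals) <- NULL
  list(rows = rows, subtotals = subtotals)
}

#' Write distribution reports (and optionally a plot)
#'
#' Writes `tally_class_ecosystem.tsv`, `tally_phylum_ecosystem.tsv` and
#' `extreme_subtotals.tsv` into `out_dir`; values equal those returned by
#' [tabulate_genotypes()] and [flag_extreme()]. Empty input produces
#' header-only files. With `plot = TRUE` (requires ggplot2) a stacked
#' relative-abundance bar chart is written as `distribution.pdf`.
#'
#' @param rows Environmentally filtered annotated table.
#' @param out_dir Output directory (created if needed).
#' @param descriptors Extreme-environment descriptor table.
#' @param plot Whether to render the stacked-bar figure.
#' @return Named character vector of file paths, invisibly.
#' @export
report_distribution <- function(rows, out_dir,
                                descriptors = extreme_descriptors(),
                                plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tally_ce <- tabulate_genotypes(rows, "class_ecosystem_type")
  tally_pe <- tabulate_genotypes(rows, "phylum_ecosystem_type")
  ext <- flag_extreme(rows, descriptors)
  paths <- c(
    class_ecosystem = file.path(out_dir, "tally_class_ecosystem.tsv"),
    phylum_ecosystem = file.path(out_dir, "tally_phylum_ecosystem.tsv"),
    extreme = file.path(out_dir, "extreme_subtotals.tsv"))
  utils::write.table(tally_ce, paths[["class_ecosystem"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tally_pe, paths[["phylum_ecosystem"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ext$subtotals, paths[["extreme"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (plot) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; skipping plot")
    } else if (nrow(tally_ce)) {
      p <- ggplot2::ggplot(tally_ce, ggplot2::aes(
        x = phac_class, y = relative_abundance_pct, fill = ecosystem_type)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "PhaC class", y = "Relative abundance (%)",
                      fill = "Ecosystem type")
      pp <- file.path(out_dir, "distribution.pdf")
      ggplot2::ggsave(pp, p, width = 7, height = 5)
      paths <- c(paths, plot = pp)
    }
  }
  invisible(paths)
}

utils::globalVariables(c("phac_class", "relative_abundance_pct",
                         "ecosystem_type"))
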