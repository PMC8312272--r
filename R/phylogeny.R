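# Desk-scale phylogenetics: alignment-based p-distances, neighbor-joining
# trees and class-annotation export for external tree viewers.

#' Alignment-based p-distance between two proteins
#'
#' One minus the identity fraction of the optimal *global* affine-gap
#' alignment, with gap columns counted in the denominator. Symmetric, 0 for
#' identical sequences, at most 1.
#'
#' @param a,b Nonempty protein strings.
#' @param scoring A [scoring_model()].
#' @return A distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b, scoring = scoring_model()) {
  .assert_scalar_string(a, "a"); .assert_scalar_string(b, "b")
  r <- .align_many(c(q = a), b, scoring, type = "global")
  1 - r$nmatch[1L] / r$align_length[1L]
}

#' Pairwise p-distance matrix over a set of labeled proteins
#'
#' @param seqs Named character vector of protein sequences (unique labels),
#'   or a sequence table with `accession` and `sequence` columns.
#' @param scoring A [scoring_model()].
#' @return A symmetric numeric matrix with zero diagonal, labeled by name.
#' @export
build_distance_matrix <- function(seqs, scoring = scoring_model()) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$accession)
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("duplicate label: '", dup[1L], "'", call. = FALSE)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in 2:n) {
    r <- .align_many(seqs[seq_len(j - 1L)], seqs[[j]], scoring, type = "global")
    d <- 1 - r$nmatch / r$align_length
    D[seq_len(j - 1L), j] <- d
    D[j, seq_len(j - 1L)] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (exact on additive matrices). Negative branch
#' lengths, an artifact NJ can produce on non-additive input, are clamped to
#' zero; the total clamped amount is reported via `message()`.
#'
#' @param D Symmetric distance matrix with zero diagonal and >= 3 labels.
#' @return An unrooted `ape` `phylo` tree whose leaves are the matrix labels.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0)) {
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  }
  phy <- ape::nj(stats::as.dist(D))
  neg <- phy$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s), total %.3g",
                    sum(neg), -sum(phy$edge.length[neg])))
    phy$edge.length[neg] <- 0
  }
  phy
}

.CLASS_COLORS <- c(I = "#1f77b4", II = "#ff7f0e", III = "#2ca02c",
                   IV = "#9467bd", Unknown = "-")

#' Export per-leaf PhaC class annotations for tree viewers
#'
#' Writes one tab-separated row per leaf: label, class and a fixed
#' class-to-color mapping. Unclassified leaves get the uncolored sentinel
#' `-`. If a tree is supplied, labels absent from its leaves are skipped
#' with a warning.
#'
#' @param classes Named character vector label -> class, or a data.frame
#'   with `accession`/`genome_id` and `phac_class` columns.
#' @param path Output path.
#' @param tree Optional `phylo` tree to validate labels against.
#' @return The annotation data.frame, invisibly.
#' @export
export_class_annotation <- function(classes, path, tree = NULL) {
  if (is.data.frame(classes)) {
    lab <- classes[["accession"]] %||% classes[["genome_id"]]
    classes <- setNames(classes$phac_class, lab)
  }
  stopifnot(is.character(classes))
  if (length(classes) && is.null(names(classes))) {
    stop("classes must be named by leaf label", call. = FALSE)
  }
  if (!length(classes)) names(classes) <- character(0)
  if (!is.null(tree)) {
    stray <- setdiff(names(classes), tree$tip.label)
    if (length(stray)) {
      warning("label(s) absent from tree, skipped: ",
              paste(stray, collapse = ", "))
      classes <- classes[setdiff(names(classes), stray)]
    }
  }
  ann <- data.frame(label = names(classes), phac_class = unname(classes),
                    color = unname(.CLASS_COLORS[unname(classes)]),
                    stringsAsFactors = FALSE)
  ann$color[is.na(ann$color)] <- "-"
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}
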