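# Scoring model: substitution matrix, affine gap penalties and the
# Karlin-Altschul parameters used to normalize raw alignment scores.

.blosum62_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Construct the alignment scoring model
#'
#' Bundles the BLOSUM62 substitution matrix, affine gap penalties (a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`) and the Karlin-Altschul
#' parameters lambda and K used by [bitscore()] and [evalue()]. Defaults are
#' the standard gapped-BLOSUM62 protein search settings (gap open 11, extend
#' 1, lambda = 0.267, K = 0.041). Stop codons (`*`) score `stop_score`
#' against everything so that alignments are discouraged from crossing
#' in-frame stops without hard segmentation; ambiguous residues (`X`, and the
#' rare letters `U`, `O`) score `x_score` against everything.
#'
#' @param gap_open Positive integer gap-opening penalty.
#' @param gap_extend Positive integer gap-extension penalty
#'   (`gap_open >= gap_extend >= 1`).
#' @param lambda Karlin-Altschul lambda (nats per raw-score unit), > 0.
#' @param k Karlin-Altschul K, in (0, 1).
#' @param stop_score Integer score of `*` against any residue.
#' @param x_score Integer score of `X`/`U`/`O` against any residue.
#' @return A list of class `phac_scoring` with elements
#'   `substitution_matrix`, `gap_open`, `gap_extend`, `lambda`, `k`,
#'   `stop_score`, `x_score`.
#' @export
scoring_model <- function(gap_open = 11L, gap_extend = 1L,
                          lambda = 0.267, k = 0.041,
                          stop_score = -4L, x_score = -1L) {
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(lambda > 0)) stop("lambda must be > 0", call. = FALSE)
  if (!(k > 0 && k < 1)) stop("k must lie in (0, 1)", call. = FALSE)
  if (!(gap_open >= gap_extend && gap_extend >= 1L)) {
    stop("need gap_open >= gap_extend >= 1", call. = FALSE)
  }
  m <- .blosum62_base()
  add <- setdiff(c("U", "O"), rownames(m))
  if (length(add)) {
    m <- rbind(m, matrix(0L, length(add), ncol(m), dimnames = list(add, colnames(m))))
    m <- cbind(m, matrix(0L, nrow(m), length(add), dimnames = list(rownames(m), add)))
  }
  m["*", ] <- stop_score; m[, "*"] <- stop_score
  for (a in c("X", "U", "O")) { m[a, ] <- x_score; m[, a] <- x_score }
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k = k,
                 stop_score = as.integer(stop_score),
                 x_score = as.integer(x_score)),
            class = "phac_scoring")
}

#' Karlin-Altschul bitscore of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`; strictly increasing in the raw score.
#'
#' @param raw_score Nonnegative raw alignment score(s).
#' @param scoring A [scoring_model()].
#' @return Bitscore(s), in bits.
#' @export
bitscore <- function(raw_score, scoring = scoring_model()) {
  stopifnot(inherits(scoring, "phac_scoring"), all(raw_score >= 0))
  (scoring$lambda * raw_score - log(scoring$k)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' `E = m * n * 2^(-bits)` for query length `m` and effective database length
#' `n`. No edge/length correction is applied: absolute values differ from
#' BLAST's composition-corrected E-values, but ordering and threshold
#' behaviour are preserved, and the statistic is exactly testable.
#'
#' @param bits Bitscore(s).
#' @param m Query length in residues (>= 1).
#' @param n Effective database length in residues (>= 1).
#' @return Expected number of chance alignments at or above `bits`.
#' @export
evalue <- function(bits, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  m * n * 2^(-bits)
}
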