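`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reverse_complement is an involution with N passthrough", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AN"), "NT")
  set.seed(21)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T", "N"), 30, TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
  expect_error(reverse_complement("ATGU"), "invalid")
})

test_that("six-frame translation follows the standard code with stops and X", {
  tr <- translate_six_frames("ATGGCC")
  expect_equal(tr$protein[tr$frame == 1], "MA")
  tr <- translate_six_frames("ATG")
  expect_equal(tr$protein[tr$frame == -1], "H")  # rc = CAT
  # stops kept in-sequence, N codons become X
  tr <- translate_six_frames("ATGTAANGG")
  expect_equal(tr$protein[tr$frame == 1], "M*X")
  # length-5 contig: one codon in each of frames +1..+3
  tr <- translate_six_frames("ATGGC")
  expect_equal(sum(nchar(tr$protein[tr$frame > 0])), 3L)
  # frames of the reverse complement equal the negative frames
  set.seed(22)
  x <- paste(sample(c("A", "C", "G", "T"), 31, TRUE), collapse = "")
  a <- translate_six_frames(x)
  b <- translate_six_frames(reverse_complement(x))
  expect_setequal(b$protein[b$frame > 0], a$protein[a$frame < 0])
  expect_setequal(b$protein[b$frame < 0], a$protein[a$frame > 0])
})

test_that("local alignment reproduces hand-derived scores and symmetry", {
  al <- align_local("AAA", "AAA")
  expect_equal(al$raw_score, 12)   # 3 x A:A = 4
  expect_equal(al$identity_fraction, 1.0)
  expect_equal(align_local("W", "W")$raw_score, 11)  # BLOSUM62 diagonal
  expect_null(align_local("A", "W"))  # best local score not positive
  set.seed(23)
  for (i in 1:20) {
    q <- random_protein(sample(5:30, 1)); t <- random_protein(sample(5:30, 1))
    a <- align_local(q, t); b <- align_local(t, q)
    expect_equal(a$raw_score %||% 0, b$raw_score %||% 0)
  }
})

test_that("local alignment scores match the brute-force affine-gap oracle", {
  scoring <- scoring_model()
  set.seed(24)
  n_pairs <- 200
  for (i in seq_len(n_pairs)) {
    q <- random_protein(sample(3:40, 1))
    t <- random_protein(sample(3:40, 1))
    expected <- sw_oracle_score(q, t, scoring)
    got <- align_local(q, t, scoring)
    expect_equal(got$raw_score %||% 0, max(expected, 0),
                 info = sprintf("pair %d: q=%s t=%s", i, q, t))
  }
})

test_that("bitscore and E-value reproduce the closed forms", {
  expect_equal(bitscore(100), 43.13, tolerance = 0.01 / 43.13)
  expect_equal(bitscore(0), 4.61, tolerance = 0.01 / 4.61)
  expect_lt(bitscore(100), bitscore(101))
  expect_equal(evalue(10, 100, 1000), 97.65625)
  expect_equal(evalue(10, 100, 2000), 2 * evalue(10, 100, 1000))
  expect_equal(evalue(1000, 100, 1000), 0)
  # one extra bit halves E
  expect_equal(evalue(11, 100, 1000), evalue(10, 100, 1000) / 2)
})

test_that("protein-vs-protein search ranks the identical target first", {
  set.seed(25)
  q <- data.frame(accession = "q1", sequence = random_protein(120),
                  stringsAsFactors = FALSE)
  targets <- data.frame(
    accession = c("self", "r1", "r2"),
    sequence = c(q$sequence, random_protein(120), random_protein(120)),
    stringsAsFactors = FALSE)
  hits <- search_protein_vs_proteins(q, targets, evalue_cutoff = 10)
  expect_equal(hits$target[1], "self")
  # within a search, bitscore-descending implies evalue-ascending
  expect_equal(order(hits$evalue), order(-hits$bitscore))
  # cutoff 0 filters everything
  expect_equal(nrow(search_protein_vs_proteins(q, targets, evalue_cutoff = 0)), 0L)
  # E-values agree with direct recomputation from the formulas
  n_db <- sum(nchar(targets$sequence))
  al <- align_local(q$sequence, targets$sequence[1])
  expect_equal(hits$evalue[1],
               evalue(bitscore(al$raw_score), nchar(q$sequence), n_db))
})

test_that("translated genome search finds a reverse-strand exact copy", {
  set.seed(26)
  prot <- random_protein(80)
  gene <- reverse_translate(prot, seed = 26)
  bg <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  contig <- paste0(substr(bg, 1, 100), reverse_complement(gene),
                   substr(bg, 101, 600))
  genome <- data.frame(genome_id = "G1", contig_id = "c1", sequence = contig,
                       stringsAsFactors = FALSE)
  q <- data.frame(accession = "q1", sequence = prot, stringsAsFactors = FALSE)
  hits <- search_protein_vs_genome(q, genome)
  expect_gte(nrow(hits), 1L)
  best <- hits[1, ]
  expect_lt(best$frame, 0)
  expect_equal(best$pct_identity, 100)
  # the reported nucleotide span excises exactly the planted gene
  expect_equal(best$t_start, 101)
  expect_equal(best$t_end, 100 + nchar(gene))
  seg <- substr(contig, best$t_start, best$t_end)
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(reverse_complement(seg)))), prot)
  # both ends lie within the contig
  expect_true(all(hits$t_start >= 1 & hits$t_end <= nchar(contig)))
})

test_that("random genomes yield no hits at the stringent cutoff", {
  set.seed(27)
  q <- data.frame(accession = "q1", sequence = random_protein(60),
                  stringsAsFactors = FALSE)
  n_empty <- 0L
  for (i in 1:100) {
    genome <- data.frame(
      genome_id = "G1", contig_id = "c1",
      sequence = paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
      stringsAsFactors = FALSE)
    h <- search_protein_vs_genome(q, genome, evalue_cutoff = 1e-10)
    n_empty <- n_empty + (nrow(h) == 0L)
  }
  expect_gte(n_empty, 99L)
})

test_that("a 10% mutated planted gene is still the genome's best hit", {
  set.seed(28)
  refs <- generate_reference_set(seed = 28)$refs[1:3, ]
  refs$phac_class <- c("I", "I", "I")
  prot <- refs$sequence[1]
  mut <- strsplit(prot, "")[[1]]
  idx <- sample(length(mut), round(0.1 * length(mut)))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (j in idx) mut[j] <- sample(setdiff(aa, mut[j]), 1)
  gene <- reverse_translate(paste(mut, collapse = ""), seed = 29)
  bg <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  genome <- data.frame(genome_id = "G1", contig_id = "c1",
                       sequence = paste0(bg, gene), stringsAsFactors = FALSE)
  hits <- search_protein_vs_genome(refs, genome)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$query[1], refs$accession[1])
  expect_gt(hits$t_start[1], nchar(bg))
})
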