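test_that("clean reference sets match the requested composition", {
  rs <- generate_reference_set(n_per_class = c(I = 5L, II = 5L, III = 5L),
                               seed = 61)
  expect_equal(nrow(rs$refs), 15L)
  expect_true(all(rs$manifest$refs$pollution == "clean"))
  expect_equal(as.integer(table(rs$manifest$refs$true_class)[c("I", "II", "III")]),
               c(5L, 5L, 5L))
  # seed proteins are mutually dissimilar by construction (identity ~ 0)
  ids <- utils::combn(3, 2)
  for (k in seq_len(ncol(ids))) {
    d <- pairwise_distance(rs$seeds[[ids[1, k]]], rs$seeds[[ids[2, k]]])
    expect_gt(d, 0.7)
  }
  # determinism
  rs2 <- generate_reference_set(n_per_class = c(I = 5L, II = 5L, III = 5L),
                                seed = 61)
  expect_identical(rs, rs2)
  expect_error(generate_reference_set(pollution = list(putative = 1.5)),
               "\\[0, 1\\]")
})

test_that("pollution is emitted as tagged in the truth manifest", {
  rs <- generate_reference_set(pollution = list(putative = 2 / 15,
                                                fragment = 1 / 15,
                                                duplicate = 2 / 15,
                                                non_phac = 1 / 15),
                               seed = 62)
  truth <- rs$manifest$refs
  expect_equal(sum(truth$pollution == "putative_name"), 2L)
  expect_equal(sum(truth$pollution == "fragment"), 1L)
  expect_equal(sum(startsWith(truth$pollution, "duplicate_of:")), 2L)
  expect_equal(sum(truth$pollution == "non_phac"), 1L)
  # curation removes exactly the polluted records (duplicates come after
  # their source, so keep-first dedup removes the copies)
  res <- curate_references(rs$refs, taxon_domain = "bacteria")
  expect_equal(sum(res$removed$reason == "duplicate"), 2L)
  expect_equal(sum(res$removed$reason == "putative"), 2L)
  expect_equal(sum(res$removed$reason == "fragment_length"), 1L)
  expect_setequal(
    res$removed$accession[res$removed$reason == "duplicate"],
    truth$accession[startsWith(truth$pollution, "duplicate_of:")])
})

test_that("reverse_translate inverts translation and is seeded", {
  expect_equal(reverse_translate("M"), "ATG")
  set.seed(63)
  for (i in 1:10) {
    p <- random_protein(sample(5:40, 1))
    dna <- reverse_translate(p, seed = i)
    expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(dna), no.init.codon = TRUE)),
                 p)
  }
  expect_identical(reverse_translate("MKVLW", seed = 9),
                   reverse_translate("MKVLW", seed = 9))
  expect_error(reverse_translate("MK*V"), "\\*")
})

test_that("generated genomes carry planted genes exactly where stated", {
  rs <- generate_reference_set(seed = 64)
  refs <- merge(rs$refs, rs$manifest$refs, by = "accession", sort = FALSE)
  refs$phac_class <- refs$true_class
  gg <- generate_genomes(refs, n_genomes = 10L, positive_fraction = 0.7,
                         background_length = 2000L, seed = 64)
  man <- gg$manifest
  expect_equal(sum(man$planted), 7L)
  expect_equal(sum(!man$planted), 3L)
  for (i in which(man$planted)) {
    contig <- gg$genomes$sequence[gg$genomes$genome_id == man$genome_id[i]]
    expect_gte(man$start[i], 1L)
    expect_lte(man$end[i], nchar(contig))
    seg <- substr(contig, man$start[i], man$end[i])
    if (man$strand[i] == -1L) seg <- reverse_complement(seg)
    expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(seg), no.init.codon = TRUE)),
                 man$mutated_protein[i])
  }
  gg2 <- generate_genomes(refs, n_genomes = 10L, positive_fraction = 0.7,
                          background_length = 2000L, seed = 64)
  expect_identical(gg, gg2)
  expect_error(generate_genomes(refs, planting_spec = "NOPE",
                                background_length = 2000L), "NOPE")
  expect_error(generate_genomes(refs, background_length = 100L), "background")
})

test_that("gold metadata sampling follows the profile", {
  prof <- data.frame(ecosystem = "Environmental",
                     ecosystem_category = "Aquatic",
                     ecosystem_type = "Marine",
                     ecosystem_subtype = "Hydrothermal vents",
                     habitat = "vent fluid", prob = 1,
                     stringsAsFactors = FALSE)
  gold <- generate_gold_metadata(sprintf("G%03d", 1:20), prof, seed = 65)
  expect_equal(nrow(gold), 20L)
  expect_true(all(gold$ecosystem_subtype == "Hydrothermal vents"))
  rows <- cbind(gold, query_accession = "Q", phac_class = "I",
                stringsAsFactors = FALSE)
  expect_true(all(flag_extreme(filter_environmental(rows))$rows$extreme))

  # 60/40 soil/marine split stays within binomial 99% bounds at n = 1000
  prof2 <- rbind(prof, prof)
  prof2$ecosystem_type <- c("Marine", "Soil")
  prof2$ecosystem_category <- c("Aquatic", "Terrestrial")
  prof2$prob <- c(0.4, 0.6)
  gold2 <- generate_gold_metadata(sprintf("G%04d", 1:1000), prof2, seed = 66)
  n_soil <- sum(gold2$ecosystem_type == "Soil")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.6)
  expect_gte(n_soil, bounds[1]); expect_lte(n_soil, bounds[2])

  prof$prob <- 0.9
  expect_error(generate_gold_metadata("G1", prof), "sum to 1")
  # readers accept generator output
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(gold, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_metadata_table(f, "gold")), 20L)
})

test_that("generator FASTA/TSV outputs are valid reader inputs", {
  sim <- simulate_study(n_genomes = 4L, seed = 67,
                        background_length = 1500L)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$refs, fa)
  expect_equal(read_fasta(fa, "protein")$sequence, sim$refs$sequence)
  ga <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(accession = sim$genomes$genome_id,
                         sequence = sim$genomes$sequence), ga)
  expect_equal(nrow(read_fasta(ga, "nucleotide")), 4L)
  meta <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sim$refs[, c("accession", "protein_name", "tigrfam_ids",
                                  "taxon_domain")],
                     meta, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_metadata_table(meta, "reference")), nrow(sim$refs))
})
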