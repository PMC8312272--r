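# Synthetic-data generator: reference sets with controlled pollution,
# genomes with planted PhaC genes on either strand, and GOLD-style ecosystem
# metadata -- all with a truth manifest, so the pipeline is testable offline.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# disjoint residue alphabets make the three class seeds pairwise ~0% identical;
# alphabets are chosen with comparable mean BLOSUM62 diagonal scores (~5-6 per
# residue) so alignment scores are comparable across classes and an exact copy
# always outscores a heavily mutated copy of another class
.CLASS_ALPHABETS <- list(
  I = c("A", "E", "K", "L", "D", "G"),
  II = c("S", "T", "P", "R", "Q", "V"),
  III = c("F", "Y", "N", "I", "M", "H"))

.rand_protein <- function(len, alphabet = .AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(p, rate) {
  if (rate <= 0) return(p)
  v <- strsplit(p, "")[[1L]]
  hit <- which(stats::rbinom(length(v), 1L, rate) == 1L)
  for (i in hit) v[i] <- sample(setdiff(.AA20, v[i]), 1L)
  paste(v, collapse = "")
}

#' Generate a synthetic PhaC reference set with known pollution
#'
#' Three divergent 400-residue seed proteins (one per class I/II/III, built
#' from disjoint residue alphabets so pairwise identity is far below 30%)
#' are mutated at `divergence` per site to produce within-class families.
#' Pollution is then added at the stated rates (fractions of the clean set):
#' `putative` (clean sequences renamed "Putative ..."), `fragment`
#' (truncated below the domain's length threshold), `duplicate` (exact
#' copies under new accessions, emitted after their source so keep-first
#' deduplication removes them) and `non_phac` (decoy sequences with
#' depolymerase/phasin/regulator names). The class is recorded in the
#' protein name for `name_frac` of clean references, in the TIGRFAM field
#' for the next `tigrfam_frac`, and omitted (class transfer's job) for the
#' rest.
#'
#' @param n_per_class Named integer vector of clean references per class.
#' @param pollution Named list/vector of rates in `[0, 1]`: `putative`,
#'   `fragment`, `duplicate`, `non_phac`.
#' @param name_frac,tigrfam_frac Fractions of clean references labeled via
#'   the protein name / the TIGRFAM field.
#' @param divergence Per-site amino-acid substitution rate within a class.
#' @param seed_length Seed protein length (residues).
#' @param taxon_domain `"bacteria"` or `"archaea"`.
#' @param seed Integer RNG seed.
#' @return A list: `refs` (columns `accession`, `sequence`, `length`,
#'   `protein_name`, `tigrfam_ids`, `taxon_domain`), `seeds` (the three seed
#'   proteins) and `manifest` (per-reference `true_class` and pollution tag,
#'   plus generator parameters).
#' @export
generate_reference_set <- function(n_per_class = c(I = 5L, II = 5L, III = 5L),
                                   pollution = list(putative = 0, fragment = 0,
                                                    duplicate = 0, non_phac = 0),
                                   name_frac = 0.6, tigrfam_frac = 0.2,
                                   divergence = 0.10, seed_length = 400L,
                                   taxon_domain = c("bacteria", "archaea"),
                                   seed = 1L) {
  taxon_domain <- match.arg(taxon_domain)
  rates <- unlist(pollution)
  if (any(rates < 0 | rates > 1)) {
    stop("pollution rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(n_per_class >= 1L),
            all(names(n_per_class) %in% c("I", "II", "III")))
  set.seed(seed)
  seeds <- lapply(.CLASS_ALPHABETS[names(n_per_class)], function(a)
    .rand_protein(seed_length, a))
  tig_of <- c(I = "TIGR01838", II = "TIGR01839", III = "TIGR01836")
  acc_i <- 0L
  next_acc <- function() { acc_i <<- acc_i + 1L; sprintf("REF%03d", acc_i) }
  rows <- list(); truth <- list()
  add <- function(acc, sequence, name, tigrfam, class, tag) {
    rows[[length(rows) + 1L]] <<- data.frame(
      accession = acc, sequence = sequence, length = nchar(sequence),
      protein_name = name, tigrfam_ids = tigrfam, taxon_domain = taxon_domain,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      accession = acc, true_class = class, pollution = tag,
      stringsAsFactors = FALSE)
  }
  for (cl in names(n_per_class)) {
    n <- n_per_class[[cl]]
    n_name <- round(name_frac * n)
    n_tig <- min(n - n_name, round(tigrfam_frac * n))
    for (j in seq_len(n)) {
      p <- .mutate_protein(seeds[[cl]], divergence)
      if (j <= n_name) {
        add(next_acc(), p,
            sprintf("Polyhydroxyalkanoate synthase, class %s", cl), "", cl, "clean")
      } else if (j <= n_name + n_tig) {
        add(next_acc(), p, "PHA synthase", tig_of[[cl]], cl, "clean")
      } else {
        add(next_acc(), p, "PHA synthase", "", cl, "clean")
      }
    }
  }
  clean <- do.call(rbind, rows)
  n_clean <- nrow(clean)
  counts <- vapply(c("putative", "fragment", "duplicate", "non_phac"),
                   function(k) as.integer(round((rates[k] %||% 0) * n_clean)),
                   0L)
  truth_df <- do.call(rbind, truth)
  class_of <- setNames(truth_df$true_class, truth_df$accession)
  for (i in seq_len(counts[["putative"]])) {
    src <- clean[sample(n_clean, 1L), ]
    add(next_acc(), .mutate_protein(src$sequence, divergence),
        "Putative polyhydroxyalkanoate synthase", "",
        class_of[[src$accession]], "putative_name")
  }
  frag_len <- if (taxon_domain == "bacteria") 150L else 60L
  for (i in seq_len(counts[["fragment"]])) {
    src <- clean[sample(n_clean, 1L), ]
    add(next_acc(), substr(src$sequence, 1L, frag_len),
        "PHA synthase", "", class_of[[src$accession]], "fragment")
  }
  for (i in seq_len(counts[["duplicate"]])) {
    src <- clean[sample(n_clean, 1L), ]
    add(next_acc(), src$sequence, src$protein_name, src$tigrfam_ids,
        class_of[[src$accession]], paste0("duplicate_of:", src$accession))
  }
  decoy_names <- c("PHA depolymerase", "Phasin", "Transcriptional regulator PhaR")
  for (i in seq_len(counts[["non_phac"]])) {
    add(next_acc(), .rand_protein(seed_length), sample(decoy_names, 1L), "",
        "Unknown", "non_phac")
  }
  refs <- do.call(rbind, rows)
  rownames(refs) <- NULL
  manifest <- list(refs = do.call(rbind, truth),
                   params = list(n_per_class = n_per_class, pollution = rates,
                                 name_frac = name_frac,
                                 tigrfam_frac = tigrfam_frac,
                                 divergence = divergence,
                                 seed_length = seed_length,
                                 taxon_domain = taxon_domain),
                   seed = seed)
  rownames(manifest$refs) <- NULL
  list(refs = refs, seeds = seeds, manifest = manifest)
}

#' Reverse-translate a protein into DNA
#'
#' Each residue is encoded by a codon drawn uniformly among its synonymous
#' codons (standard genetic code) with the seeded generator, so
#' translating the result in frame +1 recovers the input exactly.
#'
#' @param protein Amino-acid string without `*`.
#' @param seed Integer RNG seed.
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  .assert_scalar_string(protein, "protein")
  if (grepl("*", protein, fixed = TRUE)) {
    stop("protein must not contain '*'", call. = FALSE)
  }
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  v <- strsplit(toupper(protein), "")[[1L]]
  unknown <- setdiff(v, names(by_aa))
  if (length(unknown)) {
    stop("no codon for residue '", unknown[1L], "'", call. = FALSE)
  }
  set.seed(seed)
  paste(vapply(v, function(a) {
    cods <- by_aa[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

#' Generate synthetic genomes with planted PhaC genes
#'
#' Each genome is a single contig of i.i.d. uniform nucleotides of length
#' `background_length`. A fraction `positive_fraction` of genomes receive a
#' planted gene: a reference protein is drawn (uniformly, or per
#' `planting_spec`), mutated at `mutation_rate` per residue,
#' reverse-translated and written over a random window on a random strand.
#' The manifest records, per genome, the planted query, its true class, the
#' 1-based nucleotide span, the strand and the mutated protein; negative
#' genomes are plain random sequence.
#'
#' @param refs Classified reference table (`accession`, `sequence`,
#'   `phac_class`).
#' @param n_genomes Number of genomes.
#' @param positive_fraction Fraction of genomes that carry a planted gene.
#' @param mutation_rate Per-residue amino-acid substitution rate of planted
#'   genes.
#' @param background_length Genome length in nucleotides (must exceed the
#'   longest planted gene by at least 2).
#' @param planting_spec Optional character vector of reference accessions to
#'   plant, one per positive genome (recycled); unknown accessions error.
#' @param seed Integer RNG seed.
#' @return A list: `genomes` (columns `genome_id`, `contig_id`, `sequence`)
#'   and `manifest` (data.frame with one row per genome plus parameters as
#'   attributes).
#' @export
generate_genomes <- function(refs, n_genomes = 50L, positive_fraction = 0.8,
                             mutation_rate = 0.05, background_length = 3000L,
                             planting_spec = NULL, seed = 1L) {
  stopifnot(is.data.frame(refs),
            all(c("accession", "sequence", "phac_class") %in% names(refs)))
  if (!is.null(planting_spec)) {
    bad <- setdiff(planting_spec, refs$accession)
    if (length(bad)) {
      stop("planting_spec names unknown reference '", bad[1L], "'",
           call. = FALSE)
    }
  }
  max_gene <- 3L * max(nchar(refs$sequence))
  if (background_length < max_gene + 2L) {
    stop("background_length must be >= planted gene length + 2", call. = FALSE)
  }
  set.seed(seed)
  n_pos <- round(positive_fraction * n_genomes)
  planted_acc <- if (is.null(planting_spec)) {
    sample(refs$accession, n_pos, replace = TRUE)
  } else {
    rep_len(planting_spec, n_pos)
  }
  class_of <- setNames(refs$phac_class, refs$accession)
  seq_of <- setNames(refs$sequence, refs$accession)
  genomes <- vector("list", n_genomes); man <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    gid <- sprintf("G%03d", i)
    bg <- paste(sample(c("A", "C", "G", "T"), background_length,
                       replace = TRUE), collapse = "")
    if (i <= n_pos) {
      acc <- planted_acc[i]
      prot <- .mutate_protein(seq_of[[acc]], mutation_rate)
      gene <- reverse_translate(prot, seed = sample.int(2^31 - 1L, 1L))
      glen <- nchar(gene)
      strand <- sample(c(1L, -1L), 1L)
      ins <- if (strand == 1L) gene else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
      start <- sample.int(background_length - glen + 1L, 1L)
      contig <- paste0(substr(bg, 1L, start - 1L), ins,
                       substr(bg, start + glen, background_length))
      man[[i]] <- data.frame(genome_id = gid, planted = TRUE,
                             query_accession = acc,
                             true_class = unname(class_of[acc]),
                             contig_id = "c1", start = start,
                             end = start + glen - 1L, strand = strand,
                             mutated_protein = prot, stringsAsFactors = FALSE)
    } else {
      contig <- bg
      man[[i]] <- data.frame(genome_id = gid, planted = FALSE,
                             query_accession = NA_character_,
                             true_class = NA_character_, contig_id = "c1",
                             start = NA_integer_, end = NA_integer_,
                             strand = NA_integer_,
                             mutated_protein = NA_character_,
                             stringsAsFactors = FALSE)
    }
    genomes[[i]] <- data.frame(genome_id = gid, contig_id = "c1",
                               sequence = contig, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  attr(manifest, "params") <- list(n_genomes = n_genomes,
                                   positive_fraction = positive_fraction,
                                   mutation_rate = mutation_rate,
                                   background_length = background_length,
                                   seed = seed)
  list(genomes = do.call(rbind, genomes), manifest = manifest)
}

#' Default GOLD ecosystem sampling profile
#'
#' A categorical distribution over (ecosystem, category, type, subtype,
#' habitat) tuples spanning the GOLD vocabulary used in the tabulations:
#' common Freshwater/Marine/Soil settings, the extreme descriptors
#' (hydrothermal vents, saline-alkaline lakes, thermal springs, desert and
#' permafrost soils, salt mines, halite pinnacles), plus host-associated,
#' engineered and `unclassified` mass that the environmental filter must
#' drop.
#'
#' @return Data.frame with the five GOLD path columns and a `prob` column
#'   summing to 1.
#' @export
default_ecosystem_profile <- function() {
  rows <- list(
    c("Environmental", "Aquatic", "Freshwater", "Lake", "lake water", 0.18),
    c("Environmental", "Aquatic", "Marine", "Oceanic", "sea water", 0.13),
    c("Environmental", "Aquatic", "Marine", "Hydrothermal vents",
      "black smoker biofilm", 0.03),
    c("Environmental", "Aquatic", "Non-marine saline and alkaline",
      "Saline lake", "soda lake water", 0.05),
    c("Environmental", "Aquatic", "Thermal springs", "Hot spring",
      "hot spring sediment", 0.04),
    c("Environmental", "Aquatic", "Sediment", "Freshwater sediment",
      "river sediment", 0.03),
    c("Environmental", "Terrestrial", "Soil", "Loam", "cropland soil", 0.20),
    c("Environmental", "Terrestrial", "Soil", "Desert", "Desert soil", 0.03),
    c("Environmental", "Terrestrial", "Soil", "Permafrost",
      "Permafrost sediment", 0.02),
    c("Environmental", "Terrestrial", "Geologic", "Salt mine",
      "salt mine brine", 0.02),
    c("Environmental", "Terrestrial", "Rock-dwelling", "Halite pinnacle",
      "halite nodule", 0.01),
    c("Environmental", "Terrestrial", "Oil reservoir", "unclassified",
      "oil well", 0.01),
    c("Host-associated", "Plants", "Rhizosphere", "unclassified",
      "root zone", 0.12),
    c("Engineered", "Bioreactor", "Aerobic", "unclassified",
      "activated sludge", 0.05),
    c("Environmental", "Aquatic", "unclassified", "unclassified",
      "unclassified", 0.04),
    c("unclassified", "unclassified", "unclassified", "unclassified",
      "unclassified", 0.04))
  m <- do.call(rbind, rows)
  data.frame(ecosystem = m[, 1L], ecosystem_category = m[, 2L],
             ecosystem_type = m[, 3L], ecosystem_subtype = m[, 4L],
             habitat = m[, 5L], prob = as.numeric(m[, 6L]),
             stringsAsFactors = FALSE)
}

#' Generate GOLD-style metadata for a set of genomes
#'
#' Samples one (ecosystem, category, type, subtype, habitat) tuple per
#' genome from a categorical profile, plus a phylum from `phylum_probs`.
#'
#' @param genome_ids Character vector of genome identifiers.
#' @param profile Profile data.frame ([default_ecosystem_profile()]); its
#'   `prob` column must sum to 1 (within 1e-9).
#' @param domain Taxonomic domain label for all rows.
#' @param phylum_probs Named probability vector over phylum labels.
#' @param seed Integer RNG seed.
#' @return A GOLD metadata data.frame (the `"gold"` schema of
#'   [read_metadata_table()]).
#' @export
generate_gold_metadata <- function(genome_ids,
                                   profile = default_ecosystem_profile(),
                                   domain = "Bacteria",
                                   phylum_probs = c(Proteobacteria = 0.55,
                                                    Actinobacteria = 0.25,
                                                    Firmicutes = 0.15,
                                                    Bacteroidetes = 0.05),
                                   seed = 1L) {
  stopifnot(is.character(genome_ids), is.data.frame(profile),
            "prob" %in% names(profile))
  if (abs(sum(profile$prob) - 1) > 1e-9) {
    stop("profile probabilities must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(nrow(profile), length(genome_ids), replace = TRUE,
                    prob = profile$prob)
  phy <- sample(names(phylum_probs), length(genome_ids), replace = TRUE,
                prob = phylum_probs)
  out <- data.frame(genome_id = genome_ids, domain = domain, phylum = phy,
                    profile[idx, c("ecosystem", "ecosystem_category",
                                   "ecosystem_type", "ecosystem_subtype",
                                   "habitat")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic study fixture
#'
#' Convenience wrapper producing everything [run_pipeline()] needs: a
#' polluted reference set, genomes with planted genes and GOLD metadata,
#' with one truth manifest. Defaults are the package's standard study
#' conditions: 5 clean references per class with one putative, one fragment
#' and one duplicate added; 50 genomes of 3,000 nt, 80% genotype-positive,
#' planted genes mutated at 5% per residue.
#'
#' @param n_per_class Clean references per class.
#' @param pollution Pollution rates (see [generate_reference_set()]).
#' @param n_genomes,positive_fraction,mutation_rate,background_length
#'   Genome-set parameters (see [generate_genomes()]).
#' @param seed Integer RNG seed; sub-seeds for the three generators are
#'   derived from it.
#' @return A list: `refs`, `ref_manifest`, `genomes`, `genome_manifest`,
#'   `gold`, `seed`.
#' @export
simulate_study <- function(n_per_class = c(I = 5L, II = 5L, III = 5L),
                           pollution = list(putative = 1 / 15, fragment = 1 / 15,
                                            duplicate = 1 / 15, non_phac = 0),
                           n_genomes = 50L, positive_fraction = 0.8,
                           mutation_rate = 0.05, background_length = 3000L,
                           seed = 1L) {
  rs <- generate_reference_set(n_per_class = n_per_class,
                               pollution = pollution, seed = seed)
  truth <- rs$manifest$refs
  clean <- merge(rs$refs, truth[truth$pollution == "clean", ],
                 by = "accession", sort = FALSE)
  clean$phac_class <- clean$true_class
  gg <- generate_genomes(clean, n_genomes = n_genomes,
                         positive_fraction = positive_fraction,
                         mutation_rate = mutation_rate,
                         background_length = background_length,
                         seed = seed + 1L)
  gold <- generate_gold_metadata(unique(gg$genomes$genome_id),
                                 seed = seed + 2L)
  list(refs = rs$refs, ref_manifest = rs$manifest, genomes = gg$genomes,
       genome_manifest = gg$manifest, gold = gold, seed = seed)
}
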