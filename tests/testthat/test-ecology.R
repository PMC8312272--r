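gold_row <- function(eco = "Environmental", cat = "Aquatic", type = "Marine",
                     sub = "Oceanic", hab = "sea water", class = "I",
                     phylum = "Proteobacteria") {
  data.frame(genome_id = "G", domain = "Bacteria", phylum = phylum,
             ecosystem = eco, ecosystem_category = cat, ecosystem_type = type,
             ecosystem_subtype = sub, habitat = hab,
             query_accession = "Q", phac_class = class,
             stringsAsFactors = FALSE)
}

test_that("environmental filter needs Environmental + Aquatic/Terrestrial", {
  rows <- rbind(
    gold_row(),                                             # kept
    gold_row(cat = "Terrestrial", type = "Soil"),           # kept
    gold_row(eco = "Host-associated", cat = "Plants"),      # dropped
    gold_row(eco = "Engineered", cat = "Bioreactor"),       # dropped
    gold_row(type = "unclassified"),                        # dropped
    gold_row(eco = "unclassified", cat = "unclassified"))   # dropped
  kept <- filter_environmental(rows)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$ecosystem_type, c("Marine", "Soil"))
})

test_that("relative_abundance rounds half-up in exact arithmetic", {
  expect_equal(relative_abundance(4119, 16576), 24.8)
  expect_equal(relative_abundance(66, 765), 8.6)
  expect_equal(relative_abundance(0, 7), 0.0)
  expect_equal(relative_abundance(56, 204), 27.5)   # 27.45098 rounds up
  expect_equal(relative_abundance(1, 8), 12.5)      # exact .5 rounds up
  expect_equal(relative_abundance(7, 7), 100.0)
  expect_error(relative_abundance(1, 0), "total")
  expect_error(relative_abundance(5, 4))
  expect_error(relative_abundance(1.5, 4))
})

test_that("tabulation groups, orders and normalizes within classes", {
  rows <- rbind(
    do.call(rbind, replicate(5, gold_row(cat = "Terrestrial", type = "Soil"),
                             simplify = FALSE)),
    do.call(rbind, replicate(3, gold_row(type = "Marine"), simplify = FALSE)),
    do.call(rbind, replicate(2, gold_row(type = "Freshwater"),
                             simplify = FALSE)))
  tab <- tabulate_genotypes(rows, "class_ecosystem_type")
  expect_equal(tab$ecosystem_type, c("Soil", "Marine", "Freshwater"))
  expect_equal(tab$relative_abundance_pct, c(50.0, 30.0, 20.0))
  expect_equal(sum(tab$count), 10L)
  one <- tabulate_genotypes(rows[1, ], "class_ecosystem_type")
  expect_equal(one$relative_abundance_pct, 100.0)
  # permutation invariance
  set.seed(41)
  tab2 <- tabulate_genotypes(rows[sample(nrow(rows)), ], "class_ecosystem_type")
  expect_equal(tab2, tab)
  # per-class percentages sum to ~100
  rows2 <- rbind(rows, gold_row(class = "III", type = "Soil",
                                cat = "Terrestrial"))
  tab3 <- tabulate_genotypes(rows2, "class_ecosystem_type")
  sums <- tapply(tab3$relative_abundance_pct, tab3$phac_class, sum)
  expect_true(all(abs(sums - 100) <= 0.3))
  # empty input
  expect_equal(nrow(tabulate_genotypes(rows[0, ], "class")), 0L)
})

test_that("every default extreme descriptor row flags, plain rows do not", {
  extremes <- rbind(
    gold_row(type = "Marine", sub = "Hydrothermal vents", hab = "vent fluid"),
    gold_row(type = "Marine", sub = "Deep oceanic",
             hab = "basalt-hosted subsurface hydrothermal fluid"),
    gold_row(type = "Marine", sub = "Deep-sea", hab = "sediment"),
    gold_row(type = "Non-marine saline and alkaline", sub = "Saline lake"),
    gold_row(type = "Thermal springs", sub = "Hot spring"),
    gold_row(cat = "Terrestrial", type = "Geologic", sub = "Acid Mine"),
    gold_row(cat = "Terrestrial", type = "Geologic",
             sub = "Saline water, Salt, and Salt mine"),
    gold_row(cat = "Terrestrial", type = "Oil reservoir", sub = "unclassified"),
    gold_row(cat = "Terrestrial", type = "Mud volcano", sub = "unclassified"),
    gold_row(cat = "Terrestrial", type = "Rock-dwelling",
             sub = "Halite pinnacle"),
    gold_row(cat = "Terrestrial", type = "Soil", hab = "Creosote-contaminated soil"),
    gold_row(cat = "Terrestrial", type = "Soil", hab = "Desert soil"),
    gold_row(cat = "Terrestrial", type = "Soil", hab = "Permafrost sediment"),
    gold_row(cat = "Terrestrial", type = "Soil", hab = "Saline soil"))
  plain <- rbind(
    gold_row(type = "Freshwater", sub = "Lake", hab = "lake water"),
    gold_row(cat = "Terrestrial", type = "Soil", sub = "Loam", hab = "cropland"),
    gold_row(type = "Marine", sub = "Oceanic", hab = "sea water"))
  res <- flag_extreme(rbind(extremes, plain))
  expect_equal(res$rows$extreme,
               c(rep(TRUE, nrow(extremes)), rep(FALSE, nrow(plain))))
  # flagged + unflagged partition the input per class
  expect_equal(res$subtotals$count + sum(!res$rows$extreme),
               res$subtotals$total)
  expect_equal(res$subtotals$relative_abundance_pct,
               relative_abundance(res$subtotals$count, res$subtotals$total))
})

test_that("report_distribution writes tables matching in-memory results", {
  rows <- rbind(gold_row(), gold_row(type = "Thermal springs"),
                gold_row(class = "III", cat = "Terrestrial", type = "Soil"))
  out <- withr::local_tempdir()
  paths <- report_distribution(rows, out)
  tab <- utils::read.delim(paths[["class_ecosystem"]])
  expect_equal(nrow(tab), 3L)
  mem <- tabulate_genotypes(rows, "class_ecosystem_type")
  expect_equal(tab$count, mem$count)
  expect_equal(tab$relative_abundance_pct, mem$relative_abundance_pct)
  sub <- utils::read.delim(paths[["extreme"]])
  expect_equal(sub$count[sub$phac_class == "I"], 1L)  # the thermal spring
  # empty input -> header-only files
  paths0 <- report_distribution(rows[0, ], withr::local_tempdir())
  expect_equal(nrow(utils::read.delim(paths0[["class_ecosystem"]])), 0L)
})
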