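test_that("G-tract and loop annotation finds maximal runs and gaps", {
  ht <- find_g_tracts("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(ht$tracts$start, c(1, 7, 13, 19))
  expect_equal(ht$tracts$end, c(3, 9, 15, 21))
  expect_equal(ht$loops$start, c(4, 10, 16))
  expect_equal(ht$loops$end, c(6, 12, 18))

  kit <- find_g_tracts("AGGGAGGGCGCTGGGAGGAGGGGC")
  expect_equal(kit$tracts$start, c(2, 6, 13, 20))
  expect_equal(kit$tracts$end, c(4, 8, 15, 23))

  none <- find_g_tracts("ATATAT")
  expect_equal(nrow(none$tracts), 0)
  expect_equal(nrow(none$loops), 0)

  expect_error(find_g_tracts("GGGNTT"), class = "g4_error_alphabet")
})

test_that("reverse complement matches an independent oracle and is an involution", {
  expect_equal(reverse_complement("GGGTTAGGGTTAGGGTTAGGG"),
               "CCCTAACCCTAACCCTAACCC")
  expect_equal(reverse_complement("A"), "T")
  expect_error(reverse_complement("ACGU"), class = "g4_error_alphabet")
  for (seed in 1:25) {
    s <- random_dna(sample(1:60, 1), seed = seed)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("probe-to-target mapping finds the minimal-mismatch antiparallel footprint", {
  ht <- g4_targets()$hTelo
  m <- map_probe_to_target("CCCTAACCCTAACCCTAACCC", ht)
  expect_equal(m$footprint, c(1, 21))
  expect_equal(m$mismatches, 0)
  expect_equal(m$pairing, 22 - seq_len(21))

  kit_dna1 <- "TCCCTCCTCCCAGCGCCCTCCC"
  expect_equal(map_probe_to_target(kit_dna1, "GGGAGGGCGCTGGGAGGAGGGA")$mismatches, 0)
  # on the 24-nt FRET construct the best footprint carries one mismatch
  expect_equal(map_probe_to_target(kit_dna1, g4_targets()$cKIT1_fret)$mismatches, 1)

  expect_error(map_probe_to_target("TTTTTTTTTT", "ACACACACACAC"),
               class = "g4_error_footprint")
})

test_that("strategy engine reproduces the published designs exactly (golden file)", {
  built <- g4_probe_catalog()
  ref <- read_lna_fasta(system.file("extdata", "probes.fa", package = "g4invader"))
  expect_setequal(built$name, ref$name)
  merged <- dplyr::inner_join(built, ref, by = "name", suffix = c("_built", "_ref"))
  expect_equal(nrow(merged), nrow(ref))
  expect_equal(merged$lna_built, merged$lna_ref)
  expect_equal(merged$bases_built, merged$bases_ref)
})

test_that("full-length designs carry n_lna modifications and are perfectly complementary", {
  cat_tbl <- g4_probe_catalog()
  full_lna <- cat_tbl[grepl("LNA\\d$", cat_tbl$name), ]
  expect_true(all(full_lna$n_lna == 4))
  shorts <- cat_tbl[grepl("_short2?$", cat_tbl$name), ]
  expect_true(all(shorts$length_nt == 10))

  tg <- g4_targets()
  for (p in g4_probe_catalog(as_tibble = FALSE)) {
    m <- map_probe_to_target(p, tg[[p$target_id]])
    expect_equal(m$mismatches, 0)
  }
})

test_that("specific placements land where the rules say", {
  tg <- g4_targets()
  kit3 <- design_full_probe(tg$cKIT1, strategy = "MIDDLE_G")
  expect_equal(kit3$bases, "TCCCTCCTCCCAGCGCCCTCCC")
  expect_equal(kit3$lna_mask, c(3, 10, 17, 21))

  h1 <- design_full_probe(tg$hTelo, strategy = "TRACT_3P")
  expect_equal(h1$bases, "CCCTAACCCTAACCCTAACCC")
  expect_equal(h1$lna_mask, 1:4)

  dna <- design_full_probe(tg$hTelo, strategy = "UNMODIFIED")
  expect_length(dna$lna_mask, 0)

  # infeasible: MIDDLE_G wants 4 tracts but the footprint holds fewer
  expect_error(design_full_probe(tg$hTelo, footprint = c(1, 9),
                                 strategy = "MIDDLE_G"),
               class = "g4_error_strategy")
})

test_that("truncation keeps the 5' end, drops distal LNAs, never adds LNAs", {
  pr <- g4_probe_catalog(as_tibble = FALSE)
  sh <- truncate_probe(pr$KIT_LNA2, 10)
  expect_equal(sh$bases, "TCCCTCCTCC")
  expect_equal(sh$lna_mask, 2:5)
  expect_equal(sh$footprint, c(13, 22))

  hsh <- truncate_probe(pr$hTelo_LNA1, 10)
  expect_equal(hsh$bases, "CCCTAACCCT")
  expect_equal(hsh$lna_mask, 1:4)

  expect_identical(truncate_probe(pr$KIT_LNA3, 22), pr$KIT_LNA3)
  for (p in pr) {
    expect_lte(length(truncate_probe(p, 10)$lna_mask), length(p$lna_mask))
  }
})

test_that("position annotation classifies tetrad/loop contacts correctly", {
  pr <- g4_probe_catalog(as_tibble = FALSE)
  tg <- g4_targets()

  a3 <- annotate_probe_positions(pr$KIT_LNA3, tg$cKIT1)
  expect_true(all(a3$category[a3$lna] == "TETRAD_G_MIDDLE"))

  a4 <- annotate_probe_positions(pr$KIT_LNA4, tg$cKIT1)
  expect_true(all(a4$category[a4$lna] == "LOOP"))

  a1 <- annotate_probe_positions(pr$hTelo_LNA1, tg$hTelo)
  cats <- a1$category[a1$lna]
  expect_equal(sum(cats %in% c("TETRAD_G", "TETRAD_G_MIDDLE")), 3)
  expect_equal(sum(cats == "LOOP"), 1)

  broken <- pr$KIT_LNA3
  broken$pairing[1] <- 99L
  expect_error(annotate_probe_positions(broken, tg$cKIT1),
               class = "g4_error_footprint")
})

test_that("kinetic-class prediction follows the placement rules", {
  pr <- g4_probe_catalog(as_tibble = FALSE)
  tg <- g4_targets()
  klass <- function(nm) predict_kinetic_class(
    annotate_probe_positions(pr[[nm]], tg[[pr[[nm]]$target_id]]))
  expect_equal(klass("KIT_LNA3"), "ACCELERATING")
  expect_equal(klass("KIT_LNA4"), "DECELERATING")
  expect_equal(klass("KIT_LNA1"), "NEUTRAL")
  expect_equal(klass("KIT_LNA2"), "ACCELERATING")
  expect_equal(klass("hTelo_LNA1"), "ACCELERATING")

  empty <- annotate_probe_positions(pr$KIT_DNA1, tg$cKIT1)
  expect_error(predict_kinetic_class(empty), class = "g4_error_strategy")
})
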