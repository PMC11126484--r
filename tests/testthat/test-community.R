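test_that("relative abundance pools counts within the group", {
  one <- zotu_table(matrix(10, 1, 1, dimnames = list("Zotu1", "s1")),
                    samples = data.frame(sample = "s1"),
                    taxonomy = data.frame(zotu = "Zotu1", clade = "x"))
  expect_equal(unname(relative_abundance(one, "s1")), 1)

  m <- matrix(c(25, 75), 2, 1, dimnames = list(c("Zotu1", "Zotu2"), "s1"))
  two <- zotu_table(m, data.frame(sample = "s1"),
                    data.frame(zotu = c("Zotu1", "Zotu2"), clade = c("x", "y")))
  expect_equal(unname(relative_abundance(two, "s1")), c(0.25, 0.75))

  # duplicating every sample leaves proportions unchanged
  tab <- toy_zotu_table()
  expect_equal(relative_abundance(tab, c("HF_1", "HF_2")),
               relative_abundance(tab, c("HF_1", "HF_2", "HF_1", "HF_2")))
  expect_error(relative_abundance(tab, character(0)), "empty")
})

test_that("clade composition reproduces constructed AOA clade percentages", {
  pct <- c("NS-Alpha" = 38.4, "NS-Gamma" = 57.8, "NS-Zeta" = 3.6,
           "NT-Alpha" = 0.2, "NS-Beta" = 0.04, "NS-Delta" = 0.01)
  counts <- matrix(round(pct * 1000), ncol = 1,
                   dimnames = list(paste0("Zotu", 1:6), "HF"))
  tab <- zotu_table(counts, data.frame(sample = "HF"),
                    data.frame(zotu = paste0("Zotu", 1:6),
                               clade = names(pct)))
  comp <- clade_composition(tab, "HF")
  expect_equal(sum(comp$percent), 100, tolerance = 0.01)
  got <- setNames(comp$percent, comp$clade)[names(pct)]
  # printed percentages sum to 100.05, so proportional counts agree to ~0.02
  expect_equal(unname(got), unname(pct), tolerance = 1e-3)
})

test_that("clade composition covers zero-count clades and sums to 100", {
  tab <- toy_zotu_table(matrix(c(30, 70, 0, 0), 4, 1,
                               dimnames = list(paste0("Zotu", 1:4), "HF_1")))
  comp <- clade_composition(tab, "HF_1")
  expect_setequal(comp$clade, c("NS-Gamma", "NS-Alpha", "Nitrosospira"))
  expect_equal(comp$percent[comp$clade == "Nitrosospira"], 0)
  expect_equal(sum(comp$percent), 100, tolerance = 0.01)
  solo <- clade_composition(toy_zotu_table(
    matrix(c(5, 9, 0, 0), 4, 1,
           dimnames = list(paste0("Zotu", 1:4), "HF_1"))), "HF_1",
    level = "gene")
  expect_equal(solo$percent[solo$clade == "AOA"], 100)
})

test_that("top_n respects ranking, ties and n overflow", {
  m <- matrix(c(5, 10, 1), 3, 1,
              dimnames = list(c("ZotuA", "ZotuB", "ZotuC"), "s"))
  tab <- zotu_table(m, data.frame(sample = "s"),
                    data.frame(zotu = rownames(m), clade = "x"))
  expect_equal(top_n_taxa(tab, "s", 1)$taxon, "ZotuB")
  expect_equal(nrow(top_n_taxa(tab, "s", 10)), 3)
  # tie at the cut: lexicographic winner included
  m2 <- matrix(c(10, 5, 5), 3, 1,
               dimnames = list(c("ZotuC", "ZotuB", "ZotuA"), "s"))
  tab2 <- zotu_table(m2, data.frame(sample = "s"),
                     data.frame(zotu = rownames(m2), clade = "x"))
  expect_equal(top_n_taxa(tab2, "s", 2)$taxon, c("ZotuC", "ZotuA"))
})

test_that("top_n ordering equals a brute-force full sort", {
  set.seed(5)
  for (i in 1:20) {
    nz <- sample(3:8, 1)
    m <- matrix(rpois(nz * 2, 20), nz, 2,
                dimnames = list(paste0("Zotu", sample(100, nz)),
                                c("s1", "s2")))
    tab <- zotu_table(m, data.frame(sample = c("s1", "s2")),
                      data.frame(zotu = rownames(m), clade = "x"))
    pooled <- rowSums(m)
    oracle <- names(pooled)[order(-pooled, names(pooled))]
    expect_equal(top_n_taxa(tab, c("s1", "s2"), nz)$taxon, oracle)
  }
})

test_that("active/enriched classification follows the thresholds", {
  # identical compositions: active above min_abund, nothing enriched
  m <- matrix(c(50, 45, 5, 0, 50, 45, 5, 0), 4, 2,
              dimnames = list(paste0("Zotu", 1:4), c("HF", "CK")))
  tab <- zotu_table(m, data.frame(sample = c("HF", "CK")),
                    data.frame(zotu = rownames(m), clade = "x"))
  out <- active_taxa(tab, "HF", "CK")
  expect_equal(out$active, out$hf_abund >= 0.01)
  expect_false(any(out$enriched))

  # 40% vs 10%: four-fold, active and enriched
  m2 <- matrix(c(40, 60, 10, 90), 2, 2,
               dimnames = list(c("Zotu1", "Zotu2"), c("HF", "CK")))
  tab2 <- zotu_table(m2, data.frame(sample = c("HF", "CK")),
                     data.frame(zotu = rownames(m2), clade = "x"))
  out2 <- active_taxa(tab2, "HF", "CK")
  z1 <- out2[out2$taxon == "Zotu1", ]
  expect_true(z1$active && z1$enriched)

  # absent from HF: never active; absent from reference: enriched iff active
  m3 <- matrix(c(0, 100, 20, 80), 2, 2,
               dimnames = list(c("Zotu1", "Zotu2"), c("HF", "CK")))
  tab3 <- zotu_table(m3, data.frame(sample = c("HF", "CK")),
                     data.frame(zotu = rownames(m3), clade = "x"))
  out3 <- active_taxa(tab3, "HF", "CK")
  expect_false(out3$active[out3$taxon == "Zotu1"])
  # rescaling either group's counts changes nothing
  out_scaled <- active_taxa(zotu_table(m2 * c(7, 7, 3, 3),
                                       data.frame(sample = c("HF", "CK")),
                                       data.frame(zotu = rownames(m2),
                                                  clade = "x")),
                            "HF", "CK")
  expect_equal(out_scaled, out2)
})

test_that("zotu_table validates taxonomy coverage and sample ids", {
  m <- matrix(1, 2, 1, dimnames = list(c("Zotu1", "Zotu2"), "s1"))
  expect_error(zotu_table(m, data.frame(sample = "s1"),
                          data.frame(zotu = "Zotu1", clade = "x")),
               "Zotu2")
  expect_error(zotu_table(m, data.frame(sample = "other"),
                          data.frame(zotu = c("Zotu1", "Zotu2"), clade = "x")),
               "missing entries")
  expect_error(zotu_table(-m, data.frame(sample = "s1"),
                          data.frame(zotu = c("Zotu1", "Zotu2"), clade = "x")),
               ">= 0")
})

test_that("bundled synthetic Zotu fixtures load and validate", {
  dir <- system.file("extdata", package = "nsip")
  tab <- read_zotu_table(file.path(dir, "synthetic_zotu_counts.tsv"),
                         file.path(dir, "synthetic_zotu_samples.tsv"),
                         file.path(dir, "synthetic_zotu_taxonomy.tsv"))
  seqs <- check_zotu_fasta(file.path(dir, "synthetic_zotu_seqs.fasta"), tab)
  expect_setequal(names(seqs), rownames(tab$counts))
  hf <- tab$samples$sample[tab$samples$fraction_class == "HF"]
  ck <- tab$samples$sample[tab$samples$fraction_class == "light"]
  expect_equal(sum(clade_composition(tab, hf)$percent), 100, tolerance = 0.01)
  act <- active_taxa(tab, hf, ck)
  expect_true(any(act$active))
})
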