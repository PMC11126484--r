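test_that("profiles normalize to their maximum", {
  p <- profile_from_copies(c(2, 8, 4, rep(0, 13)))
  expect_equal(unname(normalize_profile(p)), c(0.25, 1, 0.5, rep(0, 13)))
  expect_equal(unname(normalize_profile(profile_from_copies(rep(7, 16)))),
               rep(1, 16))
  single <- profile_from_copies(c(rep(0, 5), 9, rep(0, 10)))
  expect_equal(unname(normalize_profile(single)), c(rep(0, 5), 1, rep(0, 10)))
  expect_error(normalize_profile(profile_from_copies(rep(0, 16))),
               "no signal")
})

test_that("hf_ratio sums raw copies and is scale invariant", {
  p <- profile_from_copies(c(10, 10, 10, 10, rep(0, 12)))
  expect_equal(hf_ratio(p, 1:16), 1)
  expect_equal(hf_ratio(p, c(1, 2)), 0.5)
  # 90.6% of copies placed in fractions 6-7 by construction
  copies <- rep(0.94, 16); copies[6:7] <- c(45.3, 45.3)
  copies[setdiff(1:16, 6:7)] <- 9.4 / 14
  p2 <- profile_from_copies(copies)
  expect_equal(hf_ratio(p2, 6:7), 0.906, tolerance = 1e-12)
  expect_equal(hf_ratio(profile_from_copies(copies * 1e5), 6:7),
               hf_ratio(p2, 6:7))
  expect_error(hf_ratio(p, integer(0)), "empty")
  expect_error(hf_ratio(profile_from_copies(rep(0, 16)), 1:2), "zero total")
})

test_that("labeled abundance is the ratio applied to the total", {
  expect_equal(labeled_abundance(0, 5e7), 0)
  r <- runif(20); a <- runif(20) * 1e8
  expect_true(all(labeled_abundance(r, a) <= a))
  expect_equal(labeled_abundance(r, a), r * a)
  expect_error(labeled_abundance(1.2, 1e7), "\\[0, 1\\]")
})

test_that("peak_bd reports the maximal fraction, ties to the heavy side", {
  single <- profile_from_copies(c(rep(0, 5), 9, rep(0, 10)))
  expect_equal(peak_bd(single), single$buoyant_density[6])
  tie <- profile_from_copies(c(0, 0, 5, 0, 0, 5, rep(0, 10)))
  # fraction 3 is heavier (higher BD) than fraction 6
  expect_equal(peak_bd(tie), tie$buoyant_density[3])
  expect_error(peak_bd(profile_from_copies(rep(0, 16))), "no signal")
})

test_that("identical paired profiles yield no labeling", {
  copies <- c(rep(0, 8), 2, 10, 3, rep(0, 5))
  p15 <- profile_from_copies(copies)
  p14 <- profile_from_copies(copies, treatment = "14N-urea")
  expect_identical(identify_heavy_fractions(p15, p14), integer(0))
})

test_that("manual heavy-fraction sets pass through validated", {
  p15 <- profile_from_copies(c(rep(1, 16)))
  p14 <- profile_from_copies(rep(1, 16), treatment = "14N-urea")
  expect_equal(identify_heavy_fractions(p15, p14, manual_set = c(9, 7, 8)),
               7:9)
  expect_error(identify_heavy_fractions(p15, p14, manual_set = c(7, 99)),
               "outside the grid")
})

test_that("heavy fractions of a labeled taxon contain the shifted band", {
  prot <- gradient_protocol(qpcr_noise_sigma = 0, detection_floor = 0)
  tx <- taxon_spec("t", 1e7, gc = 0.5, atom15n = 1)
  p15 <- simulate_gradient(tx, prot, "15N")$profiles[[1]]
  p14 <- simulate_gradient(tx, prot, "14N")$profiles[[1]]
  hf <- identify_heavy_fractions(p15, p14)
  expect_gt(length(hf), 0)
  mu <- unlabeled_density(0.5) + label_shift(1, 0.5)
  grid <- default_grid(prot)
  holds_mu <- grid$fraction_index[grid$bd_lo <= mu & mu <= grid$bd_hi]
  expect_true(holds_mu %in% hf)
  # HF sits strictly on the heavy side of the unlabeled peak
  expect_true(all(p15$buoyant_density[hf] > peak_bd(p14)))
})

test_that("profiles on different grids are rejected", {
  p15 <- profile_from_copies(rep(1, 16))
  other <- gradient_protocol(bd_top = 1.65, bd_bottom = 1.79,
                             qpcr_noise_sigma = 0)
  grid <- default_grid(other)
  p14 <- fraction_profile("AOB", "14N-urea",
                          data.frame(fraction_index = grid$fraction_index,
                                     buoyant_density = grid$buoyant_density,
                                     copies = rep(1, 16)))
  expect_error(identify_heavy_fractions(p15, p14), "fraction grid")
})

test_that("replicated quantification recovers a fully labeled taxon", {
  prot <- gradient_protocol()
  tx <- taxon_spec("t", 1e7, gc = 0.5, atom15n = 1)
  sims <- lapply(1:3, function(r) simulate_sip_experiment(tx, prot, seed = r))
  p15 <- lapply(sims, function(s) s$label15N$profiles[[1]])
  p14 <- lapply(sims, function(s) s$label14N$profiles[[1]])
  totals <- vapply(p15, function(p) sum(p$copies), numeric(1))
  est <- quantify_labeling(p15, p14, total_abundance = totals)
  expect_true(est$labeled)
  expect_gt(est$hf_ratio, 0.85)
  expect_equal(est$labeled_abundance, 1e7, tolerance = 0.15)
  expect_false(is.na(est$hf_ratio_se))
  # unlabeled taxon: quantification reports no labeling, not an estimate
  tx0 <- taxon_spec("t0", 1e7, gc = 0.5, atom15n = 0)
  sims0 <- lapply(1:3, function(r) simulate_sip_experiment(tx0, prot, seed = r))
  est0 <- quantify_labeling(lapply(sims0, function(s) s$label15N$profiles[[1]]),
                            lapply(sims0, function(s) s$label14N$profiles[[1]]),
                            total_abundance = 1e7)
  expect_false(est0$labeled)
  expect_true(is.na(est0$labeled_abundance))
})
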