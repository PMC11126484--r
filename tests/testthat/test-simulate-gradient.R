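noiseless <- gradient_protocol(qpcr_noise_sigma = 0, detection_floor = 0)

test_that("a zero-abundance taxon yields an all-zero profile", {
  tx <- taxon_spec("empty", 0, gc = 0.5, atom15n = 1)
  sim <- simulate_gradient(tx, noiseless, "15N", seed = 1)
  expect_equal(sim$profiles[["amoA"]]$copies, rep(0, 16))
})

test_that("noiseless banding matches direct numerical integration", {
  tx <- taxon_spec("t", 1e7, gc = 0.5, atom15n = 1)
  sim <- simulate_gradient(tx, noiseless, "15N", seed = 1)
  prof <- sim$profiles[["amoA"]]
  mu <- unlabeled_density(0.5) + label_shift(1, 0.5)
  grid <- default_grid(noiseless)
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    1e7 * stats::integrate(stats::dnorm, grid$bd_lo[i], grid$bd_hi[i],
                           mean = mu, sd = tx$band_sigma,
                           rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(prof$copies, oracle, tolerance = 1e-6)
  # profile maximum sits in the window containing the shifted band center
  peak <- which.max(prof$copies)
  expect_true(grid$bd_lo[peak] <= mu && mu <= grid$bd_hi[peak])
})

test_that("noiseless profiles conserve total copies", {
  for (gc in c(0.35, 0.5, 0.65)) {
    tx <- taxon_spec("t", 3.7e6, gc = gc, atom15n = 0.5)
    sim <- simulate_gradient(tx, noiseless, "15N", seed = 1)
    expect_equal(sum(sim$profiles[["amoA"]]$copies), 3.7e6,
                 tolerance = 1e-6)
  }
})

test_that("peak buoyant density is non-decreasing in the atom fraction", {
  peaks <- vapply(seq(0, 1, length.out = 11), function(a) {
    tx <- taxon_spec("t", 1e7, gc = 0.5, atom15n = a)
    peak_bd(simulate_gradient(tx, noiseless, "15N")$profiles[["amoA"]])
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("co-amplified taxa of one gene are summed; genes stay separate", {
  taxa <- list(taxon_spec("a", 1e6, gc = 0.4, gene = "AOB"),
               taxon_spec("b", 2e6, gc = 0.6, gene = "AOB"),
               taxon_spec("c", 5e5, gc = 0.5, gene = "AOA"))
  sim <- simulate_gradient(taxa, noiseless, "14N", seed = 1)
  expect_named(sim$profiles, c("AOB", "AOA"))
  expect_equal(sum(sim$profiles[["AOB"]]$copies), 3e6, tolerance = 1e-6)
  expect_equal(sum(sim$profiles[["AOA"]]$copies), 5e5, tolerance = 1e-6)
})

test_that("identical seeds reproduce identical noisy datasets", {
  tx <- taxon_spec("t", 1e7, gc = 0.5, atom15n = 1)
  s1 <- simulate_gradient(tx, gradient_protocol(), "15N", seed = 42)
  s2 <- simulate_gradient(tx, gradient_protocol(), "15N", seed = 42)
  expect_identical(s1$table, s2$table)
  e1 <- simulate_sip_experiment(tx, gradient_protocol(), seed = 7)
  e2 <- simulate_sip_experiment(tx, gradient_protocol(), seed = 7)
  expect_identical(e1$label15N$table, e2$label15N$table)
  expect_identical(e1$label14N$table, e2$label14N$table)
})

test_that("detection floor zeroes sub-threshold fractions", {
  tx <- taxon_spec("t", 1e4, gc = 0.5, atom15n = 0)
  prot <- gradient_protocol(qpcr_noise_sigma = 0, detection_floor = 10)
  sim <- simulate_gradient(tx, prot, "14N")
  copies <- sim$profiles[["amoA"]]$copies
  expect_true(all(copies == 0 | copies >= 10))
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_gradient(list(), gradient_protocol(), "15N"),
               "at least one taxon")
  expect_error(gradient_protocol(bd_top = 1.8, bd_bottom = 1.7), "exceed")
  expect_error(gradient_protocol(qpcr_noise_sigma = -1), ">= 0")
  expect_error(taxon_spec("x", -1, 0.5), "non-negative")
  expect_error(taxon_spec("x", 1, 0.5, band_sigma = 0), "> 0")
})
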