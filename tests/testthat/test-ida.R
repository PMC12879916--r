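# Ratio traces and the species-unspecific online IDA conversion.

test_that("ratio trace basics: identity ratio, no-op smoothing, masking", {
  ch <- chrom_with_ratio(rep(1, 10))
  rt <- ratio_trace(ch)
  expect_equal(rt$ratio, rep(1, 10))

  ch2 <- chrom_with_ratio(runif(20, 0.5, 2))
  expect_equal(ratio_trace(ch2, smoothing_points = 1)$ratio,
               ch2$counts[, "78"] / ch2$counts[, "74"])

  # all points below the denominator threshold -> explicit failure
  low <- isotope_chromatogram(1:5, cbind(`74` = rep(1, 5),
                                         `78` = rep(1, 5)))
  expect_error(ratio_trace(low, min_counts = 10), "no spike signal")
  expect_error(ratio_trace(ch, smoothing_points = 2), "odd")
})

test_that("baseline ratio of a spike-only simulation equals the spike ratio", {
  spec <- simulation_spec(default_serum_species(c(SELENOP = 0)))
  sim <- simulate_chromatogram(spec)
  rt <- ratio_trace(sim$chromatogram)
  r_sp <- 0.001 / 0.999
  expect_true(all(abs(rt$ratio - r_sp) < 1e-6))
})

test_that("mass flow is zero at the spike ratio and masked at the pole", {
  ida <- ida_parameters()
  r_sp <- 0.001 / 0.999
  r_nat <- 0.0089 / 0.2377
  rt <- ratio_from(c(r_sp, 0.5, 1 / r_nat))
  mf <- mass_flow(rt, ida)
  expect_identical(mf$mass_flow[1], 0)
  expect_false(mf$valid[3])
  expect_equal(mf$n_masked_pole, 1L)
  expect_true(is.na(mf$mass_flow[3]))
})

test_that("mass flow matches the independently coded closed form", {
  # printed-example check: 99.9% 74Se spike, 10 ng/min spike flow
  ida10 <- ida_parameters(spike_concentration = 100, spike_flow = 0.1)
  got <- mass_flow(ratio_from(5), ida10)$mass_flow
  want <- ida_oracle(5, 100, 0.1, 0.999, 0.001, 0.0089, 0.2377,
                     78.971, sum(c(0.999, 0.001) *
                                   se_masses_ciaaw[c("74", "78")]))
  expect_equal(got, want, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    a74 <- runif(1, 0.95, 0.999)
    a78 <- 1 - a74
    sp_ab <- c(`74` = a74, `76` = 0, `77` = 0, `78` = a78,
               `80` = 0, `82` = 0)
    nat <- c(`74` = 0.0089, `76` = 0.0937, `77` = 0.0763,
             `78` = 0.2377, `80` = 0.4961, `82` = 0.0873)
    nat <- nat * runif(6, 0.8, 1.2)
    nat <- nat / sum(nat)
    conc <- runif(1, 10, 500)
    flow <- runif(1, 0.01, 0.5)
    aw_nat <- runif(1, 78.5, 79.5)
    ida <- ida_parameters(spike_concentration = conc, spike_flow = flow,
                          spike_abundances = sp_ab,
                          natural_abundances = nat,
                          atomic_weight_natural = aw_nat)
    r_sp <- a78 / a74
    r_nat <- nat[["74"]] / nat[["78"]]
    r_m <- r_sp + runif(1, 0.01, 0.95) * (1 / r_nat - r_sp)
    got <- mass_flow(ratio_from(r_m), ida)$mass_flow
    want <- ida_oracle(r_m, conc, flow, a74, a78, nat[["74"]],
                       nat[["78"]], aw_nat,
                       sum(sp_ab * se_masses_ciaaw[names(sp_ab)]))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("mass flow is invariant under common channel rescaling", {
  r <- runif(50, 0.01, 3)
  ida <- ida_parameters()
  mf1 <- mass_flow(ratio_from(r, i74 = 1e6), ida)$mass_flow
  mf2 <- mass_flow(ratio_from(r, i74 = 3.7e4), ida)$mass_flow
  expect_equal(mf1, mf2, tolerance = 1e-12)
})

test_that("mass flow is monotone in the measured ratio on the physical branch", {
  ida <- ida_parameters()
  r_sp <- 0.001 / 0.999
  r_nat <- 0.0089 / 0.2377
  r <- seq(r_sp * 1.01, 0.99 / r_nat, length.out = 200)
  mf <- mass_flow(ratio_from(r), ida)$mass_flow
  expect_true(all(diff(mf) > 0))
  expect_true(all(mf > 0))
})

test_that("mass-bias correction is a linear action and inverts the simulator", {
  rt <- ratio_from(runif(10, 0.1, 2))
  expect_equal(mass_bias_correct(rt, 0), rt)
  corrected <- mass_bias_correct(rt, (1 / 0.99 - 1) / 4)
  expect_equal(corrected$ratio, rt$ratio * 0.99, tolerance = 1e-12)

  # simulate with mass bias, correct with the same factor, requantify
  spec <- simulation_spec(default_serum_species(c(SELENOP = 5.92)),
                          mass_bias_per_amu = 0.005)
  sim <- simulate_chromatogram(spec)
  res <- quantify_chromatogram(sim$chromatogram,
                               mass_bias_per_amu = 0.005)
  got <- res$se_ng[res$species == "SELENOP"]
  expect_lt(abs(got / 5.92 - 1), 0.005)
})

test_that("integrated mass is insensitive to mild ratio smoothing", {
  sim <- simulate_chromatogram(simulation_spec(
    default_serum_species(c(SELENOP = 5.92))))
  masses <- vapply(c(1, 3, 5), function(k) {
    res <- quantify_chromatogram(sim$chromatogram, smoothing_points = k)
    res$se_ng[res$species == "SELENOP"]
  }, 0)
  expect_true(all(abs(masses / masses[1] - 1) < 0.002))
})
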