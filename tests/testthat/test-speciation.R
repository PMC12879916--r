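# Aggregate statistics, percent composition, stoichiometry conversion
# and validation figures of merit.

test_that("report rounding is half away from zero", {
  expect_equal(round_half_out(3.55, 1), 3.6)
  expect_equal(round_half_out(-3.55, 1), -3.6)
  expect_equal(round_half_out(2.45, 1), 2.5)
  expect_equal(round_half_out(0.5), 1)
  expect_equal(round_half_out(3.449, 1), 3.4)
})

test_that("speciation table validates the sum column", {
  df <- data.frame(sample = "s1", GPx = 1, SMT = 1, SELENOP = 1,
                   SELENOW_plus_others = 1, SeAlb = 1)
  tab <- speciation_table(df)
  expect_equal(tab$sum_of_species, 5)

  df$sum_of_species <- 5.5
  expect_error(speciation_table(df), "disagrees")
  df$sum_of_species <- 5.01  # within printed-input rounding slack
  expect_s3_class(speciation_table(df), "speciation_table")
})

test_that("aggregate statistics: mean, n-1 SD, SEM, extremes", {
  df <- data.frame(sample = c("a", "b"), GPx = c(1, 3), SMT = c(2, 2),
                   SELENOP = c(10, 10), SELENOW_plus_others = c(5, 5),
                   SeAlb = c(1, 1))
  agg <- aggregate_speciation(speciation_table(df))
  raw <- agg$raw
  expect_equal(raw$GPx[raw$statistic == "average"], 2)
  expect_equal(raw$GPx[raw$statistic == "SD"], sqrt(2))
  expect_equal(raw$GPx[raw$statistic == "SEM"], sqrt(2) / sqrt(2))
  expect_equal(raw$SMT[raw$statistic == "SD"], 0)   # constant column
  expect_equal(raw$SMT[raw$statistic == "SEM"], 0)
  expect_equal(raw$GPx[raw$statistic == "maximum"], 3)
  expect_equal(raw$GPx[raw$statistic == "minimum"], 1)

  expect_error(aggregate_speciation(speciation_table(df[1, ])),
               "at least 2")
})

test_that("percent composition handles degenerate tables", {
  one <- speciation_table(data.frame(
    sample = c("a", "b"), GPx = 0, SMT = 0, SELENOP = c(10, 20),
    SELENOW_plus_others = 0, SeAlb = 0))
  expect_equal(unname(percent_composition(one)),
               c(0L, 0L, 100L, 0L, 0L))

  equal5 <- speciation_table(data.frame(
    sample = c("a", "b"), GPx = 2, SMT = 2, SELENOP = 2,
    SELENOW_plus_others = 2, SeAlb = 2))
  expect_equal(unname(percent_composition(equal5)), rep(20L, 5))
})

test_that("rounded percentages sum to ~100 on the bundled cohort", {
  pct <- percent_composition(chicken_serum_selenoproteins())
  expect_lte(abs(sum(pct) - 100), 2)
})

test_that("Se-to-protein conversion is linear and refuses non-stoichiometric species", {
  # unit identity: one Se atom, molar mass 78971 g/mol
  expect_equal(se_to_protein(42, n_se_atoms = 1, molar_mass = 78971), 42)
  expect_equal(se_to_protein(0, n_se_atoms = 13, molar_mass = 5e4), 0)
  base <- se_to_protein(59.2, species = "SELENOP")
  expect_equal(se_to_protein(118.4, species = "SELENOP"), 2 * base)

  expect_error(se_to_protein(2.1, species = "SeAlb"),
               "nonspecifically")
  expect_error(se_to_protein(34.2, species = "SELENOW_plus_others"),
               "cannot be determined")
  expect_error(se_to_protein(4.1, species = "SMT"), "cannot be determined")
  expect_error(se_to_protein(1, n_se_atoms = 0, molar_mass = 1), ">= 1")
})

test_that("protein conversion regression against back-derived molar masses", {
  tab <- chicken_serum_selenoproteins()
  m <- colMeans(as.matrix(tab[c("SELENOP", "GPx")]))
  expect_equal(round_half_out(
    se_to_protein(m[["SELENOP"]], species = "SELENOP"), 2), 2.88)
  expect_equal(round_half_out(
    se_to_protein(m[["GPx"]], species = "GPx"), 2), 1.23)
})

test_that("validation statistics: recovery, LOD, LOQ", {
  v <- validation_stats(10, 10, c(0.1, 0.2, 0.3))
  expect_equal(v$recovery_pct, 100)
  expect_equal(v$lod, 0.3)
  expect_equal(v$loq, 1.0)

  same <- validation_stats(9, 10, c(0.2, 0.2, 0.2))
  expect_equal(same$lod, 0)
  expect_equal(same$recovery_pct, 90)

  expect_error(validation_stats(1, 0, c(0.1, 0.2, 0.3)), "positive")
  expect_error(validation_stats(1, 1, c(0.1, 0.2)), "3 blank")
})
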