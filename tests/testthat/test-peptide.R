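# Tryptic digestion, peptide masses, mass matching, coverage, ladders.

test_that("trypsin rule: cleave after K/R except before P", {
  d <- digest("AKRPGR")
  expect_equal(d$peptide, c("AK", "RPGR"))
  expect_equal(d$start, c(1, 3))
  expect_equal(d$end, c(2, 6))

  expect_equal(digest("GASTN")$peptide, "GASTN")  # no K/R at all

  d1 <- digest("AKR", max_missed = 1)
  expect_setequal(d1$peptide, c("AK", "R", "AKR"))
  expect_equal(d1$missed[d1$peptide == "AKR"], 1)

  expect_error(digest("AKZ"), "unknown residue.*Z")
})

test_that("zero-missed peptides tile the parent sequence", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYU", "")[[1]]
  for (i in 1:20) {
    s <- paste(sample(alphabet, sample(10:60, 1), replace = TRUE),
               collapse = "")
    d <- digest(s)
    expect_equal(paste(d$peptide, collapse = ""), s)
    expect_equal(d$start[1], 1)
    expect_equal(d$end[nrow(d)], nchar(s))
    if (nrow(d) > 1)
      expect_equal(d$start[-1], d$end[-nrow(d)] + 1)
  }
})

test_that("peptide masses match an independent proteomics oracle", {
  # frozen reference values computed with an independent mass library
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  frozen <- c(MALAVGDEGSLK = 1189.60127, GGVTSAPDNK = 944.45632,
              EVFDAATSLGHMWNR = 1732.79914, LIPTGSEK = 843.47018,
              VYADGSTFEPNQALK = 1638.78895, TSGVDELYGR = 1095.51965)
  for (p in names(frozen))
    expect_equal(peptide_mass(p), frozen[[p]], tolerance = 5e-7)
  # Sec-containing peptide, carbamidomethylated and degraded to Dha
  expect_equal(
    peptide_mass("UCGADSTNPEYFQLR",
                 mods = c("carbamidomethyl", "sec_to_dha")),
    1725.74168, tolerance = 5e-7)
})

test_that("modification deltas are additive and match the bundled table", {
  base <- peptide_mass("ACGK")
  expect_equal(peptide_mass("ACGK", mods = "carbamidomethyl") - base,
               57.02146)
  u_base <- peptide_mass("AUGK")
  expect_equal(peptide_mass("AUGK", mods = "sec_to_dha") - u_base,
               -81.93218, tolerance = 1e-4)
  # deltas scale with the number of target residues
  expect_equal(peptide_mass("CC", mods = "carbamidomethyl") -
                 peptide_mass("CC"), 2 * 57.02146)
  expect_error(peptide_mass("AK", mods = "phospho"),
               "unknown modification.*phospho")

  custom <- data.frame(name = "oxidation", target = "M",
                       mono = 15.99491, avg = 15.999)
  expect_equal(peptide_mass("AMK", mods = "oxidation", custom = custom) -
                 peptide_mass("AMK"), 15.99491)
})

test_that("self-match yields full digest coverage (BSA-control analogue)", {
  s <- "MKAVLGDEKTSSYRLLAGHKFDETWNR"
  theo <- add_peptide_masses(digest(s))
  res <- match_masses(theo, theo$mass, protein_length = nchar(s),
                      protein_id = "control")
  expect_equal(res$coverage_fraction, 1)
  expect_equal(res$coverage_pct, 100)
  expect_equal(res$tier, "confirmed")

  # masses shifted by twice the tolerance match nothing
  shifted <- theo$mass * (1 + 40e-6)
  res2 <- match_masses(theo, shifted, tol_ppm = 20,
                       protein_length = nchar(s))
  expect_equal(nrow(res2$matches), 0)
  expect_equal(res2$coverage_fraction, 0)
  expect_equal(res2$tier, "not_confirmed")

  # empty observed list is a zero-coverage result, not an error
  res3 <- match_masses(theo, numeric(0), protein_length = nchar(s))
  expect_equal(res3$coverage_fraction, 0)
})

test_that("matching is one-to-one with deterministic tie-breaking", {
  s <- "AAKAAK"
  theo <- add_peptide_masses(digest(s))
  one <- match_masses(theo, theo$mass[1], protein_length = 6)
  expect_equal(nrow(one$matches), 1)
  expect_equal(one$matches$start, 1)  # tie broken by earlier start

  both <- match_masses(theo, theo$mass, protein_length = 6)
  expect_equal(nrow(both$matches), 2)
  expect_equal(both$coverage_fraction, 1)
})

test_that("coverage is the union of matched intervals", {
  res <- structure(
    list(protein_id = "x", protein_length = 20,
         matches = data.frame(start = c(1, 5), end = c(10, 15)),
         coverage_fraction = NA_real_, coverage_pct = NA_real_,
         tier = NA_character_),
    class = "peptide_match_result")
  out <- coverage_and_tier(res)
  expect_equal(out$coverage_fraction, 0.75)
  expect_equal(out$tier, "partially_confirmed")
})

test_that("confirmation tiers follow the coverage thresholds", {
  mk <- function(cov) structure(
    list(protein_id = "x", protein_length = 100,
         matches = data.frame(start = 1, end = cov),
         coverage_fraction = NA_real_, coverage_pct = NA_real_,
         tier = NA_character_),
    class = "peptide_match_result")
  expect_equal(coverage_and_tier(mk(59))$tier, "not_confirmed")
  expect_equal(coverage_and_tier(mk(60))$tier, "partially_confirmed")
  expect_equal(coverage_and_tier(mk(80))$tier, "partially_confirmed")
  expect_equal(coverage_and_tier(mk(85))$tier, "confirmed")
  expect_error(coverage_and_tier(mk(85), c(partial = 0.9, confirm = 0.6)),
               "partial < confirm")
})

test_that("coverage is monotone in the observed-mass set", {
  s <- "MALAVGDEGSLKUCGADSTNPEYFQLRGGVTSAPDNKEVFDAATSLGHMWNR"
  theo <- add_peptide_masses(digest(s))
  set.seed(3)
  masses <- theo$mass[theo$modified == "carbamidomethyl"]
  cov <- vapply(seq_along(masses), function(k) {
    match_masses(theo, masses[seq_len(k)],
                 protein_length = nchar(s))$coverage_fraction
  }, 0)
  expect_true(all(diff(cov) >= 0))
})

test_that("b/y fragment ladders satisfy the mass-conservation identities", {
  gg <- fragment_ladder("GG")
  expect_equal(gg$mz[gg$ion == "y" & gg$index == 1], 76.03931,
               tolerance = 1e-6)

  proton <- 1.00727646688
  for (s in c("GASTNK", "LIPTGSEK", "UCGADSTNPEYFQLR")) {
    lad <- fragment_ladder(s)
    n <- nchar(s)
    precursor <- peptide_mass(s)
    b_last <- lad$mz[lad$ion == "b" & lad$index == n - 1]
    y_first <- lad$mz[lad$ion == "y" & lad$index == 1]
    expect_equal(b_last + y_first - proton, precursor + proton,
                 tolerance = 1e-9)
    # charge-2 series from the charge-1 neutral masses
    lad2 <- fragment_ladder(s, charge = 2)
    expect_equal(lad2$mz, (lad$mz - proton + 2 * proton) / 2,
                 tolerance = 1e-9)
  }
  expect_error(fragment_ladder("G"), "2 residues")
  expect_error(fragment_ladder("GG", charge = 0), "charge")
})

test_that("the synthetic SELENOW fixture is confirmed at 88.24% coverage", {
  fasta <- system.file("extdata", "selenow_synthetic.fasta",
                       package = "selenoquant")
  masses <- read_mass_list(system.file(
    "extdata", "selenow_synthetic_masses.txt", package = "selenoquant"))
  prot <- read_proteins(fasta)
  expect_equal(nchar(prot[[1]]), 85)
  res <- digest_and_match(prot[[1]], masses,
                          protein_id = names(prot)[1])
  expect_equal(nrow(res$matches), 6)
  expect_equal(res$coverage_fraction, 75 / 85)
  expect_equal(res$coverage_pct, 88.24)
  expect_equal(res$tier, "confirmed")
})
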