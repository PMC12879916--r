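# Shared builders for toy traces used across the tests.

# Chromatogram whose 78/74 point ratios equal `ratio` exactly.
chrom_with_ratio <- function(ratio, i74 = 1e6, time_s = NULL) {
  n <- length(ratio)
  if (is.null(time_s)) time_s <- seq_len(n)
  counts <- cbind(`74` = rep(i74, n), `78` = i74 * ratio)
  isotope_chromatogram(time_s, counts, sample_id = "toy")
}

ratio_from <- function(ratio, ...) {
  ratio_trace(chrom_with_ratio(ratio, ...), smoothing_points = 1)
}

# Hand-built mass-flow trace on a uniform minute grid.
mf_trace <- function(t_min, mass_flow, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(t_min))
  structure(list(time_s = t_min * 60, mass_flow = mass_flow,
                 valid = valid, n_masked_pole = 0L),
            class = "mass_flow_trace")
}

# Independently coded closed form of the online species-unspecific IDA
# equation (kept free of any package internals; isotope masses retyped
# from the CIAAW table).
ida_oracle <- function(r_m, conc, flow, a_sp74, a_sp78,
                       a_nat74, a_nat78, aw_nat, aw_sp) {
  (conc * flow) * (aw_nat / aw_sp) * (a_sp74 / a_nat78) *
    (r_m - a_sp78 / a_sp74) / (1 - r_m * a_nat74 / a_nat78)
}

se_masses_ciaaw <- c(`74` = 73.922476, `76` = 75.919214,
                     `77` = 76.919914, `78` = 77.917309,
                     `80` = 79.916522, `82` = 81.916700)

# Printed 13-sample cohort statistics, frozen from an independent hand
# computation (mean/sd with n-1/sem/max/min, rounded half away from
# zero to one decimal).
expected_report <- data.frame(
  statistic = c("average", "SD", "SEM", "maximum", "minimum"),
  GPx = c(3.6, 0.3, 0.1, 3.9, 2.7),
  SMT = c(4.1, 1.6, 0.4, 6.9, 1.9),
  SELENOP = c(59.2, 13.4, 3.7, 81.4, 37.2),
  SELENOW_plus_others = c(34.2, 5.6, 1.5, 44.3, 24.6),
  SeAlb = c(2.1, 0.4, 0.1, 2.7, 1.4),
  sum_of_species = c(103.0, 12.0, 3.3, 126.8, 86.5),
  check.names = FALSE)
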