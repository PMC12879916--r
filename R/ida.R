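# Species-unspecific online isotope dilution: ratio traces and their
# conversion into Se mass-flow chromatograms.

#' Measured isotope-ratio trace
#'
#' Computes the pointwise 78Se/74Se intensity ratio of a chromatogram,
#' optionally after centred moving-average smoothing of both channels.
#' Points where the spike (denominator) channel falls below
#' `min_counts` are masked invalid rather than producing unstable
#' ratios.
#'
#' @param chrom An `isotope_chromatogram` containing isotopes 74 and 78.
#' @param smoothing_points Odd window length of the centred moving
#'   average applied to both channels; 1 (default) leaves the raw
#'   point ratios untouched.
#' @param min_counts Minimum denominator counts for a point to be
#'   considered valid.
#' @return An object of class `ratio_trace`: list with `time_s`,
#'   `ratio`, `valid` and the masked-point count `n_masked`.
#' @export
ratio_trace <- function(chrom, smoothing_points = 1L, min_counts = 10) {
  stopifnot(inherits(chrom, "isotope_chromatogram"))
  k <- as.integer(smoothing_points)
  if (k < 1L || k %% 2L == 0L)
    stop("smoothing_points must be a positive odd integer")
  i74 <- chrom$counts[, "74"]
  i78 <- chrom$counts[, "78"]
  if (k > 1L) {
    sm <- function(x) as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    i74 <- sm(i74)
    i78 <- sm(i78)
  }
  valid <- !is.na(i74) & !is.na(i78) & i74 >= min_counts
  ratio <- rep(NA_real_, length(valid))
  ratio[valid] <- i78[valid] / i74[valid]
  if (!any(valid))
    stop("no spike signal: every point has 74Se counts below the ",
         "validity threshold")
  structure(list(time_s = chrom$time_s, ratio = ratio, valid = valid,
                 n_masked = sum(!valid)),
            class = "ratio_trace")
}

#' Correct an isotope-ratio trace for mass bias
#'
#' Applies a linear-per-amu mass-bias model: the measured 78/74 ratio is
#' divided by `(1 + factor_per_amu * 4)`, 4 u being the mass difference
#' between the reference and spike isotopes. A factor of 0 is the
#' identity.
#'
#' @param ratio A `ratio_trace`.
#' @param factor_per_amu Dimensionless bias per atomic mass unit.
#' @return The corrected `ratio_trace`.
#' @export
mass_bias_correct <- function(ratio, factor_per_amu) {
  stopifnot(inherits(ratio, "ratio_trace"), is.finite(factor_per_amu))
  ratio$ratio <- ratio$ratio / (1 + factor_per_amu * 4)
  ratio
}

#' Convert a ratio trace into a Se mass-flow chromatogram
#'
#' Implements the species-unspecific online isotope-dilution equation.
#' With a constant post-column flow of enriched-74Se spike
#' (`MF_sp = spike_concentration * spike_flow`, ng/min), the mass flow
#' of natural-composition sample Se at each time point is
#'
#'   `MF_s(t) = MF_sp * (Aw_nat / Aw_sp) * (a_sp74 / a_nat78) *
#'              (R_m(t) - R_sp) / (1 - R_m(t) * R_nat)`
#'
#' where `R_m` is the measured 78/74 intensity ratio,
#' `R_sp = a_sp78 / a_sp74` the spike ratio and
#' `R_nat = a_nat74 / a_nat78` the inverse natural ratio. The equation
#' has two fixed points used as diagnostics: `MF_s = 0` exactly when the
#' measured ratio equals the spike ratio (no sample Se eluting), and a
#' pole when the measured ratio reaches the natural composition (spike
#' fully diluted); points within `denom_tol` of the pole are masked and
#' counted in `n_masked_pole`, never silently zeroed.
#'
#' @param ratio A `ratio_trace` (masked points propagate as masked).
#' @param ida An `ida_parameters` object.
#' @param denom_tol Tolerance on the denominator `1 - R_m * R_nat`
#'   below which a point is masked as at the natural-ratio pole.
#' @return An object of class `mass_flow_trace`: list with `time_s`,
#'   `mass_flow` (ng Se/min), `valid`, `n_masked_pole`.
#' @export
mass_flow <- function(ratio, ida, denom_tol = 1e-9) {
  stopifnot(inherits(ratio, "ratio_trace"), inherits(ida, "ida_parameters"))
  ref <- as.character(ida$reference_isotope)
  spk <- as.character(ida$spike_isotope)
  r_sp <- ida$spike_abundances[[ref]] / ida$spike_abundances[[spk]]
  r_nat <- ida$natural_abundances[[spk]] / ida$natural_abundances[[ref]]
  denom <- 1 - ratio$ratio * r_nat
  at_pole <- ratio$valid & abs(denom) < denom_tol
  valid <- ratio$valid & !at_pole
  mf <- rep(NA_real_, length(valid))
  scale <- ida$spike_mass_flow *
    (ida$atomic_weight_natural / ida$atomic_weight_spike) *
    (ida$spike_abundances[[spk]] / ida$natural_abundances[[ref]])
  mf[valid] <- scale * (ratio$ratio[valid] - r_sp) / denom[valid]
  structure(list(time_s = ratio$time_s, mass_flow = mf, valid = valid,
                 n_masked_pole = sum(at_pole)),
            class = "mass_flow_trace")
}

#' @export
print.mass_flow_trace <- function(x, ...) {
  cat("<mass_flow_trace>",
      sprintf("time: %.1f-%.1f s (%d points, %d masked)",
              min(x$time_s), max(x$time_s), length(x$time_s),
              sum(!x$valid)),
      sprintf("mass flow: max %.4g ng/min",
              suppressWarnings(max(x$mass_flow, na.rm = TRUE))),
      sep = "\n")
  invisible(x)
}

#' Write a mass-flow trace to delimited text
#'
#' Emits `time_s,mass_flow_ng_per_min`; masked points are written as
#' empty fields.
#'
#' @param mf A `mass_flow_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mass_flow <- function(mf, path) {
  stopifnot(inherits(mf, "mass_flow_trace"))
  utils::write.csv(
    data.frame(time_s = mf$time_s, mass_flow_ng_per_min = mf$mass_flow),
    path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
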