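# Forward model of the online-IDA instrument: multi-isotope
# chromatograms with known ground-truth species masses.

#' Specify one chromatographic species peak
#'
#' @param species_name Species label.
#' @param retention_time Apex retention time, minutes (> 0).
#' @param peak_sigma Gaussian peak width sigma, minutes (> 0).
#' @param se_mass Se mass injected in that species, ng (>= 0).
#' @return A list of class `species_peak`.
#' @export
species_peak <- function(species_name, retention_time, peak_sigma,
                         se_mass) {
  if (retention_time <= 0) stop("retention_time must be positive")
  if (peak_sigma <= 0) stop("peak_sigma must be positive")
  if (se_mass < 0) stop("se_mass must be non-negative")
  structure(list(species_name = species_name,
                 retention_time = retention_time,
                 peak_sigma = peak_sigma,
                 se_mass = se_mass),
            class = "species_peak")
}

#' Default serum species peaks
#'
#' The five serum Se species at their retention times under the
#' optimized column-switching separation (GPx 3, SMT 5, SELENOP 20,
#' SELENOW-containing fraction 25, SeAlb 31 min) with a common peak
#' sigma of 0.12 min. At that width every default retention window
#' extends at least eight sigma beyond its peak apex, so fixed-window
#' integration captures the entire peak to within double-precision
#' noise.
#'
#' @param se_ng Named numeric vector of injected Se masses (ng), names
#'   among the five species labels.
#' @param peak_sigma Peak sigma in minutes applied to every species.
#' @return List of `species_peak` objects.
#' @export
default_serum_species <- function(se_ng, peak_sigma = 0.12) {
  rt <- c(GPx = 3, SMT = 5, SELENOP = 20, SELENOW_plus_others = 25,
          SeAlb = 31)
  bad <- setdiff(names(se_ng), names(rt))
  if (length(bad) > 0)
    stop("unknown species: ", paste(bad, collapse = ", "))
  lapply(names(se_ng), function(s)
    species_peak(s, rt[[s]], peak_sigma, se_ng[[s]]))
}

#' Specify a simulated online-IDA run
#'
#' Collects everything the forward model needs: the species peaks, run
#' geometry (50 min acquisition, 0.3 s dwell per isotope, five isotopes
#' sampled on a common time grid), the IDA configuration, detector
#' sensitivity, an optional linear-per-amu mass-bias factor, baseline
#' counts, and the counting-noise model.
#'
#' @param species List of `species_peak` objects.
#' @param run_length Acquisition length, minutes.
#' @param dwell_time Dwell time per isotope reading, seconds.
#' @param isotopes Integer vector of monitored isotope mass numbers.
#' @param ida An `ida_parameters` object.
#' @param sensitivity Detector sensitivity (counts per reading per unit
#'   isotope molar flow); applies to every channel before mass bias.
#' @param mass_bias_per_amu Dimensionless mass-bias factor per amu:
#'   channel j is scaled by `1 + mass_bias_per_amu * (m_j - 78)`.
#' @param baseline_counts Constant background counts added to every
#'   channel.
#' @param noise `"none"` or `"poisson"` counting noise.
#' @param seed Integer RNG seed (Poisson noise only); identical specs
#'   with identical seeds give bitwise-identical chromatograms.
#' @param peak_shape `"gaussian"` (default) or `"emg"`
#'   (exponentially-modified Gaussian with time constant `emg_tau`).
#' @param emg_tau EMG exponential time constant, minutes.
#' @param sample_id,injection_volume_ml,sample_mass_g Metadata recorded
#'   on the simulated chromatogram and its ground truth.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(species,
                            run_length = 50,
                            dwell_time = 0.3,
                            isotopes = c(74L, 76L, 77L, 78L, 80L),
                            ida = ida_parameters(),
                            sensitivity = 1e6,
                            mass_bias_per_amu = 0,
                            baseline_counts = 0,
                            noise = c("none", "poisson"),
                            seed = 1L,
                            peak_shape = c("gaussian", "emg"),
                            emg_tau = 0.1,
                            sample_id = "simulated",
                            injection_volume_ml = 0.1,
                            sample_mass_g = 0.1) {
  noise <- match.arg(noise)
  peak_shape <- match.arg(peak_shape)
  if (inherits(species, "species_peak")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "species_peak")))
  if (dwell_time <= 0) stop("dwell_time must be positive")
  if (sensitivity <= 0) stop("sensitivity must be positive")
  if (baseline_counts < 0) stop("baseline_counts must be non-negative")
  for (sp in species) {
    if (run_length < sp$retention_time + 5 * sp$peak_sigma)
      stop(sprintf(paste0("run_length %g min too short for species ",
                          "'%s' eluting at %g min (need >= %g min)"),
                   run_length, sp$species_name, sp$retention_time,
                   sp$retention_time + 5 * sp$peak_sigma))
  }
  structure(list(species = species, run_length = run_length,
                 dwell_time = dwell_time, isotopes = as.integer(isotopes),
                 ida = ida, sensitivity = sensitivity,
                 mass_bias_per_amu = mass_bias_per_amu,
                 baseline_counts = baseline_counts, noise = noise,
                 seed = as.integer(seed), peak_shape = peak_shape,
                 emg_tau = emg_tau, sample_id = sample_id,
                 injection_volume_ml = injection_volume_ml,
                 sample_mass_g = sample_mass_g),
            class = "simulation_spec")
}

# Peak profile density in 1/min; integrates to 1 over the real line.
.peak_density <- function(t_min, rt, sigma, shape, tau) {
  if (shape == "gaussian") {
    stats::dnorm(t_min, mean = rt, sd = sigma)
  } else {
    lam <- 1 / tau
    arg <- (lam / 2) * (2 * rt + lam * sigma^2 - 2 * t_min)
    # guard the exp overflow far left of the peak; erfc term -> 0 there
    arg <- pmin(arg, 700)
    (lam / 2) * exp(arg) *
      pracma::erfc((rt + lam * sigma^2 - t_min) / (sqrt(2) * sigma))
  }
}

#' Simulate a multi-isotope online-IDA chromatogram
#'
#' Forward model of the SEC-AF-ICP-QQQ instrument with a constant
#' post-column enriched-74Se spike. For each time point and isotope j
#' the expected counts are
#'
#'   `sens_j * ( MF_nat(t) * a_nat_j / Aw_nat
#'             + MF_sp * a_sp_j / Aw_sp ) + baseline_counts`
#'
#' where `MF_nat(t)` is the sum of the species peak profiles (each
#' integrating to its injected `se_mass`, ng/min), `MF_sp` the constant
#' spike mass flow, and `sens_j` the channel sensitivity including the
#' linear mass-bias factor `1 + mass_bias_per_amu * (m_j - 78)`.
#' Poisson counting noise is applied when requested; the draw is
#' deterministic given the spec's seed.
#'
#' @param spec A `simulation_spec`.
#' @return A list with elements `chromatogram` (an
#'   `isotope_chromatogram`) and `truth` (a `ground_truth` list with
#'   per-species `se_ng`, `injection_volume_ml`, `sample_mass_g`).
#' @export
#' @examples
#' sim <- simulate_chromatogram(simulation_spec(
#'   default_serum_species(c(SELENOP = 5.92))))
#' sim$truth$se_ng
simulate_chromatogram <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cycle_s <- spec$dwell_time * length(spec$isotopes)
  time_s <- seq(cycle_s, spec$run_length * 60, by = cycle_s)
  t_min <- time_s / 60
  mf_nat <- rep(0, length(t_min))
  for (sp in spec$species) {
    mf_nat <- mf_nat + sp$se_mass *
      .peak_density(t_min, sp$retention_time, sp$peak_sigma,
                    spec$peak_shape, spec$emg_tau)
  }
  ida <- spec$ida
  mf_sp <- ida$spike_mass_flow
  lambda <- matrix(0, nrow = length(time_s), ncol = length(spec$isotopes),
                   dimnames = list(NULL, as.character(spec$isotopes)))
  for (j in as.character(spec$isotopes)) {
    m_j <- .se_isotopes$mass[.se_isotopes$isotope == as.integer(j)]
    sens_j <- spec$sensitivity *
      (1 + spec$mass_bias_per_amu * (as.integer(j) - 78))
    lambda[, j] <- sens_j *
      (mf_nat * ida$natural_abundances[[j]] / ida$atomic_weight_natural +
         mf_sp * ida$spike_abundances[[j]] / ida$atomic_weight_spike) +
      spec$baseline_counts
  }
  counts <- if (spec$noise == "poisson") {
    set.seed(spec$seed)
    matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
           dimnames = dimnames(lambda))
  } else {
    lambda
  }
  chrom <- isotope_chromatogram(
    time_s, counts, sample_id = spec$sample_id,
    injection_volume_ml = spec$injection_volume_ml,
    sample_mass_g = spec$sample_mass_g)
  truth <- structure(
    list(se_ng = stats::setNames(
           vapply(spec$species, function(s) s$se_mass, 0),
           vapply(spec$species, function(s) s$species_name, "")),
         injection_volume_ml = spec$injection_volume_ml,
         sample_mass_g = spec$sample_mass_g),
    class = "ground_truth")
  list(chromatogram = chrom, truth = truth)
}

#' Write simulation ground truth to a YAML config
#' @param truth A `ground_truth` list from [simulate_chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  yaml::write_yaml(list(se_ng = as.list(truth$se_ng),
                        injection_volume_ml = truth$injection_volume_ml,
                        sample_mass_g = truth$sample_mass_g),
                   path)
  invisible(path)
}

#' Simulate the 13-sample serum cohort
#'
#' One simulated injection per row of the bundled chicken-serum
#' speciation table, with ground-truth on-column masses
#' `se_ng = conc_ng_per_ml x 0.1 mL` (100 uL injected, 0.1000 g sample
#' mass under the density-1 convention).
#'
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer base seed; sample i uses `seed * 100 + i` so
#'   cohorts drawn with different base seeds are independent.
#' @param ... Passed on to [simulation_spec()] (e.g. `sensitivity`,
#'   `mass_bias_per_amu`).
#' @return Named list (one element per sample) of
#'   `list(chromatogram, truth)` pairs.
#' @export
simulate_serum_cohort <- function(noise = c("none", "poisson"),
                                  seed = 1L, ...) {
  noise <- match.arg(noise)
  tab <- chicken_serum_selenoproteins()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    se_ng <- unlist(tab[i, .species_levels]) * 0.1
    spec <- simulation_spec(
      default_serum_species(se_ng),
      noise = noise, seed = seed * 100L + i,
      sample_id = tab$sample[i], ...)
    simulate_chromatogram(spec)
  })
  names(out) <- tab$sample
  out
}
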