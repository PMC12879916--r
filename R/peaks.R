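# Baseline handling and window-based integration of mass-flow traces.

#' Estimate the mass-flow baseline from a blank region
#'
#' Median mass flow over a species-free region of the run. The default
#' blank window, 40-48 min, lies after SeAlb has eluted and before
#' re-equilibration of the 50 min method. The median keeps the estimate
#' robust to stray spikes in the blank region.
#'
#' @param mf A `mass_flow_trace`.
#' @param blank_window Numeric pair, window bounds in minutes.
#' @return Baseline mass flow, ng/min.
#' @export
estimate_baseline <- function(mf, blank_window = c(40, 48)) {
  stopifnot(inherits(mf, "mass_flow_trace"), length(blank_window) == 2)
  t_min <- mf$time_s / 60
  sel <- mf$valid & t_min >= blank_window[1] & t_min <= blank_window[2]
  if (sum(sel) < 5)
    stop(sprintf(paste0("blank window %g-%g min contains %d valid ",
                        "points; at least 5 required"),
                 blank_window[1], blank_window[2], sum(sel)))
  stats::median(mf$mass_flow[sel])
}

#' Integrate retention windows into per-species Se masses
#'
#' Trapezoidal integration of the baseline-subtracted mass-flow trace
#' over each fixed retention window; the integral of ng/min over
#' minutes is the absolute Se mass (ng) of the species. Negative
#' integrals (possible in all-baseline windows under noise) are clipped
#' to zero at the reporting stage, with the raw value retained and a
#' `clipped` flag raised. Windows in which more than `max_masked_frac`
#' of the points are masked are flagged `unreliable`.
#'
#' @param mf A `mass_flow_trace`.
#' @param windows A `species_windows` object.
#' @param baseline Baseline mass flow to subtract, ng/min (from
#'   [estimate_baseline()]).
#' @param max_masked_frac Masked-point fraction above which a window is
#'   flagged unreliable.
#' @return A data.frame of class `species_amounts` with columns
#'   `species`, `se_ng`, `raw_se_ng`, `window_start`, `window_end`,
#'   `baseline_ng_per_min`, `flags`.
#' @export
integrate_windows <- function(mf, windows, baseline = 0,
                              max_masked_frac = 0.2) {
  stopifnot(inherits(mf, "mass_flow_trace"),
            inherits(windows, "species_windows"))
  t_min <- mf$time_s / 60
  span <- range(t_min)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w0 <- windows$start_min[i]
    w1 <- windows$end_min[i]
    if (w0 < span[1] - 1e-9 || w1 > span[2] + 1e-9)
      stop(sprintf("window %s (%g-%g min) outside trace span %g-%g min",
                   windows$species[i], w0, w1, span[1], span[2]))
    idx <- t_min >= w0 & t_min <= w1
    masked_frac <- mean(!mf$valid[idx])
    sel <- idx & mf$valid
    raw <- if (sum(sel) >= 2) {
      pracma::trapz(t_min[sel], mf$mass_flow[sel] - baseline)
    } else NA_real_
    flags <- character(0)
    if (masked_frac > max_masked_frac) flags <- c(flags, "unreliable")
    se_ng <- raw
    if (!is.na(raw) && raw < 0) {
      se_ng <- 0
      flags <- c(flags, "clipped")
    }
    data.frame(species = windows$species[i],
               se_ng = se_ng,
               raw_se_ng = raw,
               window_start = w0,
               window_end = w1,
               baseline_ng_per_min = baseline,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("species_amounts", "data.frame")
  out
}

#' Convert Se masses to sample concentrations
#'
#' Normalises the on-column Se mass of each species to the sample mass
#' introduced: `conc = se_ng / sample_mass_g`, reported as ng Se/mL
#' under the serum-density-1 convention (0.1000 g of serum is 0.1 mL,
#' so ng/g and ng/mL coincide).
#'
#' @param amounts A `species_amounts` data.frame (or any data.frame with
#'   an `se_ng` column).
#' @param sample_mass_g Sample mass introduced, g (> 0).
#' @return `amounts` with an added `conc_ng_per_ml` column.
#' @export
to_concentration <- function(amounts, sample_mass_g) {
  if (!is.numeric(sample_mass_g) || sample_mass_g <= 0)
    stop("sample_mass_g must be positive")
  amounts$conc_ng_per_ml <- amounts$se_ng / sample_mass_g
  amounts
}
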