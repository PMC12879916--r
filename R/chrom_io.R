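# Chromatogram containers, delimited-text I/O and instrument configuration.

#' Construct an isotope chromatogram
#'
#' Container for one HPLC-ICP-MS injection: a common time axis plus one
#' intensity trace (counts per reading) per monitored Se isotope.
#'
#' @param time_s Numeric vector of acquisition times in seconds,
#'   strictly increasing.
#' @param counts Numeric matrix, one row per time point, one column per
#'   isotope; column names are isotope mass numbers ("74", "76", ...).
#'   Must contain at least the spike isotope 74 and the reference
#'   isotope 78. All values must be non-negative.
#' @param sample_id Sample identifier.
#' @param injection_volume_ml Injected volume in mL (0.1 mL for a
#'   100 uL serum injection).
#' @param sample_mass_g Sample mass introduced, in g, used for the final
#'   concentration normalisation.
#'
#' @return An object of class `isotope_chromatogram`: a list with
#'   elements `time_s`, `counts` and `metadata`.
#' @export
isotope_chromatogram <- function(time_s, counts,
                                 sample_id = NA_character_,
                                 injection_volume_ml = NA_real_,
                                 sample_mass_g = NA_real_) {
  time_s <- as.numeric(time_s)
  counts <- as.matrix(counts)
  if (length(time_s) == 0L)
    stop("chromatogram must contain at least one time point")
  if (any(diff(time_s) <= 0))
    stop("time axis must be strictly increasing")
  if (nrow(counts) != length(time_s))
    stop("intensity traces must have the same length as the time axis")
  if (is.null(colnames(counts)))
    stop("intensity columns must be named by isotope mass number")
  iso <- suppressWarnings(as.integer(colnames(counts)))
  if (anyNA(iso))
    stop("intensity column names must be isotope mass numbers, got: ",
         paste(colnames(counts), collapse = ", "))
  if (!all(c(74L, 78L) %in% iso))
    stop("chromatogram must include the spike isotope 74 and the ",
         "reference isotope 78")
  if (anyNA(counts) || any(counts < 0))
    stop("intensities must be non-negative and non-missing")
  structure(
    list(time_s = time_s,
         counts = counts,
         metadata = list(sample_id = sample_id,
                         injection_volume_ml = injection_volume_ml,
                         sample_mass_g = sample_mass_g)),
    class = "isotope_chromatogram")
}

#' @export
print.isotope_chromatogram <- function(x, ...) {
  cat("<isotope_chromatogram>",
      sprintf("sample: %s", x$metadata$sample_id),
      sprintf("time: %.1f-%.1f s (%d readings)",
              min(x$time_s), max(x$time_s), length(x$time_s)),
      sprintf("isotopes: %s", paste(colnames(x$counts), collapse = ", ")),
      sep = "\n")
  invisible(x)
}

#' Read a chromatogram from delimited text
#'
#' Expects a comma-delimited file with a `time_s` column followed by one
#' column per monitored isotope, named by mass number
#' (`time_s,74,76,77,78,80`). Negative intensities (possible after
#' detector blank subtraction in vendor exports) are clamped to zero;
#' the number of clamped cells is reported in a warning and stored in
#' the `n_clamped` attribute.
#'
#' @param path Path to the CSV file.
#' @param sample_id,injection_volume_ml,sample_mass_g Metadata passed to
#'   [isotope_chromatogram()]; `sample_id` defaults to the file name.
#' @return An `isotope_chromatogram` with attribute `n_clamped`.
#' @export
read_chromatogram <- function(path, sample_id = NULL,
                              injection_volume_ml = NA_real_,
                              sample_mass_g = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("chromatogram file must have a 'time_s' column: ", path)
  iso_cols <- setdiff(names(df), "time_s")
  iso <- suppressWarnings(as.integer(iso_cols))
  if (anyNA(iso))
    stop("non-isotope column in chromatogram file: ",
         paste(iso_cols[is.na(iso)], collapse = ", "))
  if (!all(c("74", "78") %in% iso_cols))
    stop("chromatogram file must contain columns 74 and 78 (spike and ",
         "reference isotopes): ", path)
  counts <- as.matrix(df[iso_cols])
  n_clamped <- sum(counts < 0)
  if (n_clamped > 0) {
    warning(sprintf("%d negative intensity value(s) clamped to 0 in %s",
                    n_clamped, path))
    counts[counts < 0] <- 0
  }
  if (is.null(sample_id)) sample_id <- basename(path)
  out <- isotope_chromatogram(df$time_s, counts, sample_id = sample_id,
                              injection_volume_ml = injection_volume_ml,
                              sample_mass_g = sample_mass_g)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Write a chromatogram to delimited text
#'
#' Inverse of [read_chromatogram()]; writing then reading a valid
#' chromatogram is the identity on the time axis and intensity traces.
#'
#' @param chrom An `isotope_chromatogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "isotope_chromatogram"))
  df <- data.frame(time_s = chrom$time_s, check.names = FALSE)
  df <- cbind(df, as.data.frame(chrom$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- retention windows -------------------------------------------------

#' Species retention windows
#'
#' Fixed-time integration windows, one per Se species, in minutes.
#' Windows must be ordered and non-overlapping (shared boundaries are
#' allowed); the chromatographic method is expected to resolve the five
#' serum species into these windows.
#'
#' @param species Character vector of species names.
#' @param start_min,end_min Numeric window bounds in minutes.
#' @return A data.frame of class `species_windows`.
#' @export
species_windows <- function(species, start_min, end_min) {
  df <- data.frame(species = as.character(species),
                   start_min = as.numeric(start_min),
                   end_min = as.numeric(end_min),
                   stringsAsFactors = FALSE)
  if (any(df$end_min <= df$start_min))
    stop("each window must have end > start")
  if (anyDuplicated(df$species))
    stop("duplicated species name in windows")
  if (is.unsorted(df$start_min, strictly = TRUE))
    stop("windows must be listed in elution order")
  if (nrow(df) > 1) {
    bad <- which(df$start_min[-1] < df$end_min[-nrow(df)])
    if (length(bad) > 0)
      stop(sprintf("overlapping windows: %s (%g-%g) and %s (%g-%g)",
                   df$species[bad[1]], df$start_min[bad[1]],
                   df$end_min[bad[1]],
                   df$species[bad[1] + 1], df$start_min[bad[1] + 1],
                   df$end_min[bad[1] + 1]))
  }
  class(df) <- c("species_windows", "data.frame")
  df
}

#' Default serum selenoprotein windows
#'
#' Retention windows for the optimized SEC-affinity column-switching
#' separation: GPx elutes near 3 min, selenometabolites (SMT) near
#' 5 min, SELENOP near 20 min, the SELENOW-containing fraction near
#' 25 min, and SeAlb near 31 min of the 50 min run.
#'
#' @return A `species_windows` object with five windows.
#' @export
default_species_windows <- function() {
  species_windows(
    species   = .species_levels,
    start_min = c(2, 4, 15, 23, 28),
    end_min   = c(4, 8, 23, 28, 35))
}

#' Load retention windows from a YAML config
#'
#' The config maps species names to `[start_min, end_min]` pairs under a
#' top-level `windows` key, e.g. `windows: {GPx: [2, 4], SMT: [4, 8]}`.
#'
#' @param path Path to the YAML file.
#' @return A `species_windows` object.
#' @export
load_windows <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$windows))
    stop("windows config must have a top-level 'windows' key: ", path)
  w <- cfg$windows
  species_windows(species = names(w),
                  start_min = vapply(w, function(x) as.numeric(x[[1]]), 0),
                  end_min   = vapply(w, function(x) as.numeric(x[[2]]), 0))
}

#' Write retention windows to a YAML config
#' @param windows A `species_windows` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  stopifnot(inherits(windows, "species_windows"))
  w <- lapply(seq_len(nrow(windows)),
              function(i) c(windows$start_min[i], windows$end_min[i]))
  names(w) <- windows$species
  yaml::write_yaml(list(windows = w), path)
  invisible(path)
}

# --- IDA parameters ----------------------------------------------------

#' Isotope-dilution (IDA) parameters
#'
#' Everything the species-unspecific online isotope-dilution equation
#' needs: the post-column spike (concentration, flow, isotopic
#' composition) and the natural Se composition of the analyte.
#'
#' Abundance vectors are named by isotope mass number, cover all six
#' stable Se isotopes and must each sum to 1 within 1e-6. The spike
#' atomic weight is computed from the spike abundances and the bundled
#' isotope masses; if supplied explicitly it must agree with that sum
#' within 0.01 u.
#'
#' @param spike_concentration Spike Se concentration, ng/mL.
#' @param spike_flow Spike flow merged at the T-piece, mL/min.
#' @param spike_abundances Named numeric vector of spike isotopic
#'   abundances (default: 99.9% 74Se, 0.1% 78Se).
#' @param natural_abundances Named numeric vector of natural Se
#'   abundances (default: bundled IUPAC values).
#' @param atomic_weight_natural Natural Se atomic weight, g/mol.
#' @param atomic_weight_spike Spike atomic weight, g/mol; computed from
#'   the abundances when `NULL`.
#' @param reference_isotope,spike_isotope Mass numbers of the reference
#'   (78) and spike (74) isotopes used in the measured ratio.
#' @return An object of class `ida_parameters`.
#' @export
#' @examples
#' ida <- ida_parameters()
#' ida$spike_mass_flow   # ng spike Se per minute entering the plasma
ida_parameters <- function(spike_concentration = 100,
                           spike_flow = 0.1,
                           spike_abundances = NULL,
                           natural_abundances = NULL,
                           atomic_weight_natural = .se_atomic_weight,
                           atomic_weight_spike = NULL,
                           reference_isotope = 78L,
                           spike_isotope = 74L) {
  iso_names <- as.character(.se_isotopes$isotope)
  if (is.null(natural_abundances)) {
    natural_abundances <- stats::setNames(.se_isotopes$abundance, iso_names)
  }
  if (is.null(spike_abundances)) {
    spike_abundances <- stats::setNames(rep(0, length(iso_names)), iso_names)
    spike_abundances["74"] <- 0.999
    spike_abundances["78"] <- 0.001
  }
  check_abundances <- function(a, what) {
    if (is.null(names(a)))
      stop(what, " abundances must be named by isotope mass number")
    if (abs(sum(a) - 1) > 1e-6)
      stop(sprintf("%s abundances sum to %.6f, expected 1 within 1e-6",
                   what, sum(a)))
    if (any(a < 0)) stop(what, " abundances must be non-negative")
    a
  }
  spike_abundances <- check_abundances(spike_abundances, "spike")
  natural_abundances <- check_abundances(natural_abundances, "natural")
  ref <- as.character(reference_isotope)
  spk <- as.character(spike_isotope)
  for (k in c(ref, spk)) {
    if (!(k %in% names(spike_abundances)) ||
        !(k %in% names(natural_abundances)))
      stop("abundance vectors must include isotope ", k)
  }
  if (spike_concentration <= 0 || spike_flow <= 0)
    stop("spike concentration and flow must be positive")
  masses <- stats::setNames(.se_isotopes$mass, iso_names)
  aw_sp_calc <- sum(spike_abundances[iso_names] * masses)
  if (is.null(atomic_weight_spike)) {
    atomic_weight_spike <- aw_sp_calc
  } else if (abs(atomic_weight_spike - aw_sp_calc) > 0.01) {
    stop(sprintf(paste0("atomic_weight_spike (%.4f) inconsistent with ",
                        "abundance-weighted isotope masses (%.4f)"),
                 atomic_weight_spike, aw_sp_calc))
  }
  structure(
    list(spike_concentration = spike_concentration,
         spike_flow = spike_flow,
         spike_mass_flow = spike_concentration * spike_flow,
         spike_abundances = spike_abundances,
         natural_abundances = natural_abundances,
         atomic_weight_natural = atomic_weight_natural,
         atomic_weight_spike = atomic_weight_spike,
         reference_isotope = as.integer(reference_isotope),
         spike_isotope = as.integer(spike_isotope)),
    class = "ida_parameters")
}

#' @export
print.ida_parameters <- function(x, ...) {
  cat("<ida_parameters>",
      sprintf("spike: %.4g ng/mL at %.4g mL/min (%.4g ng Se/min)",
              x$spike_concentration, x$spike_flow, x$spike_mass_flow),
      sprintf("ratio: %d/%d, R_spike = %.6g",
              x$reference_isotope, x$spike_isotope,
              x$spike_abundances[as.character(x$reference_isotope)] /
                x$spike_abundances[as.character(x$spike_isotope)]),
      sep = "\n")
  invisible(x)
}

#' Load IDA parameters from a YAML config
#'
#' Keys mirror the arguments of [ida_parameters()]; abundance maps use
#' quoted isotope mass numbers, e.g.
#' `spike_abundances: {"74": 0.999, "78": 0.001}`.
#'
#' @param path Path to the YAML file.
#' @return An `ida_parameters` object.
#' @export
load_ida <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_ab <- function(x) if (is.null(x)) NULL else unlist(x)
  ida_parameters(
    spike_concentration = cfg$spike_concentration %||% 100,
    spike_flow = cfg$spike_flow %||% 0.1,
    spike_abundances = as_ab(cfg$spike_abundances),
    natural_abundances = as_ab(cfg$natural_abundances),
    atomic_weight_natural = cfg$atomic_weight_natural %||% .se_atomic_weight,
    atomic_weight_spike = cfg$atomic_weight_spike,
    reference_isotope = cfg$reference_isotope %||% 78L,
    spike_isotope = cfg$spike_isotope %||% 74L)
}

#' Write IDA parameters to a YAML config
#' @param ida An `ida_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ida <- function(ida, path) {
  stopifnot(inherits(ida, "ida_parameters"))
  yaml::write_yaml(
    list(spike_concentration = ida$spike_concentration,
         spike_flow = ida$spike_flow,
         spike_abundances = as.list(ida$spike_abundances),
         natural_abundances = as.list(ida$natural_abundances),
         atomic_weight_natural = ida$atomic_weight_natural,
         atomic_weight_spike = ida$atomic_weight_spike,
         reference_isotope = ida$reference_isotope,
         spike_isotope = ida$spike_isotope),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
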