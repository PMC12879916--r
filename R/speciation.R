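# Cohort speciation tables: aggregate statistics, percent composition,
# Se-atom stoichiometry conversion and method-validation figures.

#' Round half away from zero
#'
#' Commercial rounding as used in the reported speciation tables:
#' `round_half_out(3.55, 1)` is 3.6, whereas base R's banker's rounding
#' gives 3.5 (the report convention of this package is half away from
#' zero).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble a speciation table
#'
#' One row per serum sample, one column per species (ng Se/mL) plus
#' their sum. The `sum_of_species` column must agree with the row sum of
#' the five species within `tol` (0.02 ng/mL by default, the slack left
#' by tables whose inputs were rounded to two decimals).
#'
#' @param df Data.frame with columns `sample`, `GPx`, `SMT`, `SELENOP`,
#'   `SELENOW_plus_others`, `SeAlb` and optionally `sum_of_species`
#'   (computed as the row sum when absent).
#' @param tol Allowed absolute discrepancy between `sum_of_species` and
#'   the row sum.
#' @return A data.frame of class `speciation_table`.
#' @export
speciation_table <- function(df, tol = 0.02) {
  need <- c("sample", .species_levels)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("speciation table missing columns: ", paste(miss, collapse = ", "))
  rs <- rowSums(df[.species_levels])
  if (!"sum_of_species" %in% names(df)) {
    df$sum_of_species <- rs
  } else {
    bad <- which(abs(df$sum_of_species - rs) > tol + 1e-9)
    if (length(bad) > 0)
      stop(sprintf(paste0("sum_of_species disagrees with row sum beyond ",
                          "%g in row(s): %s"),
                   tol, paste(df$sample[bad], collapse = ", ")))
  }
  df <- df[c("sample", .species_levels, "sum_of_species")]
  class(df) <- c("speciation_table", "data.frame")
  df
}

#' Reported chicken-serum selenoprotein concentrations
#'
#' The 13-sample chicken-serum speciation table bundled with the
#' package (ng Se/mL for GPx, selenometabolites, SELENOP, the
#' SELENOW-containing fraction and SeAlb, plus the reported sum). These
#' values serve both as the reference output of the quantification
#' pipeline and as ground-truth inputs for the cohort simulator.
#'
#' @return A `speciation_table` with 13 rows.
#' @export
#' @examples
#' head(chicken_serum_selenoproteins())
chicken_serum_selenoproteins <- function() {
  path <- system.file("extdata", "chicken_serum_cohort.csv",
                      package = "selenoquant", mustWork = TRUE)
  speciation_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Aggregate a speciation table
#'
#' Per-column average, standard deviation (n-1 denominator), standard
#' error of the mean, maximum and minimum. The `report` element rounds
#' every statistic half-away-from-zero to `digits` decimals, the
#' convention of the reported table; `raw` keeps full precision.
#'
#' @param table A `speciation_table` (n >= 2 rows).
#' @param digits Decimal places for the report rounding.
#' @return A list of class `speciation_aggregate` with elements `raw`
#'   and `report`, each a data.frame with a `statistic` column and one
#'   column per species.
#' @export
aggregate_speciation <- function(table, digits = 1) {
  stopifnot(inherits(table, "speciation_table"))
  if (nrow(table) < 2)
    stop("aggregate statistics require at least 2 samples")
  cols <- c(.species_levels, "sum_of_species")
  x <- as.matrix(table[cols])
  n <- nrow(x)
  raw <- rbind(average = colMeans(x),
               SD      = apply(x, 2, stats::sd),
               SEM     = apply(x, 2, stats::sd) / sqrt(n),
               maximum = apply(x, 2, max),
               minimum = apply(x, 2, min))
  as_df <- function(m) {
    data.frame(statistic = rownames(m), as.data.frame(m),
               row.names = NULL, check.names = FALSE)
  }
  structure(list(raw = as_df(raw),
                 report = as_df(round_half_out(raw, digits)),
                 n = n),
            class = "speciation_aggregate")
}

#' @export
print.speciation_aggregate <- function(x, ...) {
  cat(sprintf("<speciation_aggregate> n = %d samples\n", x$n))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Percent composition of serum Se
#'
#' Share of total serum Se carried by each species: 100 x the
#' full-precision column mean over the full-precision mean of the sum
#' column, rounded to the nearest integer (half away from zero) only at
#' the end.
#'
#' @param table A `speciation_table`.
#' @return Named integer vector of percentages, one per species.
#' @export
#' @examples
#' percent_composition(chicken_serum_selenoproteins())
percent_composition <- function(table) {
  stopifnot(inherits(table, "speciation_table"))
  m <- colMeans(as.matrix(table[c(.species_levels, "sum_of_species")]))
  if (m[["sum_of_species"]] <= 0)
    stop("mean sum of species must be positive")
  pct <- 100 * m[.species_levels] / m[["sum_of_species"]]
  stats::setNames(as.integer(round_half_out(pct, 0)), .species_levels)
}

#' Se-atom stoichiometry of the serum species
#'
#' Selenium stoichiometry fixtures used to convert Se concentration to
#' protein concentration: number of Se atoms per molecule and an
#' assumed molar mass. SELENOP carries 13 selenocysteines in chicken;
#' GPx one Se atom per subunit. The molar masses are package fixtures
#' back-derived to be consistent with the bundled concentration table
#' (the proteins' exact serum masses vary with isoform and
#' glycosylation), not independently certified values. SeAlb and the
#' SELENOW-containing fraction have no fixed Se:protein stoichiometry
#' (nonspecifically incorporated Se, unresolved mixture) and are marked
#' non-stoichiometric, as are the selenometabolites.
#'
#' @return A data.frame with columns `species`, `n_se_atoms`,
#'   `molar_mass_gmol`, `stoichiometric`, `note`.
#' @export
protein_se_stoichiometry <- function() {
  path <- system.file("extdata", "protein_se_stoichiometry.csv",
                      package = "selenoquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert a Se concentration to a protein concentration
#'
#' Linear Se-atom stoichiometry conversion:
#' `protein mg/L = conc_ng_ml * molar_mass / (n_se_atoms * 78.971) / 1000`
#' (ng/mL of Se is ug/L; dividing by the Se atomic weight and the
#' number of Se atoms per molecule gives umol protein/L, which the
#' molar mass turns into mg/L). Species without a fixed Se:protein
#' stoichiometry are refused: for SeAlb the Se is bound nonspecifically
#' to albumin, and the SELENOW-containing fraction may hold several Se
#' species, so no protein concentration can be attributed.
#'
#' @param conc_ng_ml Se concentration, ng/mL.
#' @param species Species name, used to look up
#'   [protein_se_stoichiometry()]; alternatively pass `n_se_atoms` and
#'   `molar_mass` directly with `species = NULL`.
#' @param n_se_atoms Number of Se atoms per protein molecule.
#' @param molar_mass Protein molar mass, g/mol.
#' @return Protein concentration, mg/L.
#' @export
#' @examples
#' se_to_protein(59.2, n_se_atoms = 13, molar_mass = 49985)
se_to_protein <- function(conc_ng_ml, species = NULL,
                          n_se_atoms = NULL, molar_mass = NULL) {
  if (!is.null(species)) {
    st <- protein_se_stoichiometry()
    row <- st[st$species == species, ]
    if (nrow(row) == 0)
      stop("unknown species: ", species)
    if (!row$stoichiometric)
      stop(sprintf(paste0("the protein concentration of %s cannot be ",
                          "determined: %s"), species, row$note))
    n_se_atoms <- row$n_se_atoms
    molar_mass <- row$molar_mass_gmol
  }
  if (is.null(n_se_atoms) || is.null(molar_mass))
    stop("supply either a stoichiometric species or both n_se_atoms ",
         "and molar_mass")
  if (n_se_atoms < 1) stop("n_se_atoms must be >= 1")
  if (molar_mass <= 0) stop("molar_mass must be positive")
  conc_ng_ml * molar_mass / (n_se_atoms * .se_atomic_weight) / 1000
}

#' Method-validation statistics
#'
#' Standard figures of merit for the speciation method: recovery
#' against a certified reference material and blank-based detection
#' limits (`LOD = 3 * SD_blank`, `LOQ = 10 * SD_blank`, in the units of
#' the blank amounts).
#'
#' @param measured Measured amount or concentration.
#' @param certified Certified value (> 0).
#' @param blank_amounts Numeric vector of at least 3 blank replicate
#'   amounts.
#' @return A list with `recovery_pct`, `lod`, `loq`, `sd_blank`.
#' @export
validation_stats <- function(measured, certified, blank_amounts) {
  if (certified <= 0) stop("certified value must be positive")
  if (length(blank_amounts) < 3)
    stop("at least 3 blank replicates required for LOD/LOQ")
  s <- stats::sd(blank_amounts)
  list(recovery_pct = 100 * measured / certified,
       lod = 3 * s,
       loq = 10 * s,
       sd_blank = s)
}
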