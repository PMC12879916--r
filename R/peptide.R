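# Bottom-up identification support: in-silico tryptic digestion,
# peptide masses with modifications, mass-list matching, sequence
# coverage and b/y fragment ladders.

.aa_alphabet <- names(.aa_mono)

#' Read protein sequences from FASTA
#'
#' Sequences over the 20 standard amino acids plus selenocysteine (U).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue sequences.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
  for (i in seq_along(seqs)) .check_sequence(seqs[[i]], names(seqs)[i])
  seqs
}

.check_sequence <- function(sequence, id = "protein") {
  if (nchar(sequence) == 0) stop("empty sequence: ", id)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), .aa_alphabet)
  if (length(bad) > 0)
    stop(sprintf("unknown residue(s) %s in %s",
                 paste(bad, collapse = ", "), id))
  invisible(res)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and
#' enumerates every peptide carrying 0 to `max_missed` missed
#' cleavages, with 1-based inclusive positions in the parent.
#'
#' @param sequence Protein residue sequence (character scalar).
#' @param max_missed Maximum number of missed cleavages.
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missed`.
#' @export
#' @examples
#' digest("AKRPGR")           # no cleavage at R before P
#' digest("AKR", max_missed = 1)
digest <- function(sequence, max_missed = 0L) {
  res <- .check_sequence(sequence)
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[sites + 1] != "P"]
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  nfrag <- length(starts)
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      if (i + m > nfrag) break
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste(res[starts[i]:ends[i + m]], collapse = ""),
        start = starts[i], end = ends[i + m], missed = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.resolve_mods <- function(mods, custom) {
  tab <- .modifications
  if (!is.null(custom)) {
    need <- c("name", "target", "mono", "avg")
    if (!all(need %in% names(custom)))
      stop("custom modification table needs columns: ",
           paste(need, collapse = ", "))
    tab <- rbind(tab, custom[need])
  }
  unknown <- setdiff(mods, tab$name)
  if (length(unknown) > 0)
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  tab[tab$name %in% mods, , drop = FALSE]
}

#' Peptide mass with modifications
#'
#' Sum of residue masses plus water, plus the mass delta of each
#' requested modification applied at every occurrence of its target
#' residue. Bundled modifications: `"carbamidomethyl"` (+57.02146 Da
#' on C, monoisotopic) and `"sec_to_dha"` (-81.93217 Da on U, the loss
#' of H2Se when selenocysteine degrades to dehydroalanine); others can
#' be registered through `custom`.
#'
#' @param sequence Peptide residue sequence.
#' @param mods Character vector of modification names to apply.
#' @param kind `"mono"` (monoisotopic, default) or `"average"`.
#' @param custom Optional data.frame with columns `name`, `target`,
#'   `mono`, `avg` registering additional mass deltas.
#' @return Peptide mass in Da.
#' @export
#' @examples
#' peptide_mass("G")                              # 75.03203
#' peptide_mass("UGC", mods = c("carbamidomethyl", "sec_to_dha"))
peptide_mass <- function(sequence, mods = character(0),
                         kind = c("mono", "average"), custom = NULL) {
  kind <- match.arg(kind)
  res <- .check_sequence(sequence)
  masses <- if (kind == "mono") .aa_mono else .aa_avg
  water <- if (kind == "mono") .water_mono else .water_avg
  m <- sum(masses[res]) + water
  mt <- .resolve_mods(mods, custom)
  for (i in seq_len(nrow(mt))) {
    delta <- if (kind == "mono") mt$mono[i] else mt$avg[i]
    m <- m + delta * sum(res == mt$target[i])
  }
  m
}

#' Theoretical masses for a digest
#'
#' Adds a `mass` column to a digest table. Fixed modifications are
#' applied to every peptide; each variable modification, when its
#' target residue is present, duplicates the peptide row with the
#' modified mass (`modified` column records which were applied).
#'
#' @param digested Output of [digest()].
#' @param fixed_mods,variable_mods Character vectors of modification
#'   names.
#' @param kind,custom Passed to [peptide_mass()].
#' @return The digest data.frame with `mass` and `modified` columns.
#' @export
add_peptide_masses <- function(digested,
                               fixed_mods = "carbamidomethyl",
                               variable_mods = "sec_to_dha",
                               kind = "mono", custom = NULL) {
  mt <- .resolve_mods(c(fixed_mods, variable_mods), custom)
  rows <- lapply(seq_len(nrow(digested)), function(i) {
    pep <- digested[i, , drop = FALSE]
    base <- pep
    base$mass <- peptide_mass(pep$peptide, mods = fixed_mods,
                              kind = kind, custom = custom)
    base$modified <- paste(fixed_mods, collapse = ";")
    out <- base
    for (vm in variable_mods) {
      target <- mt$target[mt$name == vm]
      if (grepl(target, pep$peptide, fixed = TRUE)) {
        alt <- pep
        alt$mass <- peptide_mass(pep$peptide,
                                 mods = c(fixed_mods, vm),
                                 kind = kind, custom = custom)
        alt$modified <- paste(c(fixed_mods, vm), collapse = ";")
        out <- rbind(out, alt)
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Match observed masses to a theoretical digest
#'
#' Greedy one-to-one matching by ascending ppm error within
#' `tol_ppm`: candidate (peptide, observed mass) pairs are ranked by
#' absolute ppm error, ties broken by fewer missed cleavages then by
#' earlier start position; each observed mass and each peptide row is
#' used at most once. An empty observed list yields a zero-coverage
#' result, not an error.
#'
#' @param theoretical Digest table with a `mass` column (see
#'   [add_peptide_masses()]).
#' @param observed Numeric vector of observed deconvoluted masses, Da.
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param protein_length Length of the parent protein, residues; needed
#'   for the coverage fraction.
#' @param protein_id Identifier recorded on the result.
#' @param thresholds Passed to [coverage_and_tier()].
#' @return A `peptide_match_result`: list with `protein_id`,
#'   `protein_length`, `matches` (data.frame `peptide`, `start`, `end`,
#'   `missed`, `theoretical`, `observed`, `ppm`), `coverage_fraction`,
#'   `coverage_pct`, `tier`.
#' @export
match_masses <- function(theoretical, observed, tol_ppm = 20,
                         protein_length, protein_id = NA_character_,
                         thresholds = c(partial = 0.60, confirm = 0.85)) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (!"mass" %in% names(theoretical))
    stop("theoretical table must have a 'mass' column; see ",
         "add_peptide_masses()")
  cand <- NULL
  if (length(observed) > 0 && nrow(theoretical) > 0) {
    grid <- expand.grid(pep = seq_len(nrow(theoretical)),
                        obs = seq_along(observed))
    ppm <- (observed[grid$obs] - theoretical$mass[grid$pep]) /
      theoretical$mass[grid$pep] * 1e6
    keep <- abs(ppm) <= tol_ppm
    cand <- data.frame(pep = grid$pep[keep], obs = grid$obs[keep],
                       ppm = ppm[keep])
  }
  matches <- theoretical[0, , drop = FALSE]
  matches$theoretical <- numeric(0)
  matches$observed <- numeric(0)
  matches$ppm <- numeric(0)
  if (!is.null(cand) && nrow(cand) > 0) {
    ord <- order(abs(cand$ppm), theoretical$missed[cand$pep],
                 theoretical$start[cand$pep])
    cand <- cand[ord, ]
    used_pep <- rep(FALSE, nrow(theoretical))
    used_obs <- rep(FALSE, length(observed))
    rows <- list()
    for (i in seq_len(nrow(cand))) {
      p <- cand$pep[i]
      o <- cand$obs[i]
      if (used_pep[p] || used_obs[o]) next
      used_pep[p] <- TRUE
      used_obs[o] <- TRUE
      row <- theoretical[p, , drop = FALSE]
      row$theoretical <- row$mass
      row$observed <- observed[o]
      row$ppm <- cand$ppm[i]
      rows[[length(rows) + 1L]] <- row
    }
    matches <- do.call(rbind, rows)
    matches <- matches[order(matches$start, matches$end), , drop = FALSE]
  }
  matches$mass <- NULL
  res <- structure(list(protein_id = protein_id,
                        protein_length = protein_length,
                        matches = matches,
                        coverage_fraction = NA_real_,
                        coverage_pct = NA_real_,
                        tier = NA_character_),
                   class = "peptide_match_result")
  coverage_and_tier(res, thresholds = thresholds)
}

#' Sequence coverage and confirmation tier
#'
#' Coverage is the size of the union of matched residue intervals
#' divided by the protein length. Tiers follow the confirmation scheme
#' used for serum selenoprotein identification: below 60% coverage a
#' protein is `not_confirmed`; from 60% up to the confirmation
#' threshold it is `partially_confirmed`; at or above the threshold
#' (default 85%) it is `confirmed`.
#'
#' @param result A `peptide_match_result`.
#' @param thresholds Named numeric vector `c(partial =, confirm =)` of
#'   ordered coverage fractions.
#' @return The result with `coverage_fraction`, `coverage_pct`
#'   (rounded to 2 decimals) and `tier` filled in.
#' @export
coverage_and_tier <- function(result,
                              thresholds = c(partial = 0.60,
                                             confirm = 0.85)) {
  stopifnot(inherits(result, "peptide_match_result"))
  if (!all(c("partial", "confirm") %in% names(thresholds)) ||
      thresholds[["partial"]] >= thresholds[["confirm"]])
    stop("thresholds must satisfy partial < confirm")
  cov <- .interval_coverage(result$matches$start, result$matches$end) /
    result$protein_length
  result$coverage_fraction <- cov
  result$coverage_pct <- round_half_out(100 * cov, 2)
  result$tier <- if (cov < thresholds[["partial"]]) {
    "not_confirmed"
  } else if (cov < thresholds[["confirm"]]) {
    "partially_confirmed"
  } else {
    "confirmed"
  }
  result
}

# Total number of residues covered by the union of [start, end]
# intervals.
.interval_coverage <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  total <- 0L
  cur_s <- start[1]
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' @export
print.peptide_match_result <- function(x, ...) {
  cat("<peptide_match_result>",
      sprintf("protein: %s (%d residues)", x$protein_id,
              x$protein_length),
      sprintf("matched peptides: %d", nrow(x$matches)),
      sprintf("coverage: %.2f%% -> %s", x$coverage_pct, x$tier),
      sep = "\n")
  invisible(x)
}

#' b/y fragment-ion ladder
#'
#' Monoisotopic b- and y-ion m/z series of a peptide at a given charge:
#' the neutral b fragment is the sum of its residues, the neutral y
#' fragment adds water, and `m/z = (neutral + z * proton) / z`.
#' Modification deltas are applied at the residues they target before
#' the ladders are accumulated.
#'
#' @param sequence Peptide residue sequence (>= 2 residues).
#' @param charge Positive integer charge state.
#' @param mods,custom As in [peptide_mass()].
#' @return A data.frame with columns `ion` ("b"/"y"), `index`, `mz`.
#' @export
#' @examples
#' fragment_ladder("GG")   # y1 = 76.03931
fragment_ladder <- function(sequence, charge = 1L, mods = character(0),
                            custom = NULL) {
  if (charge < 1) stop("charge must be >= 1")
  res <- .check_sequence(sequence)
  n <- length(res)
  if (n < 2) stop("fragment ladder needs at least 2 residues")
  rmass <- .aa_mono[res]
  mt <- .resolve_mods(mods, custom)
  for (i in seq_len(nrow(mt)))
    rmass[res == mt$target[i]] <- rmass[res == mt$target[i]] + mt$mono[i]
  b_neutral <- cumsum(rmass)[-n]
  y_neutral <- cumsum(rev(rmass))[-n] + .water_mono
  mz <- function(neutral) (neutral + charge * .proton_mass) / charge
  data.frame(
    ion = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), seq_len(n - 1L)),
    mz = c(mz(b_neutral), mz(y_neutral)),
    stringsAsFactors = FALSE)
}

#' Read an observed mass list
#'
#' One deconvoluted mass (Da) per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path Path to the text file.
#' @return Numeric vector of masses.
#' @export
read_mass_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  masses <- suppressWarnings(as.numeric(lines))
  if (anyNA(masses))
    stop("non-numeric entries in mass list: ", path)
  masses
}

#' Digest a protein and score observed masses against it
#'
#' Convenience wrapper chaining [digest()], [add_peptide_masses()] and
#' [match_masses()] for one protein.
#'
#' @param sequence Protein residue sequence.
#' @param observed Numeric vector of observed deconvoluted masses, Da.
#' @param max_missed Maximum missed cleavages.
#' @param tol_ppm Mass tolerance, ppm.
#' @param protein_id Identifier recorded on the result.
#' @param fixed_mods,variable_mods,kind,custom See
#'   [add_peptide_masses()].
#' @param thresholds See [coverage_and_tier()].
#' @return A `peptide_match_result`.
#' @export
digest_and_match <- function(sequence, observed, max_missed = 0L,
                             tol_ppm = 20, protein_id = NA_character_,
                             fixed_mods = "carbamidomethyl",
                             variable_mods = "sec_to_dha",
                             kind = "mono", custom = NULL,
                             thresholds = c(partial = 0.60,
                                            confirm = 0.85)) {
  theo <- add_peptide_masses(digest(sequence, max_missed),
                             fixed_mods = fixed_mods,
                             variable_mods = variable_mods,
                             kind = kind, custom = custom)
  match_masses(theo, observed, tol_ppm = tol_ppm,
               protein_length = nchar(sequence),
               protein_id = protein_id, thresholds = thresholds)
}
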