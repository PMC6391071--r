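## Native-MS arithmetic: average masses of proteins and ssDNA, expected
## complex masses, delta/% error against measured values, bounded
## stoichiometry decomposition, and consecutive-charge-series mass
## inference. All masses are average masses (Da), the appropriate scale
## for intact non-covalent assemblies of hundreds of kDa.

#' Average mass of a protein from its one-letter sequence
#'
#' Sum of average residue masses plus one water; with
#' \code{n_terminal_met_loss = TRUE} the leading Met residue mass is
#' subtracted (co-translational Met excision, near-universal when the
#' second residue is small).
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param n_terminal_met_loss drop the leading methionine residue mass.
#' @return mass in Da.
#' @examples
#' proteinAverageMass("G")    # 75.07, free glycine
#' @export
proteinAverageMass <- function(sequence, n_terminal_met_loss = FALSE) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(aaResidueMasses))
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  m <- sum(aaResidueMasses[aa]) + waterMass
  if (n_terminal_met_loss) {
    if (aa[1] != "M") stop("n_terminal_met_loss set but sequence has no leading M")
    m <- m - aaResidueMasses["M"]
  }
  unname(m)
}

#' Average mass of single-stranded DNA
#'
#' Sum of deoxynucleotide-monophosphate residue masses plus one water
#' gives a 5'-phosphate / 3'-OH strand; a 5'-OH terminus removes one HPO3
#' (79.98 Da) and a 3'-phosphate adds one. The 43-mer derived from the
#' lambda-origin DNA unwinding element (\code{\link{oriLambdaDUE43}}) with
#' both termini OH comes to 13,141 Da.
#'
#' @param sequence ACGT string.
#' @param five_prime,three_prime terminal chemistry, "OH" or "phosphate".
#' @return mass in Da.
#' @examples
#' round(ssdnaAverageMass(oriLambdaDUE43))        # 13141
#' ssdnaAverageMass("T")                          # thymidine, ~242.2
#' @export
ssdnaAverageMass <- function(sequence, five_prime = c("OH", "phosphate"),
                             three_prime = c("OH", "phosphate")) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  if (!nzchar(sequence)) stop("empty sequence")
  nt <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(nt, names(dnaResidueMasses))
  if (length(bad))
    stop("non-ACGT character(s): ", paste(unique(bad), collapse = ", "))
  m <- sum(dnaResidueMasses[nt]) + waterMass
  if (five_prime == "OH") m <- m - hpo3Mass
  if (three_prime == "phosphate") m <- m + hpo3Mass
  unname(m)
}

#' Expected mass of a complex
#'
#' Linear combination \code{sum(count * monomer_mass)} over components.
#'
#' @param monomer_masses named numeric vector of component monomer masses
#'   (Da).
#' @param counts numeric vector of copy numbers (>= 0), recycled against
#'   \code{monomer_masses} by name when named.
#' @return mass in Da.
#' @examples
#' complexMass(c(DnaB = 52259, lambdaP = 26518), c(DnaB = 6, lambdaP = 5))
#' @export
complexMass <- function(monomer_masses, counts) {
  if (length(monomer_masses) == 0) return(0)
  if (!is.null(names(counts)) && !is.null(names(monomer_masses)))
    counts <- counts[names(monomer_masses)]
  stopifnot(length(counts) == length(monomer_masses), all(counts >= 0))
  sum(counts * monomer_masses)
}

#' Mass error of a measured vs expected mass
#'
#' @param measured,expected masses in Da (\code{expected > 0}).
#' @return list with \code{delta} (measured - expected, Da),
#'   \code{percent} (|delta|/expected * 100), \code{ppm}.
#' @export
massError <- function(measured, expected) {
  if (any(expected <= 0)) stop("expected mass must be positive")
  delta <- measured - expected
  list(delta = delta, percent = abs(delta) / expected * 100,
       ppm = abs(delta) / expected * 1e6)
}

#' Exhaustive stoichiometry decomposition of a measured mass
#'
#' Enumerates every composition within the per-component count bounds,
#' keeps those whose expected mass lies within \code{tolerance} of the
#' measured mass, and ranks by |delta| ascending with ties broken by fewer
#' total subunits, then lexicographically by component order. With wide
#' tolerance this reproduces manual native-MS assignment: the top hit is
#' the closest-mass composition.
#'
#' @param measured measured mass, Da.
#' @param components data.frame with columns \code{name},
#'   \code{monomer_mass}, \code{count_min}, \code{count_max}.
#' @param tolerance acceptance window in Da (default Inf: rank everything).
#' @return data.frame: one count column per component, then
#'   \code{expected_mass}, \code{delta}, \code{percent_error}, \code{ppm},
#'   ranked best-first.
#' @examples
#' comps <- data.frame(name = c("DnaB", "lambdaP"),
#'                     monomer_mass = c(52259, 26518),
#'                     count_min = c(0, 0), count_max = c(6, 8))
#' head(decomposeMass(446500, comps, tolerance = 500), 3)
#' @export
decomposeMass <- function(measured, components, tolerance = Inf) {
  if (nrow(components) == 0) stop("empty component list")
  if (any(!is.finite(components$count_max)))
    stop("unbounded count ranges: count_max must be finite")
  if (any(components$count_min < 0 |
          components$count_min > components$count_max))
    stop("invalid count range")
  grid <- do.call(expand.grid, c(
    stats::setNames(
      lapply(seq_len(nrow(components)),
             function(i) components$count_min[i]:components$count_max[i]),
      components$name),
    KEEP.OUT.ATTRS = FALSE))
  expected <- as.matrix(grid) %*% components$monomer_mass
  delta <- measured - expected
  keep <- abs(delta) <= tolerance
  out <- grid[keep, , drop = FALSE]
  out$expected_mass <- expected[keep]
  out$delta <- delta[keep]
  out$percent_error <- ifelse(out$expected_mass > 0,
                              abs(out$delta) / out$expected_mass * 100, NA)
  out$ppm <- out$percent_error * 1e4
  total <- rowSums(out[, components$name, drop = FALSE])
  ord <- do.call(order, c(list(abs(out$delta), total),
                          unname(out[, components$name, drop = FALSE])))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer a mass from a consecutive charge-state peak series
#'
#' Standard electrospray charge-series arithmetic: peaks are sorted by
#' decreasing m/z; for the adjacent pair (m1 > m2) the charge of the lower
#' peak is \code{z2 = round((m1 - A)/(m1 - m2))} with A the adduct mass,
#' charges then increase by one per subsequent peak, and each peak yields
#' a mass estimate \code{M = z (m - A)}. The mean and SD over peaks are
#' returned; per-peak residuals flag corrupted peaks, and a series whose
#' SD exceeds \code{max_sd} is rejected as inconsistent with any
#' consecutive-charge assignment.
#'
#' @param mz numeric vector of peak m/z values (>= 2 peaks from
#'   consecutive charge states).
#' @param adduct charge-carrier mass, Da (default: proton, 1.00728).
#' @param max_sd reject the series when the SD of the per-peak mass
#'   estimates exceeds this (default 100 ppm of the mean estimate:
#'   instrument-level m/z noise keeps per-peak estimates within a few Da,
#'   whereas a wrong or inconsistent charge assignment disperses them by
#'   orders of magnitude more).
#' @return list with \code{mass} (Da), \code{sd}, \code{charges},
#'   \code{per_peak} (data.frame of m/z, charge, mass estimate, residual).
#' @export
inferMassFromSeries <- function(mz, adduct = protonMass, max_sd = NULL) {
  if (length(mz) < 2) stop("need >= 2 peaks from consecutive charge states")
  if (any(mz <= adduct)) stop("m/z values must exceed the adduct mass")
  mz <- sort(mz, decreasing = TRUE)
  z2 <- round((mz[1] - adduct) / (mz[1] - mz[2]))
  if (!is.finite(z2) || z2 < 2)
    stop("peaks inconsistent with a consecutive charge-state series")
  z <- (z2 - 2) + seq_along(mz)   # first (highest m/z) peak has charge z2-1
  masses <- z * (mz - adduct)
  m <- mean(masses)
  s <- stats::sd(masses)
  if (is.null(max_sd)) max_sd <- 1e-4 * m
  if (s > max_sd)
    stop(sprintf(
      "charge-series inference failed: mass SD %.1f Da exceeds %.1f Da",
      s, max_sd))
  list(mass = m, sd = s, charges = z,
       per_peak = data.frame(mz = mz, charge = z, mass = masses,
                             residual = masses - m))
}

#' Regression table of measured vs expected assembly masses
#'
#' Builds, from measured masses and component stoichiometries, the
#' measured / expected / delta / percent-error table used to validate an
#' assembly assignment.
#'
#' @param measured numeric vector of measured masses, Da.
#' @param counts matrix or data.frame (one row per measurement, one column
#'   per component) of copy numbers.
#' @param monomer_masses named vector of component monomer masses, Da
#'   (default \code{defaultComponentMasses}).
#' @return data.frame with \code{measured}, \code{expected}, \code{delta},
#'   \code{percent_error} (rounded to 2 decimals as conventionally
#'   printed, computed before rounding).
#' @export
assemblyMassTable <- function(measured, counts,
                              monomer_masses = defaultComponentMasses) {
  counts <- as.matrix(counts)
  expected <- as.vector(counts %*% monomer_masses[colnames(counts)])
  err <- massError(measured, expected)
  data.frame(measured = measured, expected = expected, delta = err$delta,
             percent_error = round(err$percent, 2))
}
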