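## Reproduction battery against deposited coordinate sets. These analyses
## compare the open-spiral helicase-loader complex (PDB 6BBM) with the
## translocating ssDNA complex (4ESV), the constricted closed planar ring
## (4NMN) and the dilated closed planar ring (2R6A). The files are not
## shipped with the package; fetch them once into a cache directory with
## downloadAccessions() (network required).

bpAccessions <- c("6bbm", "4esv", "4nmn", "2r6a")

#' Download the comparator coordinate files
#'
#' Fetches mmCIF files for the helicase-loader complex and its comparator
#' structures from RCSB into \code{dir}. Requires network access; files
#' already present are kept.
#'
#' @param dir cache directory (created if needed).
#' @param ids accession codes (default: the four structures of the
#'   reproduction battery).
#' @return named vector of file paths.
#' @export
downloadAccessions <- function(dir, ids = bpAccessions) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(ids, ".cif"))
  names(paths) <- ids
  for (i in seq_along(ids)) {
    if (!file.exists(paths[i]))
      utils::download.file(
        paste0("https://files.rcsb.org/download/", toupper(ids[i]), ".cif"),
        paths[i], quiet = TRUE, mode = "wb")
  }
  paths
}

#' Reproduction battery on the deposited models
#'
#' Runs the tier analyses that characterise helicase opening on locally
#' cached coordinate files: the CTD-vs-NTD tier-plane angle of the
#' loader complex and of the ssDNA complex, CTD-tier helical parameters
#' of both, uniqueness of the breached CTD interface gap, chamber
#' diameters of the constricted and dilated closed rings, the
#' intermolecular crosslink evaluation, and the NTD-CTD inter-tier buried
#' surface area comparison.
#'
#' @param dir directory holding \code{6bbm.cif}, \code{4esv.cif},
#'   \code{4nmn.cif}, \code{2r6a.cif} (see
#'   \code{\link{downloadAccessions}}).
#' @param bsa also compute the inter-tier BSA ordering (slow).
#' @return nested list of results.
#' @export
accessionBattery <- function(dir, bsa = TRUE) {
  paths <- file.path(dir, paste0(bpAccessions, ".cif"))
  names(paths) <- bpAccessions
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing coordinate file(s): ", paste(missing, collapse = ", "),
         "; run downloadAccessions() first (network required)")
  cfgdir <- system.file("extdata", package = "ringtier")
  bp <- loadStructure(paths["6bbm"])
  bp_tiers <- readTierConfig(file.path(cfgdir, "tiers_bp_complex.yaml"))
  ssdna <- loadStructure(paths["4esv"])
  ss_tiers <- readTierConfig(file.path(cfgdir, "tiers_ssdna_complex.yaml"))
  out <- list()
  out$bp_tier_angle <- tierPlaneAngle(bp, bp_tiers$CTD,
                                      bp_tiers$`NTD-globe`)$angle
  out$ssdna_tier_angle <- tierPlaneAngle(ssdna, ss_tiers$CTD,
                                         ss_tiers$`NTD-globe`)$angle
  out$bp_ctd_helix <- tierHelix(bp, bp_tiers$CTD)
  out$ssdna_ctd_helix <- tierHelix(ssdna, ss_tiers$CTD)
  gaps <- tierGaps(bp, bp_tiers$CTD)
  out$bp_ctd_gaps <- gaps
  out$breach_is_unique_max <-
    sum(gaps$gap > 0.8 * max(gaps$gap), na.rm = TRUE) == 1
  xl <- parseCrosslinkTable(file.path(cfgdir, "crosslinks_bp_complex.csv"))
  res <- evaluateCrosslinks(
    bp, xl[xl$intermolecular, ],
    protein_chain_map = list(EcDnaB = "C", lambdaP = c("W", "V")),
    cutoff = 30, atom = "CA", ambiguity = "min_over_chains")
  out$intermolecular_violations <- crosslinkReport(res)$counts[["violated"]]
  if (bsa) {
    closed <- loadStructure(paths["4nmn"])
    cl_tiers <- readTierConfig(file.path(cfgdir,
                                         "tiers_closed_ring.yaml"))
    tierAtoms <- function(s, t) do.call(rbind, lapply(tierDomains(t),
      function(d) selectDomain(s, d)))
    out$bsa_closed <- buriedSurfaceArea(
      tierAtoms(closed, cl_tiers$CTD),
      tierAtoms(closed, cl_tiers$`NTD-globe`))$bsa
    out$bsa_bp <- buriedSurfaceArea(
      tierAtoms(bp, bp_tiers$CTD),
      tierAtoms(bp, bp_tiers$`NTD-globe`))$bsa
    out$bsa_ordering_ok <- out$bsa_closed > out$bsa_bp
  }
  out
}
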