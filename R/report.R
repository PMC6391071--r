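## Single entry point wiring all modules: run the full analysis battery on
## one structure and emit one machine-readable report.

#' Run the full analysis battery on one structure
#'
#' Tiers -> plane fits and inter-tier angles -> per-tier helical
#' parameters -> consecutive interface gaps -> chamber diameters ->
#' optional inter-tier buried surface area -> optional crosslink
#' evaluation -> optional native-MS table. Deterministic: two runs with
#' the same config give identical reports. Every block of the report
#' records the settings it was computed with.
#'
#' @param structure path to a coordinate file, or a
#'   \code{\link{Structure}}.
#' @param tiers path to a tier config (YAML), or a named list of
#'   \code{\link{TierSpec}}.
#' @param crosslinks optional path to a crosslink CSV, or a data.frame
#'   from \code{\link{parseCrosslinkTable}}.
#' @param protein_chain_map required with \code{crosslinks}: named list
#'   protein -> chains.
#' @param ms_components optional data.frame for
#'   \code{\link{decomposeMass}}; with \code{ms_measured}, decompositions
#'   are run per measured mass.
#' @param ms_measured optional numeric vector of measured masses, Da.
#' @param settings list of mode flags: \code{com_weighting}
#'   ("atomic_mass"/"uniform"), \code{com_atoms} ("all"/"ca_only"),
#'   \code{gap_mode}, \code{xl_cutoff}, \code{xl_atom},
#'   \code{xl_ambiguity}, \code{slab_height}, \code{bsa} (logical:
#'   compute inter-tier BSA; off by default, it is the slow step),
#'   \code{sasa_points}.
#' @param out optional path: write the report as JSON.
#' @return the report, a nested list.
#' @export
runReport <- function(structure, tiers, crosslinks = NULL,
                      protein_chain_map = NULL, ms_components = NULL,
                      ms_measured = NULL, settings = list(), out = NULL) {
  def <- list(com_weighting = "atomic_mass", com_atoms = "all",
              gap_mode = "atom_atom", xl_cutoff = 30, xl_atom = "CA",
              xl_ambiguity = "min_over_chains", slab_height = 5,
              bsa = FALSE, sasa_points = 960)
  settings <- utils::modifyList(def, settings)
  if (is.character(structure)) structure <- loadStructure(structure)
  if (is.character(tiers)) tiers <- readTierConfig(tiers)
  rep <- list(settings = settings, tiers = list())
  for (nm in names(tiers)) {
    tier <- tiers[[nm]]
    ctr <- tierCenters(structure, tier, settings$com_atoms,
                       settings$com_weighting)
    ok <- stats::complete.cases(ctr$centers)
    pts <- ctr$centers[ok, , drop = FALSE]
    ax <- fitHelicalAxis(pts)
    hx <- helicalParameters(pts, ax)
    allsel <- do.call(rbind, lapply(tierDomains(tier), function(d)
      selectDomain(structure, d)))
    diam <- chamberDiameter(allsel, ax, settings$slab_height)
    gaps <- tierGaps(structure, tier, settings$gap_mode)
    rep$tiers[[nm]] <- list(
      modelled_fraction = ctr$modelled_fraction,
      plane = fitPlane(pts),
      helix = hx,
      mean_rise = meanRise(hx), mean_twist = meanTwist(hx),
      turn_pitch = helixPitch(hx), axial_extent = hx@axialExtent,
      handedness = handedness(hx),
      chamber_diameter = diam$diameter,
      gaps = gaps,
      max_gap_interface = gaps[which.max(gaps$gap),
                               c("domain_a", "domain_b")])
  }
  if (length(tiers) >= 2) {
    nms <- names(tiers)
    ang <- list()
    for (i in seq_len(length(nms) - 1))
      for (j in (i + 1):length(nms)) {
        key <- paste(nms[i], nms[j], sep = "_vs_")
        ang[[key]] <- planeAngle(rep$tiers[[nms[i]]]$plane,
                                 rep$tiers[[nms[j]]]$plane)
        if (isTRUE(settings$bsa)) {
          sa <- do.call(rbind, lapply(tierDomains(tiers[[nms[i]]]),
                        function(d) selectDomain(structure, d)))
          sb <- do.call(rbind, lapply(tierDomains(tiers[[nms[j]]]),
                        function(d) selectDomain(structure, d)))
          rep$bsa[[key]] <- buriedSurfaceArea(
            sa, sb, n_points = settings$sasa_points)
        }
      }
    rep$tier_plane_angles <- ang
  }
  if (!is.null(crosslinks)) {
    if (is.character(crosslinks)) crosslinks <- parseCrosslinkTable(crosslinks)
    res <- evaluateCrosslinks(structure, crosslinks, protein_chain_map,
                              cutoff = settings$xl_cutoff,
                              atom = settings$xl_atom,
                              ambiguity = settings$xl_ambiguity)
    rep$crosslinks <- list(results = res, summary = crosslinkReport(res))
  }
  if (!is.null(ms_components) && !is.null(ms_measured)) {
    rep$ms <- lapply(ms_measured, function(m)
      utils::head(decomposeMass(m, ms_components, tolerance = Inf), 5))
    names(rep$ms) <- paste0("measured_", ms_measured)
  }
  if (!is.null(out)) {
    jsonlite::write_json(reportToJSONable(rep), out, auto_unbox = TRUE,
                         digits = 6, pretty = TRUE)
  }
  rep
}

## strip S4 objects down to plain lists for JSON output
reportToJSONable <- function(x) {
  if (is(x, "Plane"))
    return(list(centroid = x@centroid, normal = x@normal))
  if (is(x, "HelixFit"))
    return(list(mean_rise = x@meanRise, mean_twist = x@meanTwist,
                turn_pitch = x@pitch, axial_extent = x@axialExtent,
                mean_radius = x@meanRadius, radial_rmsd = x@radialRmsd,
                handedness = x@handedness,
                rise_per_step = x@risePerStep,
                twist_per_step = x@twistPerStep))
  if (is.list(x)) return(lapply(x, reportToJSONable))
  x
}
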