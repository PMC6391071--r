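#' @import methods
NULL

## ---------------------------------------------------------------------------
## Structure: parsed atomic coordinates
## ---------------------------------------------------------------------------

#' Structure: atomic coordinates with author chain/residue identifiers
#'
#' Container for the ATOM/HETATM content of one model of a coordinate file.
#' Atoms are stored as a data.frame with columns \code{chain},
#' \code{resno} (author residue number), \code{resid} (3-letter residue
#' name), \code{atom} (PDB atom name), \code{element}, \code{x,y,z} (A) and
#' \code{occupancy}. Every element must map to a known average atomic mass.
#'
#' @slot atoms data.frame as described above.
#' @slot source character(2): file path and format tag.
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", source = "character"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z",
            "occupancy")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("structure contains zero atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atom coordinates")
  unknown <- setdiff(unique(toupper(a$element)), names(atomicMasses))
  if (length(unknown))
    return(paste("unknown element symbol(s):", paste(unknown, collapse = ", ")))
  TRUE
})

#' @describeIn Structure number of atoms
#' @param x,object a \code{Structure}
#' @export
setMethod("length", "Structure", function(x) nrow(x@atoms))

#' @describeIn Structure brief summary
#' @export
setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chains (",
      paste(sort(unique(a$chain)), collapse = " "), ")\n")
  cat("  source:", paste(object@source, collapse = " ["), "]\n")
})

#' Atom table of a Structure
#' @param x a \code{Structure}
#' @return data.frame of atom records
#' @export
atoms <- function(x) {
  stopifnot(is(x, "Structure"))
  x@atoms
}

#' Chain identifiers present in a Structure
#' @param x a \code{Structure}
#' @export
chainIds <- function(x) sort(unique(atoms(x)$chain))

## ---------------------------------------------------------------------------
## DomainSpec / TierSpec: ordered per-subunit domain definitions
## ---------------------------------------------------------------------------

#' DomainSpec: one chain + inclusive residue interval
#'
#' @slot label free-text label (e.g. "CTD-A").
#' @slot chain author chain identifier.
#' @slot start,end inclusive author residue numbers, \code{start <= end}.
#' @exportClass DomainSpec
setClass("DomainSpec",
  representation(label = "character", chain = "character",
                 start = "numeric", end = "numeric"))

setValidity("DomainSpec", function(object) {
  if (length(object@start) != 1 || length(object@end) != 1)
    return("start and end must be scalars")
  if (object@start > object@end)
    return("inverted residue interval: start > end")
  TRUE
})

#' Construct a DomainSpec
#' @param label free-text label
#' @param chain chain id
#' @param start,end inclusive author residue numbers
#' @export
DomainSpec <- function(label, chain, start, end)
  new("DomainSpec", label = as.character(label), chain = as.character(chain),
      start = as.numeric(start), end = as.numeric(end))

setMethod("show", "DomainSpec", function(object)
  cat(sprintf("DomainSpec %s: chain %s, residues %d-%d\n", object@label,
              object@chain, as.integer(object@start), as.integer(object@end))))

#' TierSpec: ordered list of domains forming one tier
#'
#' The order of \code{domains} is the spiral order (bottom to top) and is
#' always explicit; it is never inferred from chain identifiers. At least
#' three domains are required so that plane and helix fits are defined.
#'
#' @slot name tier label (e.g. "CTD").
#' @slot domains list of \code{DomainSpec}, in spiral order.
#' @exportClass TierSpec
setClass("TierSpec",
  representation(name = "character", domains = "list"))

setValidity("TierSpec", function(object) {
  if (length(object@domains) < 3)
    return("a tier needs at least 3 domains for any plane/helix fit")
  if (!all(vapply(object@domains, is, logical(1), "DomainSpec")))
    return("domains must all be DomainSpec objects")
  TRUE
})

#' Construct a TierSpec
#' @param name tier label
#' @param domains list of \code{DomainSpec} in spiral order (bottom to top)
#' @export
TierSpec <- function(name, domains)
  new("TierSpec", name = as.character(name), domains = domains)

setMethod("show", "TierSpec", function(object) {
  cat(sprintf("TierSpec %s: %d domains\n", object@name,
              length(object@domains)))
  for (d in object@domains)
    cat(sprintf("  %-10s chain %s %d-%d\n", d@label, d@chain,
                as.integer(d@start), as.integer(d@end)))
})

#' @describeIn TierSpec number of domains
#' @param x,object a \code{TierSpec}
#' @export
setMethod("length", "TierSpec", function(x) length(x@domains))

#' Domains of a TierSpec
#' @param x a \code{TierSpec}
#' @export
tierDomains <- function(x) {
  stopifnot(is(x, "TierSpec"))
  x@domains
}

## ---------------------------------------------------------------------------
## Geometry result classes
## ---------------------------------------------------------------------------

#' Plane: least-squares plane through a point set
#'
#' @slot centroid numeric(3), A.
#' @slot normal unit numeric(3).
#' @exportClass Plane
setClass("Plane", representation(centroid = "numeric", normal = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@centroid) != 3 || length(object@normal) != 3)
    return("centroid and normal must be 3-vectors")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector")
  TRUE
})

setMethod("show", "Plane", function(object)
  cat(sprintf("Plane: centroid (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              object@centroid[1], object@centroid[2], object@centroid[3],
              object@normal[1], object@normal[2], object@normal[3])))

#' HelixFit: pseudo-helical parameters of an ordered point series
#'
#' Summarises an ordered series of subunit centers as a pseudo-helix:
#' per-step rise (axial displacement, A) and twist (rotation about the
#' axis, degrees, signed so that positive = right-handed), their means, the
#' turn pitch \code{mean_rise * 360 / |mean_twist|}, the total axial extent
#' of the series (an alternative reading of "pitch" for an open spiral),
#' mean point-to-axis radius and its rmsd, and handedness.
#'
#' @slot axisPoint,axisDirection axis anchor (A) and unit direction.
#' @slot risePerStep,twistPerStep numeric(n-1).
#' @slot meanRise,meanTwist,pitch,axialExtent,meanRadius,radialRmsd scalars.
#' @slot handedness "right", "left" or "planar".
#' @exportClass HelixFit
setClass("HelixFit",
  representation(axisPoint = "numeric", axisDirection = "numeric",
                 risePerStep = "numeric", twistPerStep = "numeric",
                 meanRise = "numeric", meanTwist = "numeric",
                 pitch = "numeric", axialExtent = "numeric",
                 meanRadius = "numeric", radialRmsd = "numeric",
                 handedness = "character"))

setValidity("HelixFit", function(object) {
  if (abs(sqrt(sum(object@axisDirection^2)) - 1) > 1e-9)
    return("axisDirection must be a unit vector")
  if (!object@handedness %in% c("right", "left", "planar"))
    return("handedness must be right/left/planar")
  if (is.finite(object@pitch) && abs(object@meanTwist) > 1e-12) {
    if (abs(object@pitch * abs(object@meanTwist) / 360 - abs(object@meanRise)) >
        1e-6 * max(1, abs(object@meanRise)))
      return("pitch inconsistent with mean rise and twist")
  }
  TRUE
})

setMethod("show", "HelixFit", function(object) {
  cat(sprintf(paste0("HelixFit: rise %.3f A, twist %.3f deg, turn pitch ",
                     "%.3f A, axial extent %.3f A\n"),
              object@meanRise, object@meanTwist, object@pitch,
              object@axialExtent))
  cat(sprintf("  radius %.3f A (rmsd %.4f), handedness %s\n",
              object@meanRadius, object@radialRmsd, object@handedness))
})

#' @describeIn HelixFit mean rise per subunit (A)
#' @param x,object a \code{HelixFit}
#' @export
meanRise <- function(x) x@meanRise

#' @describeIn HelixFit mean signed twist per subunit (degrees)
#' @export
meanTwist <- function(x) x@meanTwist

#' @describeIn HelixFit turn pitch, rise * 360 / |twist| (A)
#' @export
helixPitch <- function(x) x@pitch

#' @describeIn HelixFit handedness ("right", "left" or "planar")
#' @export
handedness <- function(x) x@handedness
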