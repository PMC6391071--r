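## Coordinate I/O and atom selection. Parsing of the standard formats is
## delegated to bio3d; this layer normalises the result into the Structure
## container, resolves alternate locations and enforces the element table.

guessElement <- function(atom_name, resid) {
  ## PDB element columns are sometimes blank; fall back to the atom name.
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(atomicMasses) & !(one %in% c("C", "N", "O", "H", "P", "S")),
         two, one)
}

#' Load a coordinate file into a Structure
#'
#' Reads all ATOM/HETATM records of the first model of a PDB or mmCIF file.
#' Alternate locations are resolved by keeping, per (chain, residue, atom)
#' triple, the highest-occupancy altloc (ties broken in favour of altloc
#' "A"). Elements missing from the file are inferred from the atom name;
#' any element absent from \code{\link{atomicMasses}} is rejected.
#'
#' @param path path to a coordinate file.
#' @param format "pdb", "mmcif" or "auto" (by file extension; ".cif" is
#'   mmCIF, anything else PDB).
#' @return a \code{\link{Structure}}.
#' @examples
#' s <- makeAssembly(AssemblyParams(n_subunits = 6, rise = 4, twist = 60,
#'                                  radius = 30, seed = 1))$structure
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePDB(s, f)
#' s2 <- loadStructure(f)
#' length(s2) == length(s)
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  raw <- if (format == "mmcif")
    suppressMessages(bio3d::read.cif(path, verbose = FALSE,
                                     rm.alt = FALSE))
  else suppressMessages(suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0) stop("zero atoms in ", path)
  el <- toupper(trimws(as.character(a$elesy)))
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- guessElement(a$elety[miss], a$resid[miss])
  occ <- suppressWarnings(as.numeric(a$o))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = as.character(a$resid), atom = as.character(a$elety),
    element = el, x = a$x, y = a$y, z = a$z, occupancy = occ,
    alt = ifelse(is.na(a$alt) | a$alt == "", "", as.character(a$alt)),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- ""
  ## resolve altlocs: keep highest occupancy, ties -> altloc "" then "A"
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom,
                                     sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  unknown <- setdiff(unique(atoms$element), names(atomicMasses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  new("Structure", atoms = atoms, source = c(path, format))
}

#' Write a Structure to a PDB file
#'
#' Plain single-model PDB output (3-decimal coordinate precision). Used for
#' synthetic assemblies and pseudo-atom (center-of-mass) output.
#'
#' @param x a \code{\link{Structure}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(x, path) {
  a <- atoms(x)
  rec <- if (is.null(a$hetero)) rep("ATOM  ", nrow(a))
         else ifelse(a$hetero, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                  sprintf("%-4s", a$atom))
  lines <- sprintf(
    "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)) %% 100000, name4, a$resid,
    substr(a$chain, 1, 1), as.integer(a$resno) %% 10000,
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select the atoms of one domain
#'
#' Atoms of \code{spec}'s chain whose author residue number lies in the
#' inclusive interval, in residue (then atom) order. An empty selection is
#' a valid outcome: intervals may be entirely unmodelled in the file.
#'
#' @param structure a \code{\link{Structure}}.
#' @param spec a \code{\link{DomainSpec}}.
#' @param atom_filter "all" or "ca_only" (alpha carbons).
#' @return data.frame of atom records (possibly 0 rows).
#' @export
selectDomain <- function(structure, spec, atom_filter = c("all", "ca_only")) {
  atom_filter <- match.arg(atom_filter)
  a <- atoms(structure)
  if (!spec@chain %in% a$chain)
    stop("chain ", spec@chain, " not present in structure")
  sel <- a$chain == spec@chain & a$resno >= spec@start & a$resno <= spec@end
  if (atom_filter == "ca_only") sel <- sel & a$atom == "CA"
  out <- a[sel, , drop = FALSE]
  out[order(out$resno), , drop = FALSE]
}

#' Center of mass of an atom selection
#'
#' \eqn{\sum w_i x_i / \sum w_i} with weights equal to average atomic
#' masses (default) or 1. Hydrogens are included if present in the
#' selection (cryo-EM models typically have none).
#'
#' @param sel data.frame of atom records (from \code{\link{selectDomain}}).
#' @param weighting "atomic_mass" or "uniform".
#' @return numeric(3), A.
#' @export
centerOfMass <- function(sel, weighting = c("atomic_mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (is.null(nrow(sel)) || nrow(sel) == 0) stop("empty atom selection")
  w <- if (weighting == "atomic_mass") atomicMasses[toupper(sel$element)]
       else rep(1, nrow(sel))
  if (any(is.na(w))) stop("unknown element in selection")
  c(x = sum(w * sel$x), y = sum(w * sel$y), z = sum(w * sel$z)) / sum(w)
}

#' Ordered domain centers of a tier
#'
#' Applies \code{\link{selectDomain}} + \code{\link{centerOfMass}} to every
#' domain of a tier, in the tier's explicit spiral order. Domains whose
#' interval is entirely unmodelled yield NA rows; the modelled fraction of
#' each interval is reported so partial modelling is visible.
#'
#' @inheritParams selectDomain
#' @param tier a \code{\link{TierSpec}}.
#' @param weighting passed to \code{\link{centerOfMass}}.
#' @return list with \code{centers} (n x 3 matrix, A), \code{labels} and
#'   \code{modelled_fraction} (fraction of interval residues present).
#' @export
tierCenters <- function(structure, tier,
                        atom_filter = c("all", "ca_only"),
                        weighting = c("atomic_mass", "uniform")) {
  atom_filter <- match.arg(atom_filter)
  weighting <- match.arg(weighting)
  doms <- tierDomains(tier)
  centers <- matrix(NA_real_, length(doms), 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  frac <- numeric(length(doms))
  for (i in seq_along(doms)) {
    d <- doms[[i]]
    sel <- selectDomain(structure, d, atom_filter)
    frac[i] <- length(unique(sel$resno)) / (d@end - d@start + 1)
    if (nrow(sel) > 0) centers[i, ] <- centerOfMass(sel, weighting)
  }
  list(centers = centers,
       labels = vapply(doms, function(d) d@label, character(1)),
       modelled_fraction = frac)
}

#' Read a tier configuration file
#'
#' YAML file with one entry per tier:
#' \preformatted{
#' tiers:
#'   - name: CTD
#'     domains:                 # spiral order, bottom -> top
#'       - {label: CTD-A, chain: A, start: 203, end: 471}
#'       - ...
#' }
#' A configuration for the helicase-loader complex model (chains A-F, the
#' loader chains V-Z) ships with the package; see
#' \code{system.file("extdata", "tiers_bp_complex.yaml", package="ringtier")}.
#' Two conventions for the N-terminal globe interval are provided as
#' separate profiles because the source conventions disagree.
#'
#' @param path YAML file path.
#' @return named list of \code{\link{TierSpec}}.
#' @export
readTierConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tiers)) stop("tier config must have a 'tiers' entry")
  out <- lapply(cfg$tiers, function(t) {
    doms <- lapply(t$domains, function(d)
      DomainSpec(d$label, d$chain, d$start, d$end))
    TierSpec(t$name, doms)
  })
  names(out) <- vapply(cfg$tiers, function(t) t$name, character(1))
  out
}
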