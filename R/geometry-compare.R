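## Rigid-body superposition (Kabsch), subunit rotation extraction,
## per-residue alpha-carbon displacement, and cis/trans isomer calls.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' RMSD between paired atoms. Pairing is by author residue number and atom
#' name within the two selections (atoms present in only one selection are
#' dropped); set \code{pair_by = "index"} when the inputs are already
#' matched row-for-row.
#'
#' @param mobile,reference atom data.frames.
#' @param pair_by "residue" (chain-agnostic residue number + atom name) or
#'   "index" (row order; requires equal row counts).
#' @return list with \code{R} (3x3 rotation), \code{t} (translation so that
#'   \code{x R^T + t} maps mobile onto reference), \code{rmsd} (A),
#'   \code{n} (atoms paired), and \code{angle} (rotation angle, degrees).
#' @export
superpose <- function(mobile, reference, pair_by = c("residue", "index")) {
  pair_by <- match.arg(pair_by)
  if (pair_by == "residue") {
    ka <- paste(mobile$resno, mobile$atom)
    kb <- paste(reference$resno, reference$atom)
    common <- intersect(ka, kb)
    mobile <- mobile[match(common, ka), , drop = FALSE]
    reference <- reference[match(common, kb), , drop = FALSE]
  }
  if (nrow(mobile) != nrow(reference))
    stop("index pairing requires equal atom counts")
  if (nrow(mobile) < 3) stop("need at least 3 paired atoms")
  x <- coordMatrix(mobile); y <- coordMatrix(reference)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  if (svd(xc, nu = 0)$d[2] < 1e-9) stop("degenerate (collinear) pairing")
  sv <- svd(t(xc) %*% yc)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, -cy)
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(R = R, t = t, rmsd = rmsd, n = nrow(mobile), angle = ang)
}

applyTransform <- function(sel, R, t) {
  p <- coordMatrix(sel) %*% t(R)
  sel$x <- p[, 1] + t[1]; sel$y <- p[, 2] + t[2]; sel$z <- p[, 3] + t[3]
  sel
}

#' Rotation of a probe subunit between two assemblies
#'
#' Both assemblies are superposed on the anchor domain; the residual
#' rotation taking the probe domain of the first onto the probe domain of
#' the second is then extracted and its angle returned as
#' \code{acos((trace(R) - 1)/2)}. This quantifies, e.g., the inclination
#' of a subunit towards the helical axis between two conformers.
#'
#' @param structure_a,structure_b \code{\link{Structure}} objects.
#' @param anchor,probe \code{\link{DomainSpec}} objects resolvable in both
#'   structures (author numbering must correspond).
#' @param atom_filter passed to \code{\link{selectDomain}} (default Ca
#'   only, robust to side-chain differences).
#' @return list with \code{angle} (degrees), \code{anchor_rmsd},
#'   \code{probe_rmsd}.
#' @export
subunitRotation <- function(structure_a, structure_b, anchor, probe,
                            atom_filter = "ca_only") {
  an_a <- selectDomain(structure_a, anchor, atom_filter)
  an_b <- selectDomain(structure_b, anchor, atom_filter)
  fit0 <- superpose(an_a, an_b)
  pa <- applyTransform(selectDomain(structure_a, probe, atom_filter),
                       fit0$R, fit0$t)
  pb <- selectDomain(structure_b, probe, atom_filter)
  fit1 <- superpose(pa, pb)
  list(angle = fit1$angle, anchor_rmsd = fit0$rmsd, probe_rmsd = fit1$rmsd)
}

#' Per-residue alpha-carbon displacement after anchor superposition
#'
#' Superposes structure A onto structure B over the anchor domain, then
#' reports the Euclidean distance between corresponding alpha carbons of
#' the listed residues (on \code{chain}). Residues lacking a Ca in either
#' model are reported unmapped (NA).
#'
#' @inheritParams subunitRotation
#' @param chain chain holding the probed residues (in both structures).
#' @param residues integer vector of author residue numbers.
#' @return data.frame with \code{resno}, \code{displacement} (A, NA when
#'   unmapped).
#' @export
residueCaDisplacement <- function(structure_a, structure_b, anchor,
                                  chain, residues) {
  an_a <- selectDomain(structure_a, anchor, "ca_only")
  an_b <- selectDomain(structure_b, anchor, "ca_only")
  fit <- superpose(an_a, an_b)
  a <- atoms(structure_a); b <- atoms(structure_b)
  out <- data.frame(resno = residues, displacement = NA_real_)
  for (i in seq_along(residues)) {
    ra <- a[a$chain == chain & a$resno == residues[i] & a$atom == "CA", ]
    rb <- b[b$chain == chain & b$resno == residues[i] & b$atom == "CA", ]
    if (nrow(ra) == 1 && nrow(rb) == 1) {
      ra <- applyTransform(ra, fit$R, fit$t)
      out$displacement[i] <-
        sqrt((ra$x - rb$x)^2 + (ra$y - rb$y)^2 + (ra$z - rb$z)^2)
    }
  }
  out
}

#' Classify a subunit as cis or trans
#'
#' In hexameric helicases, monomer conformers alternate between two
#' states: in the cis monomer the N-terminal helical hairpin points toward
#' the C-terminal domain of the same chain, in the trans monomer it points
#' away. The call is made on center-of-mass geometry: cis iff the angle at
#' the globe COM between the hairpin COM and the parent CTD COM is < 90
#' degrees.
#'
#' @param globe,hairpin,parent_ctd atom data.frames of the NTD globe, the
#'   NTD helical hairpin, and the same chain's CTD.
#' @param weighting passed to \code{\link{centerOfMass}}.
#' @return "cis" or "trans".
#' @export
classifyIsomer <- function(globe, hairpin, parent_ctd,
                           weighting = "atomic_mass") {
  g <- centerOfMass(globe, weighting)
  h <- centerOfMass(hairpin, weighting)
  c_ <- centerOfMass(parent_ctd, weighting)
  v1 <- h - g; v2 <- c_ - g
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate geometry: coincident COMs")
  if (sum(v1 * v2) / (n1 * n2) > 0) "cis" else "trans"
}
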