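## Solvent-accessible surface area (Shrake-Rupley style spherical sampling
## on a deterministic golden-spiral lattice), buried surface area between
## atom groups, and interface residue lists.

## Deterministic, near-uniform unit sphere lattice (Fibonacci / golden
## spiral). Same n always gives the same points, so SASA is reproducible
## across platforms and runs.
sphereLattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley style numerical SASA: each atom's solvent-accessible
#' sphere (vdW radius + probe radius) is sampled on a deterministic
#' golden-spiral lattice of \code{n_points}; points not buried inside any
#' neighbouring atom's accessible sphere contribute area. Hydrogens, if
#' present, are treated as ordinary atoms (cryo-EM models typically have
#' none).
#'
#' @param sel atom data.frame.
#' @param probe_radius solvent probe radius, A (default 1.4, water).
#' @param n_points lattice points per atom (default 960).
#' @return list with \code{total} (A^2), \code{per_atom} (A^2 vector),
#'   \code{probe_radius}, \code{n_points}.
#' @examples
#' a <- data.frame(chain = "A", resno = 1, resid = "C", atom = "C1",
#'                 element = "C", x = 0, y = 0, z = 0, occupancy = 1)
#' s <- sasa(a)
#' abs(s$total - 4 * pi * (1.7 + 1.4)^2) / s$total  # < 1%
#' @export
sasa <- function(sel, probe_radius = 1.4, n_points = 960) {
  if (is.null(nrow(sel)) || nrow(sel) == 0) stop("empty atom selection")
  el <- toupper(sel$element)
  if (any(!el %in% names(vdwRadii)))
    stop("unknown element(s): ",
         paste(setdiff(unique(el), names(vdwRadii)), collapse = ", "))
  r <- vdwRadii[el] + probe_radius
  p <- cbind(sel$x, sel$y, sel$z)
  n <- nrow(p)
  lat <- sphereLattice(n_points)
  per_atom <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (p[, 1] - p[i, 1])^2 + (p[, 2] - p[i, 2])^2 + (p[, 3] - p[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    pts <- sweep(lat * r[i], 2, p[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[, 1] - p[j, 1])^2 + (pts[, 2] - p[j, 2])^2 +
             (pts[, 3] - p[j, 3])^2
      acc <- acc & dj2 > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom,
       probe_radius = probe_radius, n_points = n_points)
}

#' Buried surface area between two atom groups
#'
#' Two-sided total \code{BSA = SASA(a) + SASA(b) - SASA(a+b)}, summing the
#' burial on both sides of the interface. The one-sided (halved) value is
#' reported alongside because conventions differ between publications.
#'
#' @param sel_a,sel_b disjoint atom data.frames.
#' @param probe_radius,n_points passed to \code{\link{sasa}}.
#' @return list with \code{bsa} (two-sided, A^2), \code{bsa_one_sided},
#'   \code{convention = "two-sided"}, and the three component SASA totals.
#' @export
buriedSurfaceArea <- function(sel_a, sel_b, probe_radius = 1.4,
                              n_points = 960) {
  ka <- paste(sel_a$chain, sel_a$resno, sel_a$atom)
  kb <- paste(sel_b$chain, sel_b$resno, sel_b$atom)
  if (length(intersect(ka, kb)))
    stop("overlapping group definitions: groups must be disjoint")
  sa <- sasa(sel_a, probe_radius, n_points)$total
  sb <- sasa(sel_b, probe_radius, n_points)$total
  cols <- intersect(names(sel_a), names(sel_b))
  sab <- sasa(rbind(sel_a[, cols, drop = FALSE],
                    sel_b[, cols, drop = FALSE]),
              probe_radius, n_points)$total
  bsa <- sa + sb - sab
  list(bsa = bsa, bsa_one_sided = bsa / 2, convention = "two-sided",
       sasa_a = sa, sasa_b = sb, sasa_ab = sab)
}

#' Interface residues between two groups
#'
#' Two residue lists per group: \emph{contacts} (residues with any
#' inter-atomic distance to the other group <= \code{contact_cutoff}) and
#' \emph{footprint} (residues with any atom within
#' \code{footprint_cutoff} of an alpha carbon of the other group). Lists
#' are sorted by chain then residue number.
#'
#' @param sel_a,sel_b atom data.frames.
#' @param contact_cutoff any-atom contact cutoff, A (default 4).
#' @param footprint_cutoff atom-to-Ca footprint cutoff, A (default 10).
#' @return list with \code{contacts_a}, \code{contacts_b},
#'   \code{footprint_a}, \code{footprint_b}: data.frames of (chain, resno).
#' @export
interfaceResidues <- function(sel_a, sel_b, contact_cutoff = 4,
                              footprint_cutoff = 10) {
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) stop("empty atom selection")
  a <- coordMatrix(sel_a); b <- coordMatrix(sel_b)
  d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
  resList <- function(sel, keep) {
    u <- unique(sel[keep, c("chain", "resno"), drop = FALSE])
    u[order(u$chain, u$resno), , drop = FALSE]
  }
  caA <- sel_a$atom == "CA"; caB <- sel_b$atom == "CA"
  list(
    contacts_a = resList(sel_a, apply(d <= contact_cutoff, 1, any)),
    contacts_b = resList(sel_b, apply(d <= contact_cutoff, 2, any)),
    footprint_a = if (any(caB))
      resList(sel_a, apply(d[, caB, drop = FALSE] <= footprint_cutoff, 1,
                           any))
      else resList(sel_a, rep(FALSE, nrow(sel_a))),
    footprint_b = if (any(caA))
      resList(sel_b, apply(d[caA, , drop = FALSE] <= footprint_cutoff, 2,
                           any))
      else resList(sel_b, rep(FALSE, nrow(sel_b))))
}
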