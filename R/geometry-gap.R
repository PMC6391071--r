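## Breach-gap and chamber-diameter measurements.

coordMatrix <- function(sel) {
  m <- cbind(sel$x, sel$y, sel$z)
  colnames(m) <- c("x", "y", "z")
  m
}

minPairDistance <- function(a, b) {
  ## a, b: coordinate matrices; returns min distance and achieving indices.
  ## Blocked to keep memory bounded on large selections.
  best <- list(d = Inf, i = NA_integer_, j = NA_integer_)
  bs <- 2000L
  for (i0 in seq(1, nrow(a), by = bs)) {
    ia <- i0:min(i0 + bs - 1, nrow(a))
    d2 <- outer(rowSums(a[ia, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * (a[ia, , drop = FALSE] %*% t(b))
    k <- arrayInd(which.min(d2), dim(d2))
    dmin <- sqrt(max(0, d2[k]))
    if (dmin < best$d) best <- list(d = dmin, i = ia[k[1]], j = k[2])
  }
  best
}

#' Minimum gap between two atom groups
#'
#' Minimum pairwise inter-atomic distance between two selections, used to
#' measure the width of a breached subunit-subunit interface. Modes:
#' \describe{
#'   \item{atom_atom}{all-atom minimum distance (default).}
#'   \item{ca_ca}{alpha carbons only.}
#'   \item{surface}{all-atom distance minus the two van der Waals radii
#'     (clamped at 0), i.e. the surface-to-surface separation.}
#' }
#'
#' @param sel_a,sel_b atom data.frames (e.g. from
#'   \code{\link{selectDomain}}).
#' @param mode "atom_atom", "ca_ca" or "surface".
#' @return list with \code{min_distance} (A), \code{atom_a}, \code{atom_b}
#'   (the achieving atom records) and \code{mode}.
#' @export
interfaceGap <- function(sel_a, sel_b,
                         mode = c("atom_atom", "ca_ca", "surface")) {
  mode <- match.arg(mode)
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) stop("empty atom selection")
  if (mode == "ca_ca") {
    sel_a <- sel_a[sel_a$atom == "CA", , drop = FALSE]
    sel_b <- sel_b[sel_b$atom == "CA", , drop = FALSE]
    if (nrow(sel_a) == 0 || nrow(sel_b) == 0)
      stop("no alpha carbons in selection")
  }
  if (mode == "surface") {
    ## minimise d_ij - r_i - r_j exhaustively (radii differ per atom)
    ra <- vdwRadii[toupper(sel_a$element)]
    rb <- vdwRadii[toupper(sel_b$element)]
    a <- coordMatrix(sel_a); b <- coordMatrix(sel_b)
    best <- list(d = Inf, i = NA, j = NA)
    bs <- 2000L
    for (i0 in seq(1, nrow(a), by = bs)) {
      ia <- i0:min(i0 + bs - 1, nrow(a))
      d <- sqrt(pmax(outer(rowSums(a[ia, , drop = FALSE]^2),
                           rowSums(b^2), "+") -
                     2 * (a[ia, , drop = FALSE] %*% t(b)), 0))
      d <- d - outer(ra[ia], rb, "+")
      k <- arrayInd(which.min(d), dim(d))
      if (d[k] < best$d) best <- list(d = d[k], i = ia[k[1]], j = k[2])
    }
    gap <- max(0, best$d)
    return(list(min_distance = gap, atom_a = sel_a[best$i, ],
                atom_b = sel_b[best$j, ], mode = mode))
  }
  best <- minPairDistance(coordMatrix(sel_a), coordMatrix(sel_b))
  list(min_distance = best$d, atom_a = sel_a[best$i, ],
       atom_b = sel_b[best$j, ], mode = mode)
}

#' Gaps across all consecutive subunit interfaces of a tier
#'
#' Measures \code{\link{interfaceGap}} between every pair of consecutive
#' domains in the tier's spiral order, including the wrap-around pair
#' (last, first) that spans a breached interface in an open spiral.
#'
#' @inheritParams tierHelix
#' @param mode gap mode, see \code{\link{interfaceGap}}.
#' @return data.frame with columns \code{domain_a}, \code{domain_b},
#'   \code{gap} (A), sorted in spiral order.
#' @export
tierGaps <- function(structure, tier, mode = "atom_atom") {
  doms <- tierDomains(tier)
  n <- length(doms)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  out <- data.frame(domain_a = character(n), domain_b = character(n),
                    gap = numeric(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    a <- selectDomain(structure, doms[[idx[k, 1]]])
    b <- selectDomain(structure, doms[[idx[k, 2]]])
    out$domain_a[k] <- doms[[idx[k, 1]]]@label
    out$domain_b[k] <- doms[[idx[k, 2]]]@label
    out$gap[k] <- if (nrow(a) && nrow(b))
      interfaceGap(a, b, mode)$min_distance else NA_real_
  }
  out
}

#' Inner chamber diameter of a tier
#'
#' Partitions the atoms into axial slabs and reports, per slab, the
#' effective inner diameter \code{2 * min(distance-to-axis - vdW radius)}.
#' The headline diameter is the smallest positive slab value (the
#' constriction). A warning is attached when the axis passes outside the
#' atom cloud of some slab (negative effective radius).
#'
#' @param sel atom data.frame of the tier.
#' @param axis list with \code{point}, \code{direction}.
#' @param slab_height slab thickness along the axis, A (default 5).
#' @return list with \code{diameter} (A), \code{profile} (data.frame of
#'   slab midpoints and diameters) and the method parameters.
#' @export
chamberDiameter <- function(sel, axis, slab_height = 5) {
  if (nrow(sel) == 0) stop("empty atom selection")
  p <- coordMatrix(sel)
  d <- unitv(axis$direction)
  rel <- sweep(p, 2, axis$point)
  ax <- as.vector(rel %*% d)
  r <- sqrt(pmax(0, rowSums(rel^2) - ax^2)) - vdwRadii[toupper(sel$element)]
  br <- seq(min(ax) - 1e-9, max(ax) + slab_height, by = slab_height)
  slab <- findInterval(ax, br)
  prof <- data.frame(
    mid = (br[-length(br)] + br[-1]) / 2,
    diameter = vapply(seq_len(length(br) - 1), function(k) {
      if (!any(slab == k)) return(NA_real_)
      2 * min(r[slab == k])
    }, numeric(1)))
  prof <- prof[!is.na(prof$diameter), , drop = FALSE]
  pos <- prof$diameter[prof$diameter > 0]
  list(diameter = if (length(pos)) min(pos) else min(prof$diameter),
       profile = prof, slab_height = slab_height,
       axis_outside_cloud = any(prof$diameter < 0))
}
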