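## Plane fitting and inter-plane angles for tier geometry.

unitv <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

asPointMatrix <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 3) stop("points must be an n x 3 matrix")
  storage.mode(p) <- "double"
  if (anyNA(p)) stop("points contain NA (unmodelled domain center?)")
  p
}

#' Least-squares plane through a point set
#'
#' Centroid is the mean of the points; the normal is the direction
#' minimising the sum of squared point-plane distances, i.e. the smallest
#' principal component of the centered points.
#'
#' @param points n x 3 matrix (n >= 3), A.
#' @return a \code{\link{Plane}}.
#' @examples
#' ring <- makeHelixPoints(HelixParams(n_subunits = 6, rise = 0, twist = 60,
#'                                     radius = 20))$points
#' fitPlane(ring)   # normal along z
#' @export
fitPlane <- function(points) {
  p <- asPointMatrix(points)
  if (nrow(p) < 3) stop("need at least 3 points to fit a plane")
  ctr <- unname(colMeans(p))
  x <- sweep(p, 2, ctr)
  sv <- svd(x, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate input: points are (nearly) collinear")
  new("Plane", centroid = ctr, normal = unitv(sv$v[, 3]))
}

#' Acute angle between two planes
#'
#' \code{acos(|n_a . n_b|)} in degrees: the acute dihedral between the two
#' planes, symmetric in its arguments and bounded in [0, 90].
#'
#' @param a,b \code{\link{Plane}} objects.
#' @return angle in degrees.
#' @export
planeAngle <- function(a, b) {
  stopifnot(is(a, "Plane"), is(b, "Plane"))
  d <- abs(sum(a@normal * b@normal))
  acos(min(1, d)) * 180 / pi
}

#' Angle between two tiers of a structure
#'
#' Convenience wrapper: extracts ordered domain centers for both tiers and
#' returns the acute angle between their least-squares planes, together
#' with the two plane fits.
#'
#' @param structure a \code{\link{Structure}}.
#' @param tier_a,tier_b \code{\link{TierSpec}} objects.
#' @param atom_filter,weighting passed to \code{\link{tierCenters}}.
#' @return list with \code{angle} (degrees), \code{plane_a}, \code{plane_b}.
#' @export
tierPlaneAngle <- function(structure, tier_a, tier_b,
                           atom_filter = "all", weighting = "atomic_mass") {
  ca <- tierCenters(structure, tier_a, atom_filter, weighting)$centers
  cb <- tierCenters(structure, tier_b, atom_filter, weighting)$centers
  pa <- fitPlane(ca[stats::complete.cases(ca), , drop = FALSE])
  pb <- fitPlane(cb[stats::complete.cases(cb), , drop = FALSE])
  list(angle = planeAngle(pa, pb), plane_a = pa, plane_b = pb)
}
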