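## Pseudo-helical axis fitting and per-step rise/twist extraction for an
## ordered series of subunit centers (the spiral order comes from the
## TierSpec and is never inferred).

## Distance of each point to the line (p0, unit d)
radialDistances <- function(p, p0, d) {
  rel <- sweep(p, 2, p0)
  ax <- as.vector(rel %*% d)
  sqrt(pmax(0, rowSums(rel^2) - ax^2))
}

axisFromAngles <- function(theta, phi)
  unname(c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta)))

## For a fixed axis direction, the best anchor is found in closed form:
## project the points onto the plane normal to the direction and fit a
## circle center by linear least squares (Kasa fit). Returns the 3D anchor
## and the variance of the point-to-axis radii at that anchor.
anchorForDirection <- function(p, d) {
  e1 <- unitv(if (abs(d[3]) < 0.9) cross3(d, c(0, 0, 1)) else
              cross3(d, c(1, 0, 0)))
  e2 <- cross3(d, e1)
  u <- as.vector(p %*% e1); v <- as.vector(p %*% e2)
  A <- cbind(2 * u, 2 * v, 1)
  sol <- tryCatch(qr.solve(A, u^2 + v^2), error = function(e) NULL)
  if (is.null(sol)) { a <- mean(u); b <- mean(v) } else {
    a <- sol[1]; b <- sol[2]
  }
  p0 <- a * e1 + b * e2 + mean(as.vector(p %*% d)) * d
  list(point = p0, variance = stats::var(radialDistances(p, p0, d)))
}

#' Fit a pseudo-helical axis to an ordered point series
#'
#' Deterministic two-stage scheme. The axis direction is initialised from
#' the least-squares plane normal of the point set (plus a fixed fan of
#' perturbed restarts to avoid local minima), and refined by Nelder-Mead
#' least squares on the variance of the point-to-axis radii (an ideal
#' helix has constant radius). For each candidate direction the optimal
#' axis anchor is computed in closed form as the least-squares circle
#' center of the points projected along that direction, so the search
#' space is only the two direction angles. The direction is oriented so
#' that the mean rise along the ordered points is >= 0. If no refinement
#' start improves on the plane-normal axis the latter is returned and
#' flagged unconverged.
#'
#' @param points n x 3 matrix (n >= 4 recommended; n >= 3 accepted), A.
#' @param max_iter iteration budget per refinement start (default 200).
#' @param tol convergence tolerance on the radial variance (default 1e-9).
#' @return list with \code{point} (axis anchor), \code{direction} (unit),
#'   \code{radial_variance}, and \code{converged}.
#' @export
fitHelicalAxis <- function(points, max_iter = 200, tol = 1e-9) {
  p <- asPointMatrix(points)
  if (nrow(p) < 3) stop("need at least 3 points")
  if (max(stats::dist(p)) < 1e-12) stop("points are all coincident")
  pl <- fitPlane(p)
  d0 <- pl@normal
  theta0 <- acos(max(-1, min(1, d0[3])))
  phi0 <- atan2(d0[2], d0[1])
  objective <- function(par)
    anchorForDirection(p, axisFromAngles(par[1], par[2]))$variance
  init_var <- objective(c(theta0, phi0))
  ## A finite helical point set can be equidistant from more than one line
  ## (sampling degeneracy), so candidates that tie on radial variance are
  ## discriminated by the evenness of their rise steps: the generating
  ## axis gives (near-)constant per-step rise, spurious axes do not.
  riseStepVar <- function(par) {
    d <- axisFromAngles(par[1], par[2])
    anc <- anchorForDirection(p, d)
    ax <- as.vector(sweep(p, 2, anc$point) %*% d)
    stats::var(diff(ax))
  }
  ## restarts: plane normal with a fixed perturbation fan, the mean cross
  ## product of consecutive chords (robust for steep helices, where the
  ## plane normal is far from the axis), and the best cells of a coarse
  ## deterministic direction grid scored by both criteria
  toAngles <- function(d) c(acos(max(-1, min(1, d[3]))), atan2(d[2], d[1]))
  ch <- diff(p)
  if (nrow(ch) >= 2) {
    cp <- t(vapply(seq_len(nrow(ch) - 1), function(k)
      cross3(ch[k, ], ch[k + 1, ]), numeric(3)))
    cc <- colMeans(cp)
    cc_start <- if (sqrt(sum(cc^2)) > 1e-9) toAngles(unitv(cc)) else NULL
  } else cc_start <- NULL
  grid <- as.matrix(expand.grid(theta = seq(0, 90, by = 15) * pi / 180,
                                phi = seq(0, 345, by = 15) * pi / 180))
  gv <- apply(grid, 1, objective)
  gr <- apply(grid, 1, riseStepVar)
  grid_starts <- grid[unique(c(order(gv)[1:3], order(gr)[1:3])), ,
                      drop = FALSE]
  starts <- rbind(if (!is.null(cc_start)) rbind(cc_start),
                  c(theta0, phi0),
                  grid_starts,
                  cbind(theta0 + c(-1, -1, 1, 1, -0.4, -0.4, 0.4, 0.4) * 0.5,
                        phi0 + c(-1, 1, -1, 1, -2, 2, -2, 2) * 0.8))
  scale2 <- mean(radialDistances(p, colMeans(p), pl@normal))^2 + 1
  cands <- list()
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], objective, method = "Nelder-Mead",
                        control = list(maxit = max_iter * 4,
                                       reltol = 1e-15))
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = max_iter * 4,
                                       reltol = 1e-15))
    cands[[length(cands) + 1]] <- fit
    ## an exact solution on both criteria cannot be improved: stop early
    if (fit$value < 1e-16 * scale2 && riseStepVar(fit$par) < 1e-12 * scale2)
      break
  }
  vals <- vapply(cands, `[[`, numeric(1), "value")
  tied <- which(vals <= min(vals) * 1.05 + tol)
  pick <- tied[which.min(vapply(tied, function(k)
    riseStepVar(cands[[k]]$par), numeric(1)))]
  best <- cands[[pick]]
  converged <- best$value <= max(tol, init_var)
  par <- if (converged) best$par else c(theta0, phi0)
  d <- axisFromAngles(par[1], par[2])
  anc <- anchorForDirection(p, d)
  ## orient so mean rise along the ordered series is >= 0
  ax <- as.vector(sweep(p, 2, anc$point) %*% d)
  if (mean(diff(ax)) < 0) d <- -d
  list(point = anc$point, direction = d,
       radial_variance = anc$variance, converged = converged)
}

#' Pseudo-helical parameters of an ordered point series
#'
#' For each consecutive pair of points: rise = difference of axial
#' coordinates; twist = signed angle between the radial components in the
#' axis-normal plane (positive = right-handed screw when traversing the
#' points in order with the axis oriented along increasing rise). Means,
#' the turn pitch \code{mean_rise * 360 / |mean_twist|}, the total axial
#' extent, mean radius and radial rmsd are summarised in a
#' \code{\link{HelixFit}}. Handedness is "planar" when |mean rise| is below
#' \code{planar_tol}, else "right"/"left" by the sign of the mean twist
#' under the stated convention.
#'
#' @param points n x 3 ordered matrix (n >= 2), A.
#' @param axis list with \code{point} and \code{direction}, e.g. from
#'   \code{\link{fitHelicalAxis}}.
#' @param planar_tol rise (A) below which the series is called planar.
#' @return a \code{\link{HelixFit}}.
#' @export
helicalParameters <- function(points, axis, planar_tol = 1e-6) {
  p <- asPointMatrix(points)
  if (nrow(p) < 2) stop("need at least 2 points")
  d <- unitv(axis$direction)
  rel <- sweep(p, 2, axis$point)
  ax <- as.vector(rel %*% d)
  rad <- rel - outer(ax, d)
  rlen <- sqrt(rowSums(rad^2))
  if (any(rlen < 1e-9))
    stop("point ", which(rlen < 1e-9)[1],
         " lies on the helical axis; twist undefined")
  n <- nrow(p)
  rise <- diff(ax)
  twist <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    a <- rad[k, ]; b <- rad[k + 1, ]
    twist[k] <- atan2(sum(cross3(a, b) * d), sum(a * b)) * 180 / pi
  }
  mrise <- mean(rise)
  mtwist <- mean(twist)
  pitch <- if (abs(mtwist) > 1e-12) mrise * 360 / abs(mtwist) else Inf
  ## with the axis oriented along increasing rise, positive mean twist is a
  ## right-handed screw
  hand <- if (abs(mrise) <= planar_tol) "planar"
          else if (mtwist * sign(mrise) >= 0) "right" else "left"
  new("HelixFit",
      axisPoint = axis$point, axisDirection = d,
      risePerStep = rise, twistPerStep = twist,
      meanRise = mrise, meanTwist = mtwist, pitch = pitch,
      axialExtent = max(ax) - min(ax),
      meanRadius = mean(rlen),
      radialRmsd = sqrt(mean((rlen - mean(rlen))^2)),
      handedness = hand)
}

#' Fit a helix to a tier of a structure
#'
#' Extracts ordered domain centers, fits the pseudo-helical axis and
#' returns the helical parameters.
#'
#' @inheritParams tierPlaneAngle
#' @param tier a \code{\link{TierSpec}}.
#' @return a \code{\link{HelixFit}}.
#' @export
tierHelix <- function(structure, tier, atom_filter = "all",
                      weighting = "atomic_mass") {
  ctr <- tierCenters(structure, tier, atom_filter, weighting)$centers
  ctr <- ctr[stats::complete.cases(ctr), , drop = FALSE]
  helicalParameters(ctr, fitHelicalAxis(ctr))
}

#' Brute-force helical axis search (reference implementation)
#'
#' Exhaustive scan over axis orientations on an angular grid (with the
#' anchor re-optimised per orientation by the radial centroid), returning
#' the orientation with the smallest radial variance. Slow by construction;
#' intended as an independent check of \code{\link{fitHelicalAxis}} on
#' small point sets.
#'
#' @param points n x 3 matrix.
#' @param grid_deg angular grid spacing in degrees (default 2).
#' @return list like \code{\link{fitHelicalAxis}}.
#' @export
bruteForceAxis <- function(points, grid_deg = 2) {
  p <- asPointMatrix(points)
  best <- list(radial_variance = Inf)
  for (th in seq(0, 90, by = grid_deg)) {
    for (ph in seq(0, 360 - grid_deg, by = grid_deg)) {
      d <- axisFromAngles(th * pi / 180, ph * pi / 180)
      anc <- anchorForDirection(p, d)
      if (anc$variance < best$radial_variance)
        best <- list(point = anc$point, direction = d,
                     radial_variance = anc$variance, converged = TRUE)
    }
  }
  ax <- as.vector(sweep(p, 2, best$point) %*% best$direction)
  if (mean(diff(ax)) < 0) best$direction <- -best$direction
  best
}
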