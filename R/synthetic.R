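## Synthetic-assembly generators: ideal (optionally noise-perturbed and
## breached) N-subunit helices and planar rings with known ground truth,
## charge-state peak series, and crosslink fixtures with planted
## violations. Every generator is a pure function of its parameter record
## including the seed (R's Mersenne-Twister, set per call), so fixtures
## are bit-identical across reruns.

#' Parameters of an ideal pseudo-helical subunit arrangement
#'
#' @param n_subunits number of subunits (>= 3).
#' @param rise axial displacement per subunit, A (0 gives a planar ring).
#' @param twist rotation per subunit, degrees (positive = right-handed
#'   with the axis along increasing rise).
#' @param radius distance of each subunit center from the axis, A (> 0).
#' @param axis_point,axis_direction axis pose (defaults: origin, +z).
#' @param noise_sd isotropic Gaussian noise on each point, A.
#' @param seed integer seed for the noise.
#' @return parameter record (list) for \code{\link{makeHelixPoints}}.
#' @export
HelixParams <- function(n_subunits, rise, twist, radius,
                        axis_point = c(0, 0, 0),
                        axis_direction = c(0, 0, 1),
                        noise_sd = 0, seed = 1L) {
  stopifnot(n_subunits >= 3, radius > 0, noise_sd >= 0)
  list(n_subunits = as.integer(n_subunits), rise = rise, twist = twist,
       radius = radius, axis_point = axis_point,
       axis_direction = unitv(axis_direction),
       noise_sd = noise_sd, seed = as.integer(seed),
       rng = "Mersenne-Twister")
}

## orthonormal frame (e1, e2, d) for a unit axis direction d
axisFrame <- function(d) {
  e1 <- unitv(if (abs(d[3]) < 0.9) cross3(d, c(0, 0, 1)) else
              cross3(d, c(1, 0, 0)))
  list(e1 = e1, e2 = cross3(d, e1), d = d)
}

#' Generate ordered points on an ideal helix
#'
#' Point k (k = 0..n-1) sits at angle \code{k * twist}, height
#' \code{k * rise} and distance \code{radius} from the axis, plus optional
#' seeded Gaussian noise. The generating parameters are returned alongside
#' as ground truth.
#'
#' @param params record from \code{\link{HelixParams}}.
#' @return list with \code{points} (n x 3 matrix) and \code{truth}
#'   (the parameter record).
#' @export
makeHelixPoints <- function(params) {
  fr <- axisFrame(params$axis_direction)
  k <- seq_len(params$n_subunits) - 1
  th <- k * params$twist * pi / 180
  p <- outer(params$radius * cos(th), fr$e1) +
       outer(params$radius * sin(th), fr$e2) +
       outer(k * params$rise, fr$d)
  p <- sweep(p, 2, params$axis_point, "+")
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    p <- p + matrix(stats::rnorm(length(p), 0, params$noise_sd), ncol = 3)
  }
  colnames(p) <- c("x", "y", "z")
  list(points = p, truth = params)
}

#' Parameters of a synthetic multi-subunit assembly
#'
#' Extends \code{\link{HelixParams}} with a pseudo-atom cloud per subunit
#' and optional planted features: a breached interface (the subunits after
#' \code{breach_after} are displaced so that the minimum inter-atomic gap
#' across the breached interface equals \code{breach_gap}) and a second
#' tier with its own rise/twist, an axial offset and an inter-tier tilt.
#' Pseudo-atoms are all carbon (one vdW radius, one mass), which keeps the
#' surface-area and diameter oracles analytic.
#'
#' @inheritParams HelixParams
#' @param atoms_per_domain pseudo-atoms per subunit.
#' @param domain_radius radius of each subunit's atom cloud, A.
#' @param breach_after index i: breach the interface between subunits i
#'   and i+1 (NULL for none).
#' @param breach_gap planted minimum inter-atomic gap, A.
#' @param tier2 optional list(rise, twist, tilt_deg, offset) for a second
#'   tier: same n_subunits/radius, axis tilted by \code{tilt_deg} about
#'   the x-axis and shifted \code{offset} A along +z.
#' @return parameter record for \code{\link{makeAssembly}}.
#' @export
AssemblyParams <- function(n_subunits, rise, twist, radius,
                           atoms_per_domain = 30L, domain_radius = 6,
                           noise_sd = 0, seed = 1L,
                           breach_after = NULL, breach_gap = 0,
                           tier2 = NULL, nz_offset = 0) {
  stopifnot(breach_gap >= 0, nz_offset >= 0)
  c(HelixParams(n_subunits, rise, twist, radius, noise_sd = noise_sd,
                seed = seed),
    list(atoms_per_domain = as.integer(atoms_per_domain),
         domain_radius = domain_radius, breach_after = breach_after,
         breach_gap = breach_gap, tier2 = tier2, nz_offset = nz_offset))
}

## A zero-mean pseudo-atom cloud: atoms_per_domain points in a ball of the
## given radius, centered so the cloud COM is exactly at the origin.
domainCloud <- function(n, radius) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * radius * stats::runif(n)^(1 / 3)
  sweep(u, 2, colMeans(u))
}

tierAtoms <- function(centers, params, chain_ids, resno_offset = 0) {
  nz <- if (is.null(params$nz_offset)) 0 else params$nz_offset
  out <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cloud <- sweep(domainCloud(params$atoms_per_domain,
                               params$domain_radius), 2, centers[i, ], "+")
    ca <- data.frame(
      chain = chain_ids[i],
      resno = resno_offset + seq_len(nrow(cloud)),
      resid = if (nz > 0) "LYS" else "GLY", atom = "CA", element = "C",
      x = cloud[, 1], y = cloud[, 2], z = cloud[, 3],
      occupancy = 1, stringsAsFactors = FALSE)
    if (nz > 0) {
      ## pseudo side-chain atom at a seeded random offset; element kept
      ## carbon so the one-radius surface/diameter oracles stay analytic
      u <- matrix(stats::rnorm(3 * nrow(cloud)), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * nz
      nzrow <- ca
      nzrow$atom <- "NZ"
      nzrow$x <- ca$x + u[, 1]; nzrow$y <- ca$y + u[, 2]
      nzrow$z <- ca$z + u[, 3]
      ca <- rbind(ca, nzrow)
      ca <- ca[order(ca$resno), , drop = FALSE]
    }
    out[[i]] <- ca
  }
  do.call(rbind, out)
}

#' Generate a synthetic assembly with known ground truth
#'
#' Builds one (optionally two) tier(s) of pseudo-subunits: each subunit is
#' a seeded carbon pseudo-atom cloud whose center of mass sits exactly on
#' its helix point. Subunits are chains A, B, C, ... with one CA atom per
#' residue. A planted breach displaces all subunits after the breach point
#' along the closest-atom direction until the minimum inter-atomic gap
#' across the breached interface equals the requested value (to < 0.01 A,
#' by fixed-point iteration on the realised gap).
#'
#' @param params record from \code{\link{AssemblyParams}}.
#' @return list with \code{structure} (\code{\link{Structure}}),
#'   \code{tiers} (named list of \code{\link{TierSpec}}), and
#'   \code{truth} (parameter record plus realised breach gap).
#' @export
makeAssembly <- function(params) {
  set.seed(params$seed)
  n <- params$n_subunits
  chains <- LETTERS[seq_len(n)]
  centers <- makeHelixPoints(params)$points
  at <- tierAtoms(centers, params, chains)
  tiers <- list(tier1 = TierSpec("tier1", lapply(seq_len(n), function(i)
    DomainSpec(paste0("tier1-", chains[i]), chains[i], 1,
               params$atoms_per_domain))))
  if (!is.null(params$tier2)) {
    t2 <- params$tier2
    tilt <- t2$tilt_deg * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(tilt), -sin(tilt)),
                c(0, sin(tilt), cos(tilt)))
    p2 <- HelixParams(n, t2$rise, t2$twist, params$radius,
                      noise_sd = params$noise_sd, seed = params$seed + 1L)
    c2 <- makeHelixPoints(p2)$points %*% t(Rx)
    c2[, 3] <- c2[, 3] + t2$offset
    at2 <- tierAtoms(c2, params, chains,
                     resno_offset = params$atoms_per_domain + 100)
    at <- rbind(at, at2)
    tiers$tier2 <- TierSpec("tier2", lapply(seq_len(n), function(i)
      DomainSpec(paste0("tier2-", chains[i]), chains[i],
                 params$atoms_per_domain + 101,
                 params$atoms_per_domain + 100 + params$atoms_per_domain)))
  }
  realised_gap <- NA_real_
  if (!is.null(params$breach_after)) {
    ## Open the ring like a spiral: subunits after the breach are displaced
    ## along the opening direction with a linear taper (full displacement
    ## next to the breach, none at the far end), so the wrap-around
    ## interface stays closed and the planted opening is the widest gap.
    ## The displacement magnitude is solved by fixed-point iteration on
    ## the realised minimum inter-atomic gap.
    i <- params$breach_after
    stopifnot(i >= 1, i < n)
    selA <- at$chain == chains[i]
    w <- stats::setNames(numeric(n), chains)
    moved <- (i + 1):n
    w[moved] <- if (length(moved) > 1)
      rev(seq(0, 1, length.out = length(moved))) else 1
    for (iter in 1:10) {
      a <- as.matrix(at[selA, c("x", "y", "z")])
      b <- as.matrix(at[at$chain == chains[i + 1], c("x", "y", "z")])
      best <- minPairDistance(b, a)   # move the far side away from A
      u <- unitv(b[best$i, ] - a[best$j, ])
      shift <- params$breach_gap - best$d
      if (abs(shift) < 0.005) break
      for (k in moved) {
        sk <- at$chain == chains[k]
        at[sk, c("x", "y", "z")] <-
          sweep(as.matrix(at[sk, c("x", "y", "z")]), 2,
                w[k] * shift * u, "+")
      }
    }
    a <- as.matrix(at[selA, c("x", "y", "z")])
    b <- as.matrix(at[at$chain == chains[i + 1], c("x", "y", "z")])
    realised_gap <- minPairDistance(b, a)$d
  }
  rownames(at) <- NULL
  s <- new("Structure", atoms = at, source = c("<synthetic>", "generated"))
  list(structure = s, tiers = tiers,
       truth = c(params, list(centers = centers,
                              realised_gap = realised_gap)))
}

#' Generate a charge-state peak series for a known mass
#'
#' m/z = (mass + z * adduct) / z for each charge in \code{charges}, plus
#' optional seeded Gaussian m/z noise.
#'
#' @param mass species mass, Da.
#' @param charges positive integer charges (consecutive for inference).
#' @param adduct charge-carrier mass, Da (default proton).
#' @param mz_noise_sd Gaussian noise on each m/z, Th.
#' @param seed integer seed.
#' @return list with \code{mz} (sorted decreasing), \code{charges} and
#'   \code{truth}.
#' @export
makePeakSeries <- function(mass, charges, adduct = protonMass,
                           mz_noise_sd = 0, seed = 1L) {
  stopifnot(all(charges > 0), mass > 0)
  set.seed(seed)
  mz <- (mass + charges * adduct) / charges
  if (mz_noise_sd > 0) mz <- mz + stats::rnorm(length(mz), 0, mz_noise_sd)
  ord <- order(mz, decreasing = TRUE)
  list(mz = mz[ord], charges = charges[ord],
       truth = list(mass = mass, adduct = adduct,
                    mz_noise_sd = mz_noise_sd, seed = seed))
}

#' Generate a crosslink fixture with planted violations
#'
#' Samples residue pairs from a structure so that \code{n_satisfied}
#' pairs have atom distances in [margin, cutoff - margin] and
#' \code{n_violated} pairs exceed cutoff + margin, writes them as a
#' crosslink table, and returns the ground truth. Infeasible requests
#' (not enough residue pairs in the required distance bands) error.
#'
#' @param structure a \code{\link{Structure}} (pairs are drawn from its
#'   CA atoms).
#' @param n_satisfied,n_violated planted pair counts.
#' @param cutoff classification cutoff, A (default 30).
#' @param margin distance margin around the cutoff, A (default 5): keeps
#'   the plant robust to the choice of distance atom.
#' @param seed integer seed.
#' @return list with \code{pairs} (data.frame in
#'   \code{\link{parseCrosslinkTable}} layout), \code{protein_chain_map}
#'   (each chain its own protein), and \code{truth}.
#' @export
makeCrosslinkFixture <- function(structure, n_satisfied, n_violated,
                                 cutoff = 30, margin = 5, seed = 1L) {
  set.seed(seed)
  a <- atoms(structure)
  a <- a[a$atom == "CA", , drop = FALSE]
  if (n_satisfied + n_violated == 0) {
    return(list(pairs = data.frame(protein_1 = character(),
                                   residue_1 = integer(),
                                   protein_2 = character(),
                                   residue_2 = integer(),
                                   annotation = character(),
                                   intermolecular = logical()),
                protein_chain_map = list(), truth = list(planted = c(0, 0))))
  }
  p <- cbind(a$x, a$y, a$z)
  d <- as.matrix(stats::dist(p))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[ut]
  sat_pool <- which(dd >= margin & dd <= cutoff - margin)
  vio_pool <- which(dd >= cutoff + margin)
  if (length(sat_pool) < n_satisfied || length(vio_pool) < n_violated)
    stop("infeasible request: not enough residue pairs in the required ",
         "distance bands (have ", length(sat_pool), " satisfied / ",
         length(vio_pool), " violated candidates)")
  pick <- c(sample(sat_pool, n_satisfied), sample(vio_pool, n_violated))
  i <- ut[pick, 1]; j <- ut[pick, 2]
  pairs <- data.frame(
    protein_1 = paste0("prot", a$chain[i]), residue_1 = a$resno[i],
    protein_2 = paste0("prot", a$chain[j]), residue_2 = a$resno[j],
    annotation = rep(c("planted-satisfied", "planted-violated"),
                     c(n_satisfied, n_violated)),
    stringsAsFactors = FALSE)
  pairs$intermolecular <- pairs$protein_1 != pairs$protein_2
  chains <- sort(unique(a$chain))
  map <- stats::setNames(as.list(chains), paste0("prot", chains))
  list(pairs = pairs, protein_chain_map = map,
       truth = list(planted = c(satisfied = n_satisfied,
                                violated = n_violated),
                    distances = dd[pick], cutoff = cutoff, seed = seed))
}
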