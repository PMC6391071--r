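test_that("fitPlane recovers constructed planes", {
  ring <- makeHelixPoints(HelixParams(6, 0, 60, 20))$points
  pl <- fitPlane(ring)
  expect_equal(abs(pl@normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl@centroid[3], 0, tolerance = 1e-9)
  ## plane z = x tan(15deg)
  tilted <- ring
  tilted[, 3] <- ring[, 1] * tan(15 * pi / 180)
  ang <- acos(abs(fitPlane(tilted)@normal[3])) * 180 / pi
  expect_equal(ang, 15, tolerance = 1e-9)
  ## alternating +-delta hexagon: centroid and normal stay on z
  alt <- ring
  alt[, 3] <- rep(c(0.8, -0.8), 3)
  pl2 <- fitPlane(alt)
  expect_equal(pl2@centroid[3], 0, tolerance = 1e-9)
  expect_equal(abs(pl2@normal[3]), 1, tolerance = 1e-9)
  ## collinear input is degenerate
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fitPlane(line), "collinear|degenerate")
})

test_that("planeAngle is the acute dihedral, symmetric and bounded", {
  mk <- function(n) new("Plane", centroid = c(0, 0, 0), normal = n)
  a <- mk(c(0, 0, 1))
  expect_equal(planeAngle(a, a), 0)
  b <- mk(c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  expect_equal(planeAngle(a, b), 10, tolerance = 1e-9)
  expect_equal(planeAngle(b, a), planeAngle(a, b))
  ## anti-parallel normals are the same plane
  expect_equal(planeAngle(a, mk(c(0, 0, -1))), 0, tolerance = 1e-9)
  ## fixture at 90 degrees
  expect_equal(planeAngle(a, mk(c(1, 0, 0))), 90, tolerance = 1e-9)
})

test_that("noise-free helices are recovered to 1e-6 across the grid", {
  for (rise in c(0.5, 4.1, 10)) {
    for (twist in c(30, 56.4, 70)) {
      for (radius in c(10, 50)) {
        p <- makeHelixPoints(HelixParams(6, rise, twist, radius))$points
        hx <- helicalParameters(p, fitHelicalAxis(p))
        expect_equal(meanRise(hx), rise, tolerance = 1e-6)
        expect_equal(meanTwist(hx), twist, tolerance = 1e-6)
        expect_equal(hx@meanRadius, radius, tolerance = 1e-6)
        expect_equal(handedness(hx), "right")
      }
    }
  }
})

test_that("noisy helices are recovered within 3 sigma / sqrt(n)", {
  sigma <- 0.5
  n <- 8
  p <- makeHelixPoints(HelixParams(n, 4.1, 56.4, 30, noise_sd = sigma,
                                   seed = 7))$points
  hx <- helicalParameters(p, fitHelicalAxis(p))
  expect_lt(abs(meanRise(hx) - 4.1), 3 * sigma / sqrt(n))
})

test_that("planar rings report zero rise and planar handedness", {
  ring <- makeHelixPoints(HelixParams(6, 0, 60, 20))$points
  ax <- fitHelicalAxis(ring)
  ## axis equals the ring normal; all radii equal
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  expect_lt(ax$radial_variance, 1e-12)
  hx <- helicalParameters(ring, ax)
  expect_equal(meanRise(hx), 0, tolerance = 1e-9)
  expect_equal(handedness(hx), "planar")
  expect_equal(meanTwist(hx), 60, tolerance = 1e-6)
})

test_that("helical parameters are invariant under rigid motion", {
  p <- makeHelixPoints(HelixParams(6, 7.4, 60, 30))$points
  R <- rotZ(40) %*% rotX(29)
  p2 <- p %*% t(R) + matrix(rep(c(5, -3, 10), each = 6), ncol = 3)
  hx <- helicalParameters(p2, fitHelicalAxis(p2))
  expect_equal(meanRise(hx), 7.4, tolerance = 1e-6)
  expect_equal(meanTwist(hx), 60, tolerance = 1e-6)
  expect_equal(helixPitch(hx), 44.4, tolerance = 1e-6)
  expect_equal(handedness(hx), "right")
})

test_that("mirroring the input flips handedness", {
  p <- makeHelixPoints(HelixParams(6, 7.4, 60, 30))$points
  m <- p
  m[, 1] <- -m[, 1]
  expect_equal(handedness(helicalParameters(p, fitHelicalAxis(p))), "right")
  expect_equal(handedness(helicalParameters(m, fitHelicalAxis(m))), "left")
})

test_that("refined axis never underperforms an exhaustive orientation scan", {
  for (seed in 1:3) {
    par <- HelixParams(6, 4.1 + seed, 50 + 5 * seed, 25,
                       noise_sd = 0.3, seed = seed)
    p <- makeHelixPoints(par)$points
    ours <- fitHelicalAxis(p)$radial_variance
    brute <- bruteForceAxis(p, grid_deg = 2)$radial_variance
    expect_lte(ours, brute + 1e-12)
  }
})

test_that("a point on the axis makes the twist undefined, with a clear error", {
  p <- rbind(c(0, 0, 0), c(10, 0, 5), c(0, 10, 10), c(-10, 0, 15))
  expect_error(
    helicalParameters(p, list(point = c(0, 0, -1), direction = c(0, 0, 1))),
    "axis")
})

test_that("the turn pitch identity holds in every HelixFit", {
  for (twist in c(30, 56.4, 60)) {
    p <- makeHelixPoints(HelixParams(6, 4.1, twist, 30))$points
    hx <- helicalParameters(p, fitHelicalAxis(p))
    expect_equal(helixPitch(hx) * abs(meanTwist(hx)) / 360, meanRise(hx),
                 tolerance = 1e-6)
    ## the axial extent of an n-point spiral is (n-1) * rise
    expect_equal(hx@axialExtent, 5 * meanRise(hx), tolerance = 1e-6)
  }
})

test_that("interfaceGap measures planted separations in all modes", {
  a <- atomRow(0, 0, 0)
  b <- atomRow(15, 0, 0, chain = "B")
  expect_equal(interfaceGap(a, b)$min_distance, 15)
  expect_equal(interfaceGap(a, b, "ca_ca")$min_distance, 15)
  ## surface mode subtracts both carbon radii
  expect_equal(interfaceGap(a, b, "surface")$min_distance, 15 - 2 * 1.7)
  expect_error(interfaceGap(a[0, ], b), "empty")
})

test_that("a planted breach is recovered as the unique maximal gap", {
  ## breach a planar closed ring, the ring-opening scenario
  asm <- makeAssembly(AssemblyParams(6, 0, 60, 20, seed = 3,
                                     breach_after = 1, breach_gap = 20))
  gA <- selectDomain(asm$structure, tierDomains(asm$tiers$tier1)[[1]])
  gB <- selectDomain(asm$structure, tierDomains(asm$tiers$tier1)[[2]])
  expect_equal(interfaceGap(gA, gB)$min_distance, 20, tolerance = 0.5)
  gaps <- tierGaps(asm$structure, asm$tiers$tier1)
  expect_equal(which.max(gaps$gap), 1L)
  expect_equal(sum(gaps$gap > 15), 1L)
})

test_that("chamberDiameter matches the analytic cylinder", {
  ## ring of carbon pseudo-atoms at radius 10 about z: 2 * (10 - 1.7)
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  ring <- do.call(rbind, lapply(seq_along(th), function(i)
    atomRow(10 * cos(th[i]), 10 * sin(th[i]), 0, resno = i)))
  axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  d1 <- chamberDiameter(ring, axis)
  expect_equal(d1$diameter, 16.6, tolerance = 1e-9)
  ## a cylinder of several such rings gives the same constriction
  cyl <- do.call(rbind, lapply(0:4, function(k) {
    r <- ring
    r$z <- r$z + 4 * k
    r$resno <- r$resno + 100 * k
    r
  }))
  expect_equal(chamberDiameter(cyl, axis)$diameter, 16.6, tolerance = 1e-9)
})

test_that("superpose recovers constructed transforms and agrees with bio3d", {
  asm <- standardAssembly()
  a <- selectDomain(asm$structure, tierDomains(asm$tiers$tier1)[[1]])
  self <- superpose(a, a)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$angle, 0, tolerance = 1e-4)
  b <- moveAtoms(a, rotZ(25), c(3, 4, 5))
  fit <- superpose(b, a)
  expect_equal(fit$angle, 25, tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  ## independent cross-check against bio3d's superposition rmsd
  xyz_b <- as.vector(t(as.matrix(b[, c("x", "y", "z")])))
  xyz_a <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  moved <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b))
  expect_equal(bio3d::rmsd(xyz_a, moved), fit$rmsd, tolerance = 1e-4)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "3")
})

test_that("subunitRotation isolates the probe rotation", {
  asm <- standardAssembly()
  anchor <- tierDomains(asm$tiers$tier1)[[1]]
  probe <- tierDomains(asm$tiers$tier1)[[4]]
  ## identical complexes: zero residual rotation
  r0 <- subunitRotation(asm$structure, asm$structure, anchor, probe)
  expect_equal(r0$angle, 0, tolerance = 1e-6)
  ## rotate only the probe domain by 20 degrees about its own COM axis
  at <- atoms(asm$structure)
  sel <- at$chain == probe@chain
  com <- centerOfMass(at[sel, ])
  at[sel, c("x", "y", "z")] <-
    moveAtoms(at[sel, ], rotZ(20),
              com - as.vector(rotZ(20) %*% com))[, c("x", "y", "z")]
  s2 <- new("Structure", atoms = at, source = c("<mod>", "generated"))
  r1 <- subunitRotation(asm$structure, s2, anchor, probe)
  expect_equal(r1$angle, 20, tolerance = 1e-6)
})

test_that("residueCaDisplacement reports planted shifts and unmapped residues", {
  asm <- standardAssembly()
  d0 <- residueCaDisplacement(asm$structure, asm$structure,
                              tierDomains(asm$tiers$tier1)[[1]],
                              chain = "C", residues = c(5, 10, 15))
  expect_equal(d0$displacement, c(0, 0, 0), tolerance = 1e-9)
  ## translate three residues of chain C by 5 A
  at <- atoms(asm$structure)
  sel <- at$chain == "C" & at$resno %in% c(5, 10, 15)
  at$x[sel] <- at$x[sel] + 3
  at$y[sel] <- at$y[sel] + 4
  s2 <- new("Structure", atoms = at, source = c("<mod>", "generated"))
  d1 <- residueCaDisplacement(asm$structure, s2,
                              tierDomains(asm$tiers$tier1)[[1]],
                              chain = "C", residues = c(5, 10, 15, 999))
  expect_equal(d1$displacement[1:3], c(5, 5, 5), tolerance = 1e-9)
  expect_true(is.na(d1$displacement[4]))
})

test_that("classifyIsomer resolves the hairpin orientation", {
  globe <- atomRow(0, 0, 0)
  ctd <- atomRow(10, 0, 0, chain = "A", resno = 50)
  toward <- atomRow(5, 0, 0, resno = 20)
  away <- atomRow(-5, 0, 0, resno = 20)
  expect_equal(classifyIsomer(globe, toward, ctd), "cis")
  expect_equal(classifyIsomer(globe, away, ctd), "trans")
  side <- atomRow(0.01, 5, 0, resno = 20)
  expect_equal(classifyIsomer(globe, side, ctd), "cis")
  expect_error(classifyIsomer(globe, globe, ctd), "degenerate")
})
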