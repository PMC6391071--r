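test_that("protein average masses follow the residue table", {
  expect_equal(proteinAverageMass("G"), 75.07, tolerance = 0.01)
  expect_equal(proteinAverageMass("MG", n_terminal_met_loss = TRUE),
               proteinAverageMass("G"))
  expect_error(proteinAverageMass(""), "empty")
  expect_error(proteinAverageMass("GXZ"), "non-standard")
  expect_error(proteinAverageMass("GA", n_terminal_met_loss = TRUE), "M")
})

test_that("ssDNA average masses handle termini correctly", {
  ## the origin-derived 43-mer with 5'/3'-OH
  expect_equal(ssdnaAverageMass(oriLambdaDUE43), 13141, tolerance = 1)
  ## a single T with both OH is thymidine
  expect_equal(ssdnaAverageMass("T"), 242.2, tolerance = 0.1)
  ## 5'-phosphate adds one HPO3
  expect_equal(ssdnaAverageMass(oriLambdaDUE43, five_prime = "phosphate") -
                 ssdnaAverageMass(oriLambdaDUE43), 79.98, tolerance = 0.01)
  expect_equal(ssdnaAverageMass("T", three_prime = "phosphate") -
                 ssdnaAverageMass("T"), 79.98, tolerance = 0.01)
  expect_error(ssdnaAverageMass("ACGU"), "non-ACGT")
  expect_error(ssdnaAverageMass(""), "empty")
})

test_that("complexMass is linear in counts", {
  mm <- c(DnaB = 52259, lambdaP = 26518)
  expect_equal(complexMass(mm, c(DnaB = 6, lambdaP = 5)), 446144)
  expect_equal(complexMass(mm, c(DnaB = 6, lambdaP = 5)) +
                 complexMass(mm, c(DnaB = 0, lambdaP = 1)),
               complexMass(mm, c(DnaB = 6, lambdaP = 6)))
  expect_equal(complexMass(numeric(0), numeric(0)), 0)
})

test_that("massError reproduces delta/percent and is scale-invariant", {
  e <- massError(446500, 446145)
  expect_equal(e$delta, 355)
  expect_equal(round(e$percent, 2), 0.08)
  expect_equal(massError(5, 5)$percent, 0)
  for (k in c(0.5, 2, 10))
    expect_equal(massError(k * 446500, k * 446145)$percent, e$percent)
  expect_error(massError(1, 0), "positive")
})

test_that("the measured-assembly regression table reproduces printed errors", {
  ## measured masses of the three self-consistent assemblies (in magnesium
  ## acetate buffer) and the ssDNA-bound complex
  counts <- rbind(c(6, 5, 0), c(6, 6, 0), c(6, 5, 1))
  colnames(counts) <- c("DnaB", "lambdaP", "ssDNA")
  tab <- assemblyMassTable(c(446500, 473100, 459480), counts)
  expect_equal(tab$delta, c(355, 437, 195), tolerance = 2)
  expect_equal(tab$percent_error, c(0.08, 0.09, 0.04))
  ## the three expected masses agree with the printed sums within 2 Da
  expect_equal(tab$expected, c(446145, 472663, 459285), tolerance = 2)
})

test_that("decomposeMass matches an exhaustive brute-force oracle", {
  comps <- data.frame(name = c("DnaB", "lambdaP"),
                      monomer_mass = c(52259, 26518),
                      count_min = c(0, 0), count_max = c(6, 8))
  bruteBest <- function(measured) {
    best <- NULL
    for (i in 0:6) for (j in 0:8) {
      d <- abs(measured - (i * 52259 + j * 26518))
      if (is.null(best) || d < best$d ||
          (d == best$d && i + j < best$i + best$j))
        best <- list(i = i, j = j, d = d)
    }
    best
  }
  for (m in c(446500, 473100, 419950)) {
    top <- decomposeMass(m, comps, tolerance = 500)[1, ]
    oracle <- bruteBest(m)
    expect_equal(top$DnaB, oracle$i)
    expect_equal(top$lambdaP, oracle$j)
  }
  ## headline assignments over the open count ranges
  expect_equal(unlist(decomposeMass(446500, comps, 500)[1, 1:2]),
               c(DnaB = 6L, lambdaP = 5L))
  expect_equal(unlist(decomposeMass(419950, comps, 500)[1, 1:2]),
               c(DnaB = 6L, lambdaP = 4L))
  ## with an unconstrained helicase count, 473,100 Da is actually closer
  ## to a 5-helicase/8-loader composition than to hexamer+6 loaders;
  ## fixing the helicase at its hexameric count recovers the published
  ## assignment
  expect_equal(unlist(decomposeMass(473100, comps, 500)[1, 1:2]),
               c(DnaB = 5L, lambdaP = 8L))
  hexed <- comps
  hexed$count_min[1] <- 6
  expect_equal(unlist(decomposeMass(473100, hexed, 500)[1, 1:2]),
               c(DnaB = 6L, lambdaP = 6L))
  ## oracle equivalence across a coarse measured-mass grid
  for (m in seq(3e5, 5e5, by = 1e4)) {
    top <- decomposeMass(m, comps)[1, ]
    oracle <- bruteBest(m)
    expect_equal(abs(top$delta), oracle$d)
  }
})

test_that("decomposeMass handles exact, singleton and invalid ranges", {
  one <- data.frame(name = "X", monomer_mass = 1000,
                    count_min = 0, count_max = 5)
  hit <- decomposeMass(2000, one, tolerance = 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$X, 2)
  ## singleton ranges with infinite tolerance: exactly one composition
  fixed <- data.frame(name = c("A", "B"), monomer_mass = c(100, 10),
                      count_min = c(2, 3), count_max = c(2, 3))
  all <- decomposeMass(500, fixed)
  expect_equal(nrow(all), 1L)
  expect_equal(all$expected_mass, 230)
  expect_error(decomposeMass(1, one[0, ]), "empty")
  bad <- one
  bad$count_max <- Inf
  expect_error(decomposeMass(1, bad), "unbounded")
})

test_that("tie-breaking prefers fewer total subunits deterministically", {
  comps <- data.frame(name = c("A", "B"), monomer_mass = c(200, 100),
                      count_min = c(0, 0), count_max = c(4, 8))
  ## 400 Da: (2,0) and (1,2) and (0,4) all exact; fewest subunits wins
  top <- decomposeMass(400, comps, tolerance = 0)
  expect_equal(unlist(top[1, 1:2]), c(A = 2, B = 0))
})

test_that("charge-series inference recovers masses and flags corruption", {
  ## noise-free recovery within 1 Da
  ps <- makePeakSeries(446145, 40:50)
  out <- inferMassFromSeries(ps$mz)
  expect_equal(out$mass, 446145, tolerance = 1)
  expect_equal(sort(out$charges), 40:50)
  ## two peaks from z and z+1: exact closed-form recovery
  m <- 10000
  mz2 <- c((m + 5 * protonMass) / 5, (m + 6 * protonMass) / 6)
  expect_equal(inferMassFromSeries(mz2)$mass, m, tolerance = 1e-6)
  ## a corrupted peak inflates the SD beyond the acceptance threshold
  bad <- ps$mz
  bad[5] <- bad[5] + 5
  expect_error(inferMassFromSeries(bad), "SD")
  ## with a permissive threshold the per-peak residual names the culprit
  loose <- inferMassFromSeries(bad, max_sd = 1e6)
  expect_equal(which.max(abs(loose$per_peak$residual)), 5L)
  expect_error(inferMassFromSeries(ps$mz[1]), ">= 2")
})
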