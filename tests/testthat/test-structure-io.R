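test_that("synthetic assemblies survive a PDB write/read round trip", {
  asm <- standardAssembly()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(asm$structure, f)
  s2 <- loadStructure(f)
  expect_equal(length(s2), length(asm$structure))
  ## format precision is 3 decimals
  expect_lt(max(abs(atoms(s2)$x - atoms(asm$structure)$x)), 5e-4 + 1e-12)
  expect_lt(max(abs(atoms(s2)$z - atoms(asm$structure)$z)), 5e-4 + 1e-12)
  expect_identical(atoms(s2)$chain, atoms(asm$structure)$chain)
})

test_that("a minimal hand-written PDB parses to the printed coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      -4.500   0.250  10.125  1.00  0.00           C",
    "END"), f)
  s <- loadStructure(f)
  expect_equal(length(s), 2L)
  expect_equal(atoms(s)$x, c(1, -4.5))
  expect_equal(atoms(s)$z, c(3, 10.125))
  expect_equal(atoms(s)$resno, c(1L, 2L))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AALA A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       9.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- loadStructure(f)
  expect_equal(length(s), 2L)
  ## residue 1: B wins on occupancy; residue 2: tie resolved to altloc A
  expect_equal(atoms(s)$x[atoms(s)$resno == 1], 5)
  expect_equal(atoms(s)$x[atoms(s)$resno == 2], 1)
})

test_that("unreadable files and unknown elements are rejected", {
  expect_error(loadStructure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  QQ  UNK A   1       0.000   0.000   0.000  1.00  0.00          Xx",
    "END"), f)
  expect_error(loadStructure(f), "unknown element")
})

test_that("DomainSpec rejects inverted intervals at construction", {
  expect_error(DomainSpec("d", "A", 1, 0), "inverted|start")
  expect_s4_class(DomainSpec("d", "A", 5, 5), "DomainSpec")
})

test_that("TierSpec requires at least three explicitly ordered domains", {
  d <- lapply(1:2, function(i) DomainSpec(paste0("d", i), "A", 1, 10))
  expect_error(TierSpec("t", d), "at least 3")
})

test_that("selectDomain returns exactly the interval, in order, idempotently", {
  asm <- standardAssembly()
  spec <- DomainSpec("mid", "B", 10, 19)
  sel <- selectDomain(asm$structure, spec)
  expect_equal(sort(unique(sel$resno)), 10:19)
  expect_true(all(sel$chain == "B"))
  expect_false(is.unsorted(sel$resno))
  ## order-stable: re-selecting from the selection context gives the same
  sel2 <- selectDomain(asm$structure, spec)
  expect_identical(sel, sel2)
  ## an entirely unmodelled interval is an empty, non-error selection
  empty <- selectDomain(asm$structure, DomainSpec("gone", "B", 500, 600))
  expect_equal(nrow(empty), 0L)
  expect_error(selectDomain(asm$structure, DomainSpec("x", "Q", 1, 5)),
               "chain")
})

test_that("centerOfMass does mass- and uniform-weighted averaging", {
  expect_equal(unname(centerOfMass(atomRow(1, 2, 3))), c(1, 2, 3))
  two <- rbind(atomRow(0, 0, 0), atomRow(2, 0, 0, resno = 2))
  expect_equal(unname(centerOfMass(two)), c(1, 0, 0))
  ## one carbon at origin, one oxygen at (1,0,0)
  co <- rbind(atomRow(0, 0, 0, element = "C"),
              atomRow(1, 0, 0, resno = 2, element = "O", atom = "O"))
  expect_equal(unname(centerOfMass(co, "uniform")), c(0.5, 0, 0))
  expect_equal(unname(centerOfMass(co, "atomic_mass")),
               c(15.999 / (12.011 + 15.999), 0, 0), tolerance = 1e-12)
  expect_error(centerOfMass(co[0, ]), "empty")
})

test_that("centerOfMass is equivariant under rigid motion", {
  asm <- standardAssembly()
  sel <- selectDomain(asm$structure, asm$tiers$tier1@domains[[3]])
  R <- rotZ(37) %*% rotX(18)
  t <- c(4, -7, 12)
  com0 <- centerOfMass(sel)
  com1 <- centerOfMass(moveAtoms(sel, R, t))
  expect_equal(unname(com1), as.vector(R %*% com0 + t), tolerance = 1e-9)
})

test_that("the shipped tier configuration parses into ordered TierSpecs", {
  cfg <- readTierConfig(system.file("extdata", "tiers_bp_complex.yaml",
                                    package = "ringtier"))
  expect_true(all(c("CTD", "NTD-globe", "loader") %in% names(cfg)))
  expect_equal(length(cfg$CTD), 6L)
  expect_equal(length(cfg$loader), 5L)
  ## spiral order is explicit: bottom chain A, top chain B
  chains <- vapply(tierDomains(cfg$CTD), function(d) d@chain, "")
  expect_equal(chains[1], "A")
  expect_equal(chains[6], "B")
  ## both globe conventions are selectable
  expect_true(all(c("NTD-head", "NTD-tail") %in% names(cfg)))
})
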