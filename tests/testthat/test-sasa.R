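test_that("single spheres match the closed-form area for every element", {
  radii <- defaultVdwRadii()
  for (el in names(radii)) {
    m <- cloudModel(matrix(c(0, 0, 0), 1), elements = el)
    res <- shrakeRupley(m, nPoints = 96L, radii = radii,
                        excludeHydrogens = FALSE)
    analytic <- 4 * pi * (radii[[el]] + 1.4)^2
    ## an unoccluded sphere keeps every test point: exact, well inside the
    ## 1/nPoints quadrature resolution
    expect_equal(atomAreas(res)$area, analytic,
                 tolerance = 1 / 96, info = el)
  }
})

test_that("distant atoms are additive and a caged atom scores zero", {
  ## two identical atoms 100 A apart: no occlusion
  m2 <- cloudModel(rbind(c(0, 0, 0), c(100, 0, 0)), elements = "C")
  res2 <- shrakeRupley(m2, nPoints = 960L)
  single <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(atomAreas(res2)$area, rep(single, 2), tolerance = 1e-12)

  ## a nitrogen at the centre of a tight octahedral carbon cage
  cage <- rbind(c(0, 0, 0),
                2.0 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  m3 <- cloudModel(cage, elements = c("N", rep("C", 6)))
  res3 <- shrakeRupley(m3, nPoints = 960L)
  expect_equal(atomAreas(res3)$area[1], 0)
})

test_that("per-residue areas are exact sums and totals agree", {
  m <- makeHelix("ARNDCQEGHILKMFPSTWYV")
  res <- shrakeRupley(m, nPoints = 240L)
  at <- atomAreas(res); rt <- residueAreas(res)
  expect_true(all(at$area >= 0))
  sums <- tapply(at$area, at$resno, sum)
  expect_equal(rt$area, as.numeric(sums[as.character(rt$resno)]))
  expect_equal(sum(rt$area), sum(at$area))
})

test_that("occlusion is monotone: adding an atom never raises others' area", {
  set.seed(3)
  base <- matrix(runif(30, 0, 8), ncol = 3)
  m1 <- cloudModel(base, elements = "C")
  a1 <- atomAreas(shrakeRupley(m1, nPoints = 240L))$area
  withExtra <- rbind(base, c(4, 4, 4))
  m2 <- cloudModel(withExtra, elements = "C")
  a2 <- atomAreas(shrakeRupley(m2, nPoints = 240L))$area
  expect_true(all(a2[1:10] <= a1 + 1e-12))
})

test_that("relative accessibility normalises, flags unknowns, classifies", {
  m <- makeHelix("GGGGG")
  res <- relativeSasa(shrakeRupley(m, nPoints = 960L))
  rt <- residueAreas(res)
  ## terminal glycine of an extended stretch is close to its table maximum
  expect_gt(rt$relative[1], 60)
  expect_true(all(rt$relative >= 0))

  ## area equal to the maximum -> 100; zero -> 0
  fake <- res
  fake@residueTable$area <- defaultMaxAcc()[["G"]]
  expect_equal(residueAreas(relativeSasa(fake))$relative, rep(100, 5))
  fake@residueTable$area <- 0
  expect_equal(residueAreas(relativeSasa(fake))$relative, rep(0, 5))

  ## unknown residue type: NA marker, never silent zero
  unk <- res
  unk@residueTable$resid[2] <- "XYZ"
  rtu <- residueAreas(relativeSasa(unk))
  expect_true(is.na(rtu$relative[2]))
  expect_equal(attr(rtu, "flaggedResidues"), "XYZ")
})

test_that("burial classification follows the 25/80 thresholds", {
  expect_equal(classifyBurial(10), "core")
  expect_equal(classifyBurial(50), "noninterface")
  expect_equal(classifyBurial(90), "exposed")
  expect_equal(classifyBurial(c(24.999, 25, 80, 80.001)),
               c("core", "noninterface", "noninterface", "exposed"))
  expect_equal(classifyBurial(NA_real_), "unscored")
  expect_error(classifyBurial(-1), "negative")
})

test_that("per-residue areas agree with an independent implementation", {
  ## cross-validation against biotite's Shrake-Rupley (python), same
  ## element radii set (Bondi/Mantina "Single"), probe 1.4
  m <- makeHelix("ARNDCQEGHILKMFPSTWYVKLMNPQRSTV", structureId = "xval")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePdb(m, pdb)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "import biotite.structure as struc",
    "import biotite.structure.io.pdb as pdbio",
    "arr = pdbio.PDBFile.read(sys.argv[1]).get_structure(model=1)",
    "sasa = struc.sasa(arr, probe_radius=1.4, point_number=1000,",
    "                  vdw_radii='Single')",
    "res = struc.apply_residue_wise(arr, sasa, np.nansum)",
    "ids = struc.get_residues(arr)[0]",
    "with open(sys.argv[2], 'w') as fh:",
    "    for i, a in zip(ids, res):",
    "        fh.write(f'{i}\\t{a}\\n')"), script)
  status <- system2("python", c(script, pdb, out))
  expect_equal(status, 0L)
  ext <- utils::read.delim(out, header = FALSE,
                           col.names = c("resno", "area"))

  res <- residueAreas(shrakeRupley(m, nPoints = 960L))
  merged <- merge(res, ext, by = "resno", suffixes = c("", ".ext"))
  expect_equal(nrow(merged), 30L)
  relErr <- abs(merged$area - merged$area.ext) / merged$area.ext
  expect_lt(max(relErr), 0.05)
})
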