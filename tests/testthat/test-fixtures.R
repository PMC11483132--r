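test_that("helix geometry is ideal", {
  m <- makeHelix("AAAAAAAAAA")
  a <- atomRecords(m)
  ca <- as.matrix(a[a$elety == "CA", c("x", "y", "z")])
  d1 <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  expect_true(all(abs(d1 - 3.83) < 0.05))          # consecutive C-alpha
  d3 <- sqrt(rowSums((ca[-(1:3), ] - ca[1:7, ])^2))
  expect_true(all(d3 > 5 & d3 < 6))                # i, i+3 helical range

  expect_equal(residueRecords(makeHelix("AAA", startResno = 101L))$resno,
               101:103)
  expect_error(makeHelix("AXB"), "invalid")
})

test_that("planted context anchors are realised at the requested distance", {
  ref <- paste(rep("LKMFPSTWYV", 6), collapse = "")
  cx <- makeComplex(ref,
                    chains = list(list(chainId = "A", span = c(1, 60)),
                                  list(chainId = "B", span = c(1, 60))),
                    dimerDistance = 4.5,
                    zinc = list(anchorChain = "A", anchorPos = 31L,
                                distance = 4.8))
  t <- cx$contexts
  expect_true(t$zinc_site[t$chain == "A" & t$uniprotPos == 31])
  expect_equal(min(t$zinc_min_dist, na.rm = TRUE), 4.8, tolerance = 1e-6)
  expect_equal(min(t$dimer_min_dist, na.rm = TRUE), 4.5, tolerance = 1e-6)

  ## conflicting distances are a generation error: a zinc planted farther
  ## away than the flagging cutoff can never flag its anchor
  refW <- paste(rep("W", 40), collapse = "")
  expect_error(
    makeComplex(refW, chains = list(list(chainId = "A", span = c(1, 40))),
                zinc = list(anchorChain = "A", anchorPos = 20L,
                            distance = 5.5)),
    "unrealisable")
})

test_that("generation is a pure function of the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- caseStudyFixture(d1, seed = 3)
  fx2 <- caseStudyFixture(d2, seed = 3)
  for (f in c("complexPdb", "predictedPdb", "referenceFasta",
              "mutationTable"))
    expect_identical(readLines(fx1[[f]]), readLines(fx2[[f]]),
                     info = f)
  expect_identical(fx1$expectedRecords, fx2$expectedRecords)
  expect_identical(fx1$contexts, fx2$contexts)
})

test_that("randomized complexes verify against brute-force internally", {
  aas <- strsplit("LKMFPSTWYV", "")[[1]]
  set.seed(55)
  ## anchor side chains must face away from the partner chain (which sits
  ## along +x): keep helix angles in the 90..270 degree sector
  angleOf <- function(p) ((p - 1) * 100) %% 360
  anchors <- Filter(function(p) angleOf(p) > 90 && angleOf(p) < 270, 10:40)
  for (i in 1:8) {
    ref <- paste(sample(aas, 50, TRUE), collapse = "")
    cx <- makeComplex(ref,
                      chains = list(list(chainId = "A", span = c(1, 50)),
                                    list(chainId = "B", span = c(1, 50))),
                      dimerDistance = runif(1, 3.8, 4.9),
                      dna = list(nBp = 4L, anchorChain = "A",
                                 anchorPos = sample(anchors, 1),
                                 distance = runif(1, 3.5, 4.8)))
    ## the shipped ground truth must agree with an oracle recomputation
    a <- atomRecords(cx$model)
    prot <- which(a$category == "protein")
    nuc <- which(a$category == "nucleic")
    nb <- neighborsAsKeys(findNeighbors(cx$model, prot, nuc, 5.0))
    flagged <- sort(unique(nb$source))
    t <- cx$contexts
    truthKeys <- sort(paste(t$chain, t$resno, t$insert,
                            sep = "|")[t$dna_interface])
    expect_equal(flagged, truthKeys, info = paste("seed iter", i))
  }
})

test_that("mutation-table fixtures mirror the hotspot example", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mt <- makeMutationTable(c(R248Q = 3L, G245S = 1L), path)
  lines <- readLines(path)
  expect_equal(length(lines), 5L)                  # header + 4 rows
  expect_equal(sort(mt$expected$count), c(1L, 3L))
  expect_equal(sum(mt$expected$frequency), 1.0)
})

test_that("the case-study fixture ships coherent ground truth", {
  fx <- caseStudyFixture(withr::local_tempdir(), seed = 2)
  expect_equal(nrow(fx$expectedRecords), 20L)
  expect_equal(sum(fx$expectedRecords$frequency), 1, tolerance = 1e-12)
  expect_true(all(c("R248Q", "R248W", "R273H", "R273C", "R282W", "G245S")
                  %in% formatProteinChange(fx$expectedRecords$ref_aa,
                                           fx$expectedRecords$position,
                                           fx$expectedRecords$alt_aa)))
  ## planted context positions are flagged in the shipped truth
  t <- fx$contexts
  for (ctxName in names(fx$plantedContexts)) {
    for (p in fx$plantedContexts[[ctxName]]) {
      expect_true(any(t[[ctxName]][t$chain == "A" & t$uniprotPos == p]),
                  info = paste(ctxName, p))
    }
  }
  ## disorder pattern: 100 of 300 positions
  expect_equal(length(fx$disorderPositions), 100L)
  ## reference letters agree with the hotspot notations
  letters1 <- strsplit(fx$reference, "")[[1]]
  expect_equal(letters1[c(245, 248, 273, 282)], c("G", "R", "R", "R"))
})
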