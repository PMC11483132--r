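test_that("neighbor search respects the cutoff boundary", {
  m <- cloudModel(rbind(c(0, 0, 0), c(4.9, 0, 0)), elements = "C")
  a <- atomRecords(m)
  nb <- findNeighbors(m, 1L, 2L, cutoff = 5.0)
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$minDist, 4.9)

  m2 <- cloudModel(rbind(c(0, 0, 0), c(5.1, 0, 0)), elements = "C")
  expect_equal(nrow(findNeighbors(m2, 1L, 2L, cutoff = 5.0)), 0L)
})

test_that("grid neighbor search equals brute force on random clouds", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    coords <- matrix(runif(n * 3, 0, 40), ncol = 3)
    m <- cloudModel(coords, elements = "C")
    for (cutoff in c(5.0, 6.0)) {
      nb <- neighborsAsKeys(findNeighbors(m, seq_len(n), seq_len(n),
                                          cutoff))
      br <- bruteNeighborPairs(m, seq_len(n), seq_len(n), cutoff)
      expect_equal(nb$source, br$source)
      expect_equal(nb$target, br$target)
      expect_equal(nb$minDist, br$minDist, tolerance = 1e-12)
    }
  }
})

test_that("cutoff monotonicity: smaller cutoff yields a subset", {
  set.seed(23)
  coords <- matrix(runif(300, 0, 30), ncol = 3)
  m <- cloudModel(coords, elements = "C")
  idx <- seq_len(nrow(coords))
  small <- neighborsAsKeys(findNeighbors(m, idx, idx, 4.0))
  large <- neighborsAsKeys(findNeighbors(m, idx, idx, 6.0))
  expect_true(all(paste(small$source, small$target) %in%
                    paste(large$source, large$target)))
})

makeContextFixture <- function(seed) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- paste(withr::with_seed(seed, sample(aas, 60, TRUE)), collapse = "")
  ## anchors need side-chain stubs
  substr(ref, 20, 20) <- "L"
  substr(ref, 40, 40) <- "C"
  substr(ref, 50, 50) <- "K"
  makeComplex(ref,
              chains = list(list(chainId = "A", span = c(1, 60)),
                            list(chainId = "B", span = c(1, 60))),
              dimerDistance = 4.5,
              dna = list(nBp = 5L, anchorChain = "A", anchorPos = 20L,
                         distance = 4.0),
              zinc = list(anchorChain = "A", anchorPos = 40L,
                          distance = 4.6),
              ligand = list(anchorChain = "A", anchorPos = 50L,
                            distance = 4.0))
}

test_that("annotators equal the exhaustive ground truth on fixtures", {
  for (seed in c(1, 2, 3)) {
    cx <- makeContextFixture(seed)
    truth <- cx$contexts
    ctx <- annotateContexts(cx$model)
    expect_equal(ctx$ligand_site, truth$ligand_site)
    expect_equal(ctx$ligand_ids, truth$ligand_ids)
    expect_equal(ctx$dimer_interface, truth$dimer_interface)
    expect_equal(ctx$partner_chains, truth$partner_chains)
    expect_equal(ctx$dna_interface, truth$dna_interface)
    expect_equal(ctx$zinc_site, truth$zinc_site)
    ## min distances agree where flagged
    expect_equal(ctx$ligand_site_min_dist[ctx$ligand_site],
                 truth$ligand_min_dist[truth$ligand_site],
                 tolerance = 1e-9)
    expect_equal(ctx$dimer_interface_min_dist[ctx$dimer_interface],
                 truth$dimer_min_dist[truth$dimer_interface],
                 tolerance = 1e-9)
  }
})

test_that("structures without partners yield no flags", {
  m <- makeHelix("ARNDCQEGHILKMFPSTWYV")
  ctx <- annotateContexts(m)
  expect_false(any(ctx$ligand_site))
  expect_false(any(ctx$dimer_interface))
  expect_false(any(ctx$dna_interface))
  expect_false(any(ctx$zinc_site))
})

test_that("ligands far from the protein flag nothing", {
  m <- makeHelix("ARNDCQEGHILKMFPSTWYV")
  a <- atomRecords(m)
  lig <- a[1, ]
  lig$chain <- "L"; lig$resno <- 1L; lig$resid <- "LIG"
  lig$category <- "ligand"; lig$elety <- "C1"; lig$elesy <- "C"
  lig$x <- 500; lig$y <- 500; lig$z <- 500
  m2 <- new("StructureModel", structureId = "far", source = "experimental",
            modelNumber = 1L, atoms = rbind(a, lig))
  expect_false(any(annotateLigandSites(m2)$ligand_site))
})

test_that("dimer flags are symmetric at the chain-pair level", {
  cx <- makeContextFixture(4)
  ctx <- annotateDimerInterface(cx$model)
  flaggedA <- ctx$dimer_interface[ctx$chain == "A"]
  flaggedB <- ctx$dimer_interface[ctx$chain == "B"]
  expect_true(any(flaggedA) && any(flaggedB))
})

test_that("waters and excluded ions never count as ligands", {
  m <- makeHelix("ARNDCQEGHILKMFPSTWYV")
  a <- atomRecords(m)
  near <- a[a$resno == 10 & a$elety == "CB", ]
  water <- near; water$chain <- "W"; water$resno <- 1L
  water$resid <- "HOH"; water$category <- "water"
  water$elety <- "O"; water$elesy <- "O"; water$x <- water$x + 3
  ion <- near; ion$chain <- "I"; ion$resno <- 1L
  ion$resid <- "MG"; ion$category <- "metal"
  ion$elety <- "MG"; ion$elesy <- "MG"; ion$x <- ion$x + 3.5
  m2 <- new("StructureModel", structureId = "wi", source = "experimental",
            modelNumber = 1L, atoms = rbind(a, water, ion))
  expect_false(any(annotateLigandSites(m2)$ligand_site))
  expect_false(any(annotateZincSites(m2)$zinc_site))  # MG is not ZN
})
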