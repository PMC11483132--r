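test_that("identity and free-end-gap alignments behave as expected", {
  al <- globalAlign("ACDE", "ACDE")
  expect_equal(al@alignedQuery, "ACDE")
  expect_equal(al@alignedReference, "ACDE")
  expect_equal(al@identityFraction, 1.0)

  al2 <- globalAlign("CDE", "ACDEF")
  expect_equal(al2@alignedQuery, "-CDE-")
  expect_equal(al2@alignedReference, "ACDEF")
  expect_equal(al2@identityFraction, 1.0)

  ## one substitution in a 30-mer
  set.seed(11)
  q <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I"), 30, TRUE),
             collapse = "")
  qq <- q
  substr(qq, 15, 15) <- if (substr(q, 15, 15) == "A") "C" else "A"
  al3 <- globalAlign(qq, q)
  expect_equal(al3@identityFraction, 29 / 30)

  expect_error(globalAlign("", "ACDE"), "non-empty")
})

test_that("alignment score equals the exhaustive enumeration oracle", {
  set.seed(42)
  alphabet <- c("A", "C", "D", "E")
  for (i in 1:12) {
    nq <- sample(1:5, 1)
    nr <- sample(2:8, 1)
    q <- paste(sample(alphabet, nq, TRUE), collapse = "")
    r <- paste(sample(alphabet, nr, TRUE), collapse = "")
    expect_equal(globalAlign(q, r)@score, bruteAlignScore(q, r),
                 info = paste(q, "vs", r))
  }
})

test_that("gapped strings recover the inputs exactly", {
  set.seed(5)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:10) {
    q <- paste(sample(aas, sample(4:20, 1), TRUE), collapse = "")
    r <- paste(sample(aas, sample(10:40, 1), TRUE), collapse = "")
    al <- globalAlign(q, r)
    expect_equal(nchar(al@alignedQuery), nchar(al@alignedReference))
    expect_equal(gsub("-", "", al@alignedQuery), q)
    expect_equal(gsub("-", "", al@alignedReference), r)
  }
})

test_that("residue maps recover offsets, deletions and stay injective", {
  set.seed(21)
  ref <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                      60, TRUE), collapse = "")

  ## offset numbering
  m <- makeHelix(substr(ref, 1, 10), startResno = 101L)
  rm1 <- buildResidueMap(m, "A", ref)
  e <- mapEntries(rm1)
  expect_equal(e$resno, 101:110)
  expect_equal(e$uniprotPos, 1:10)
  expect_false(anyDuplicated(e$uniprotPos) > 0)

  ## deleted segment: reference positions 5..9 absent from the image
  cx <- makeComplex(ref, chains = list(list(chainId = "A", span = c(1, 30),
                                            deleted = 5:9)))
  rm2 <- buildResidueMap(cx$model, "A", ref)
  e2 <- mapEntries(rm2)
  expect_equal(nrow(e2), 25L)                      # nothing observed omitted
  expect_setequal(e2$uniprotPos, setdiff(1:30, 5:9))

  ## low identity is an error
  other <- paste(rep("W", 40), collapse = "")
  mo <- makeHelix(other)
  expect_error(buildResidueMap(mo, "A", paste(rep("D", 40), collapse = "")),
               "does not match reference")
})

test_that("insertion-code residues absent from the reference get no entry", {
  m <- makeHelix("ACDEFGHIKL", startResno = 51L)
  a <- atomRecords(m)
  ## plant an extra residue (55, 'A') between 55 and 56: an insertion
  ins <- a[a$resno == 55L, ]
  ins$insert <- "A"
  ins$resid <- "TRP"
  ins[, c("x", "y", "z")] <- ins[, c("x", "y", "z")] + 2.0
  a2 <- rbind(a[a$resno <= 55L, ], ins, a[a$resno > 55L, ])
  rownames(a2) <- NULL
  m2 <- new("StructureModel", structureId = "ins", source = "experimental",
            modelNumber = 1L, atoms = a2)
  ref <- "ACDEFGHIKL"
  rmap <- buildResidueMap(m2, "A", ref)
  e <- mapEntries(rmap)
  expect_equal(nrow(e), 10L)                       # insertion unmapped
  expect_false(any(e$insert == "A"))
  expect_equal(e$uniprotPos, 1:10)
})

test_that("mismatched aligned pairs are mapped and counted", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  mutSeq <- ref
  substr(mutSeq, 8, 8) <- "A"                      # engineered substitution
  m <- makeHelix(mutSeq)
  rmap <- buildResidueMap(m, "A", ref)
  expect_equal(rmap@nMismatches, 1L)
  e <- mapEntries(rmap)
  expect_true(8 %in% e$uniprotPos)                 # still mapped
  expect_true(e$mismatch[e$uniprotPos == 8])
  expect_equal(rmap@identityFraction, 19 / 20)
})

test_that("renumbering recovery is exact on randomized corrupted fixtures", {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(99)
  for (i in 1:25) {
    ref <- paste(sample(aas, 100, TRUE), collapse = "")
    offset <- sample(-50:400, 1)
    delStart <- sample(20:60, 1)
    deleted <- delStart:(delStart + sample(3:10, 1))
    ## distinct letters at the deletion edges keep the planted gap
    ## placement the unique alignment optimum
    L <- strsplit(ref, "")[[1]]
    L[max(deleted)] <- setdiff(aas, L[min(deleted) - 1])[1]
    L[min(deleted)] <- setdiff(aas, L[max(deleted) + 1])[1]
    ref <- paste(L, collapse = "")
    span <- c(sample(1:10, 1), sample(80:100, 1))
    cx <- makeComplex(ref, chains = list(list(
      chainId = "A", span = span, offset = offset, deleted = deleted)))
    ## a few substitutions (< 15%) on top; kept away from deletion edges
    ## and chain termini, where a substituted residue makes the planted
    ## gap placement non-unique
    a <- atomRecords(cx$model)
    rr <- residueRecords(cx$model)
    nearEdge <- c(outer(-3:3, c(min(deleted), max(deleted),
                                span[1], span[2]), "+")) + offset
    candidates <- setdiff(rr$resno, nearEdge)
    subPos <- sample(candidates, 5)
    for (p in subPos) {
      old <- a$resid[a$resno == p][1]
      new3 <- setdiff(c("TRP", "GLY", "PRO"), old)[1]
      a$resid[a$resno == p & a$elety %in% c("N", "CA", "C", "O")] <- new3
      a <- a[!(a$resno == p & !a$elety %in% c("N", "CA", "C", "O")), ]
    }
    m <- new("StructureModel", structureId = "corr",
             source = "experimental", modelNumber = 1L, atoms = a)
    rmap <- buildResidueMap(m, "A", ref)
    e <- mapEntries(rmap)
    truth <- cx$numbering$A
    expect_equal(nrow(e), nrow(truth))
    expect_equal(e$uniprotPos[match(truth$resno, e$resno)],
                 truth$uniprotPos, info = paste("fixture", i))
    expect_false(anyDuplicated(e$uniprotPos) > 0)
  }
})

test_that("renumberStructure rewrites mapped residues only", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  cx <- makeComplex(ref,
                    chains = list(list(chainId = "A", span = c(3, 18),
                                       offset = 200L)),
                    zinc = list(anchorChain = "A", anchorPos = 10L,
                                distance = 4.5))
  rmap <- buildResidueMap(cx$model, "A", ref)
  renum <- renumberStructure(cx$model, list(rmap))
  rr <- residueRecords(renum)
  expect_equal(sort(rr$resno[rr$category == "protein"]), 3:18)
  expect_equal(rr$resno[rr$resid == "ZN"], 1L)     # untouched

  ## identity numbering: output equals input
  m0 <- makeHelix(ref)
  rmap0 <- buildResidueMap(m0, "A", ref)
  expect_equal(atomRecords(renumberStructure(m0, list(rmap0))),
               atomRecords(m0))

  ## homodimer with two different offsets, both recovered
  cx2 <- makeComplex(ref,
                     chains = list(
                       list(chainId = "A", span = c(1, 20), offset = 30L),
                       list(chainId = "B", span = c(1, 20), offset = -0L)))
  maps <- list(buildResidueMap(cx2$model, "A", ref),
               buildResidueMap(cx2$model, "B", ref))
  renum2 <- renumberStructure(cx2$model, maps)
  rr2 <- residueRecords(renum2)
  expect_equal(sort(unique(rr2$resno[rr2$chain == "A"])), 1:20)
  expect_equal(sort(unique(rr2$resno[rr2$chain == "B"])), 1:20)
})

test_that("reference FASTA reading honours the accession flag", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 first", "ACDEF", ">P2 second", "GHIKL"), path)
  expect_error(readReferenceFasta(path), "multi-record")
  expect_equal(readReferenceFasta(path, "P2")$sequence, "GHIKL")
  path1 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only", "MMMM"), path1)
  expect_equal(readReferenceFasta(path1)$sequence, "MMMM")
})
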