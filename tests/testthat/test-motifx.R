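# Window extraction and iterative motif enrichment.

test_that("windows are extracted with terminal padding", {
  prot <- c(P1 = "MKRSST", P2 = "SAAAAAA")
  expect_identical(extractWindow(prot, "P1", 4), "---MKRSST----")
  expect_identical(extractWindow(prot, "P2", 1), "------SAAAAAA")
  prot2 <- c(P3 = paste(rep("A", 20), collapse = ""))
  w <- extractWindow(prot2, "P3", 10)
  expect_identical(w, strrep("A", 13))
  expect_false(grepl("-", w))
  expect_error(extractWindow(prot, "P1", 7), "out of range")
  expect_error(extractWindow(prot, "P9", 1), "unknown protein")
})

test_that("background windows cover every central-residue occurrence", {
  prot <- c(P1 = "ASA")
  bw <- backgroundWindows(prot, "S", 13)
  expect_length(bw, 1)
  expect_identical(substr(bw, 7, 7), "S")
  prot2 <- c(P1 = "SSSSSSS", P2 = "TTT")   # 7 S and 3 T
  expect_length(backgroundWindows(prot2, c("S", "T"), 13), 10)
  expect_length(backgroundWindows(prot2, "Y", 13), 0)
})

test_that("binomial tail matches direct summation", {
  expect_equal(binomialTail(2, 3, 0.5), 0.5)   # 4 of 8 outcomes
  expect_equal(binomialTail(0, 10, 0.3), 1.0)
  expect_equal(binomialTail(5, 5, 1.0), 1.0)
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    k <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(binomialTail(k, n, p), binomTailOracle(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(binomialTail(4, 3, 0.5), "k <= n")
  expect_error(binomialTail(1, 3, 1.5), "p0")
})

test_that("a planted enriched position is fixed and claims its windows", {
  set.seed(301)
  bg <- uniformWindows(2000, "S")
  fg <- uniformWindows(30, "S")
  ## plant R at position -3 in 25 of 30 foreground windows
  substr(fg[1:25], 4, 4) <- "R"
  part <- motifxPartition(fg, paste0("w", 1:30), bg, motifParams())
  expect_length(part$motifs, 1)
  m <- part$motifs[[1]]
  expect_identical(m$fixed$pos, -3L)
  expect_identical(m$fixed$residue, "R")
  expect_setequal(m$ids, paste0("w", which(substr(fg, 4, 4) == "R")))
  expect_true(binomialTail(25, 30, mean(substr(bg, 4, 4) == "R")) < 1e-6)
})

test_that("small foregrounds yield no motifs and all windows unassigned", {
  set.seed(302)
  bg <- uniformWindows(500, "S")
  fg <- uniformWindows(5, "S")
  substr(fg, 4, 4) <- "R"
  part <- motifxPartition(fg, paste0("w", 1:5), bg, motifParams())
  expect_length(part$motifs, 0)
  expect_setequal(part$unassigned, paste0("w", 1:5))
  expect_error(motifxPartition(fg, paste0("w", 1:5), character(0)),
               "background")
})

test_that("module membership is disjoint and satisfies both thresholds", {
  set.seed(303)
  bg <- uniformWindows(2000, "S")
  fg <- c(uniformWindows(40, "S"), uniformWindows(40, "S"))
  substr(fg[1:35], 4, 4) <- "R"        # motif 1: R at -3
  substr(fg[41:75], 10, 10) <- "P"     # motif 2: P at +3
  ids <- paste0("w", seq_along(fg))
  part <- motifxPartition(fg, ids, bg, motifParams())
  expect_gte(length(part$motifs), 2)
  claimed <- unlist(lapply(part$motifs, `[[`, "ids"))
  expect_identical(anyDuplicated(claimed), 0L)
  expect_setequal(c(claimed, part$unassigned), ids)
  for (m in part$motifs) {
    expect_gte(length(m$ids), 10)
    expect_gte(nrow(m$fixed), 1)
    ## every member matches every fixed position
    for (i in seq_len(nrow(m$fixed))) {
      col <- m$fixed$pos[i] + 7
      expect_true(all(substr(m$windows, col, col) == m$fixed$residue[i]))
    }
  }
})

test_that("pad characters never count toward enrichment", {
  set.seed(304)
  bg <- uniformWindows(1000, "S")
  ## foreground padded at positions -6..-4 (N-terminal sites) with R at -3
  fg <- uniformWindows(30, "S")
  substr(fg, 1, 3) <- "---"
  substr(fg[1:28], 4, 4) <- "R"
  part <- motifxPartition(fg, paste0("w", 1:30), bg, motifParams())
  expect_length(part$motifs, 1)
  expect_identical(part$motifs[[1]]$fixed$pos, -3L)
  ## '-' itself must never be a fixed residue
  expect_false(any(part$motifs[[1]]$fixed$residue == "-"))
})

test_that("S and T foregrounds are processed separately", {
  set.seed(305)
  bg <- c(uniformWindows(1000, "S"), uniformWindows(1000, "T"))
  fgS <- uniformWindows(20, "S")
  substr(fgS, 4, 4) <- "R"
  fgT <- uniformWindows(20, "T")
  substr(fgT, 10, 10) <- "L"
  part <- motifxPartition(c(fgS, fgT), paste0("w", 1:40), bg, motifParams())
  centrals <- vapply(part$motifs, `[[`, character(1), "central")
  expect_setequal(centrals, c("S", "T"))
  for (m in part$motifs) {
    if (m$central == "S") expect_identical(m$fixed$residue, "R")
    if (m$central == "T") expect_identical(m$fixed$residue, "L")
  }
})

test_that("foregrounds drawn from the background yield no motifs", {
  ## Monte-Carlo under the null at significance 1e-6
  set.seed(306)
  bg <- uniformWindows(3000, "S")
  n_with_motif <- 0
  for (i in 1:40) {
    fg <- bg[sample(length(bg), 30)]
    part <- motifxPartition(fg, as.character(1:30), bg, motifParams())
    if (length(part$motifs) > 0) n_with_motif <- n_with_motif + 1
  }
  expect_lte(n_with_motif / 40, 0.05)
})

test_that("modules built per class carry class, motif and members", {
  s <- smallScenario(seed = 21, noiseSd = 0)
  cls <- classifyPeptides(s$peptides,
                          classificationParams(strainOrder = strainNames(s$peptides)))
  mods <- buildModules(s$peptides, cls, s$proteome, motifParams())
  expect_gte(length(mods), 2)
  for (m in mods) {
    expect_gte(length(memberPeptides(m)), 10)
    expect_match(motifString(m), "^[A-Z.]{6}[st][A-Z.]{6}$")
    ## members all share the module's class
    mem_cls <- cls$class[match(memberPeptides(m), cls$peptide_id)]
    expect_true(all(mem_cls == classLabel(m)))
  }
  ## within a class, no peptide sits in two modules
  for (cl in unique(vapply(mods, classLabel, character(1)))) {
    ids <- unlist(lapply(mods[vapply(mods, classLabel, character(1)) == cl],
                         memberPeptides))
    expect_identical(anyDuplicated(ids), 0L)
  }
})
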