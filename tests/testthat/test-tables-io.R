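# Readers, writers and round-trip fidelity for the pipeline's file formats.

writeToyPeptideFile <- function(path, rows) {
  header <- paste(c("peptide_id", "protein_id", "site_pos", "window",
                    "S1_rep1_log2fc", "S1_rep2_log2fc",
                    "S2_rep1_log2fc", "S2_rep2_log2fc"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
}

test_that("peptide tables parse, reject malformed windows, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeToyPeptideFile(path, c(
    "p1\tP1\t10\tAAAAAASAAAAAA\t0.1\t0.2\t0.3\t0.4",
    "p2\tP2\t5\tRRRKKKTDDDEEE\t-1\t-1.5\t2\t2.5",
    "p3\tP3\t3\tAAAAAA\t0\t0\t0\t0",          # short window: rejected
    "p4\tP4\t8\tAAAAAAGAAAAAA\t0\t0\t0\t0"))  # non-S/T/Y center: rejected
  expect_message(pp <- readPeptideTable(path, c("S1", "S2")), "2 row")
  expect_identical(peptideIds(pp), c("p1", "p2"))
  expect_identical(peptideInfo(pp)$central, c("S", "T"))
  expect_equal(unname(foldChanges(pp)["p2" == peptideIds(pp), "S2.2"]), 2.5)
  expect_equal(unname(strainMeans(pp)[1, ]), c(0.15, 0.35))

  out <- withr::local_tempfile(fileext = ".tsv")
  writePeptideTable(pp, out)
  pp2 <- readPeptideTable(out, c("S1", "S2"))
  expect_identical(peptideInfo(pp2), peptideInfo(pp))
  expect_equal(foldChanges(pp2), foldChanges(pp))
})

test_that("peptide table errors name the missing column and bad row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tprotein_id\twindow\tS1_rep1_log2fc",
               "p1\tP1\tAAAAAASAAAAAA\t0.5"), path)
  expect_error(readPeptideTable(path, "S1"), "site_pos")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeToyPeptideFile(path2, "p1\tP1\t1\tAAAAAASAAAAAA\t0.1\tbad\t0\t0")
  expect_error(readPeptideTable(path2, c("S1", "S2")), "row 1")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeToyPeptideFile(path3, character(0))
  expect_warning(pp <- readPeptideTable(path3, c("S1", "S2")), "no rows")
  expect_length(peptideIds(pp), 0)
})

test_that("network reading canonicalizes edges and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tdirected\tetype",
               "B\tA\t0\tppi",
               "A\tB\t0\tppi",      # same undirected pair, other order
               "A\tB\t1\tkinase_substrate",
               "C\tC\t0\tppi",      # self-loop
               "C\tD\t1\tppi"), path)
  expect_warning(net <- readNetwork(path), "self-loop")
  e <- networkEdges(net)
  expect_equal(nrow(e), 3)
  expect_setequal(networkNodes(net), c("A", "B", "C", "D"))
  ## the undirected pair collapsed to one record with sorted endpoints,
  ## the directed copy of the same pair is distinct
  undir <- e[!e$directed, ]
  expect_equal(nrow(undir), 1)
  expect_true(undir$source < undir$target)
  expect_true(any(e$directed & e$etype == "kinase_substrate"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tdirected\tetype", "A\tB\t0\tmystery"), bad)
  expect_error(readNetwork(bad), "etype")
})

test_that("network canonicalization is idempotent under re-writing", {
  s <- smallScenario()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(s$network, p1)
  n1 <- readNetwork(p1)
  writeNetwork(n1, p2)
  n2 <- readNetwork(p2)
  expect_identical(networkEdges(n1), networkEdges(n2))
  expect_identical(sort(networkNodes(n1)), sort(networkNodes(n2)))
})

test_that("kinase intensity libraries read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rows <- c("kinase\tposition\tresidue\tintensity",
            paste("KA", rep(c(-2, 1), each = 20), rep(aa, 2),
                  seq(0.5, 20, by = 0.5), sep = "\t"))
  writeLines(rows, path)
  lib <- readKinaseIntensities(path)
  m <- intensityMatrix(lib, "KA")
  expect_equal(dim(m), c(20, 2))
  expect_identical(colnames(m), c("-2", "1"))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeKinaseIntensities(lib, out)
  lib2 <- readKinaseIntensities(out)
  expect_equal(intensityMatrix(lib2, "KA"), m)

  writeLines(c(rows, "KA\t-2\tA\t3"), path)   # duplicate cell
  expect_error(readKinaseIntensities(path), "duplicate")
  writeLines(c(rows[1], sub("0.5$", "-1", rows[2]), rows[-(1:2)]), path)
  expect_error(readKinaseIntensities(path), "negative")
  writeLines(rows[-2], path)                  # missing residue A at -2
  expect_error(readKinaseIntensities(path), "missing residue")
})

test_that("proteome FASTA identifiers and case are normalized", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "mkrsst", ">P2", "AAAA"), path)
  prot <- readProteome(path)
  expect_identical(names(prot), c("P1", "P2"))
  expect_identical(unname(prot["P1"]), "MKRSST")
  writeLines(c(">P1", "AA", ">P1 again", "CC"), path)
  expect_error(readProteome(path), "duplicate")
})

test_that("SIF output is three tab-separated fields per edge, in order", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeSIF(data.frame(source = "Tpk2", relation = "regulates",
                      target = "M1"), path)
  expect_identical(readBin(path, "raw", 100), charToRaw("Tpk2\tregulates\tM1\n"))

  writeSIF(data.frame(source = character(0), relation = character(0),
                      target = character(0)), path)
  expect_identical(file.size(path), 0)

  edges <- data.frame(source = c("A", "B"), relation = "contains",
                      target = c("x", "y"))
  writeSIF(edges, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_true(all(lengths(strsplit(lines, "\t")) == 3))
  expect_identical(lines[1], "A\tcontains\tx")

  expect_error(writeSIF(data.frame(source = "A\tB", relation = "r",
                                   target = "C"), path), "tab")
  expect_error(writeSIF(data.frame(source = "A", relation = "two words",
                                   target = "C"), path), "whitespace")
})

test_that("result tables are deterministic and manifested", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- list(scores = data.frame(module_id = c("b", "a"),
                                  protein_id = c("P2", "P1"),
                                  p_value = c(0.123456789, 1e-9)))
  m1 <- writeResultTables(res, out1, config = list(x = 1), seed = 5)
  m2 <- writeResultTables(res, out2, config = list(x = 1), seed = 5)
  expect_identical(unname(tools::md5sum(file.path(out1, "scores.tsv"))),
                   unname(tools::md5sum(file.path(out2, "scores.tsv"))))
  expect_identical(m1$outputs, m2$outputs)
  tab <- read.delim(file.path(out1, "scores.tsv"))
  expect_identical(tab$module_id, c("a", "b"))     # sorted
  expect_true(file.exists(file.path(out1, "run_manifest.json")))

  m3 <- writeResultTables(list(empty = res$scores[0, ]), out1)
  tab0 <- read.delim(file.path(out1, "empty.tsv"))
  expect_equal(nrow(tab0), 0)
  expect_identical(names(tab0), names(res$scores))
})

test_that("scenario files written by the generator round-trip", {
  s <- smallScenario()
  dir <- withr::local_tempdir()
  writeScenario(s, dir)
  pp <- readPeptideTable(file.path(dir, "peptides.tsv"),
                         strainNames(s$peptides))
  expect_identical(peptideInfo(pp), peptideInfo(s$peptides))
  expect_equal(foldChanges(pp), foldChanges(s$peptides))
  net <- readNetwork(file.path(dir, "network.tsv"))
  expect_identical(networkEdges(net), networkEdges(s$network))
  lib <- readKinaseIntensities(file.path(dir, "kinase_intensities.tsv"))
  expect_equal(intensityMatrix(lib, "KIN01"),
               intensityMatrix(s$kinaseLibrary, "KIN01"))
  prot <- readProteome(file.path(dir, "proteome.fasta"))
  expect_identical(sort(names(prot)), sort(names(s$proteome)))
  expect_identical(unname(prot[names(s$proteome)]), unname(s$proteome))
})
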