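test_that("multi-model PDB write/read round-trips topology and coordinates", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 10, seed = 4,
                                           regime = "flexible"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(gen$ensemble, f)
  back <- readEnsemble(f)
  expect_equal(nModels(back), 10)
  # PDB MODEL records are integers, so ids map to their model numbers
  expect_equal(modelIds(back), as.character(1:10))
  expect_identical(atomTable(back)[, c("name", "resName", "resId", "chain")],
                   atomTable(gen$ensemble)[, c("name", "resName", "resId",
                                               "chain")])
  expect_lt(max(abs(coords(back) - coords(gen$ensemble))), 1e-3 + 1e-12)

  # exactly one MODEL/ENDMDL pair per conformer, END terminator
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), 10)
  expect_equal(sum(grepl("^ENDMDL", lines)), 10)
  expect_equal(lines[length(lines)], "END")
})

test_that("read agrees with an independent PDB parser", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 3, seed = 9,
                                           regime = "static"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(gen$ensemble, f)
  ours <- readEnsemble(f)
  ref <- bio3d::read.pdb(f, multi = TRUE)
  refXyz <- ref$xyz[1, ]
  expect_equal(as.numeric(t(coords(ours, 1))), as.numeric(refXyz),
               tolerance = 1e-9)
  expect_equal(atomTable(ours)$name, ref$atom$elety)
  expect_equal(atomTable(ours)$resId, ref$atom$resno)
})

test_that("a file without MODEL records is a one-model ensemble", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(gen$ensemble, f)
  lines <- readLines(f)
  atomOnly <- lines[grepl("^ATOM", lines)]
  n <- length(atomOnly) / 2
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(atomOnly[seq_len(n)], "END"), f2)
  one <- readEnsemble(f2)
  expect_equal(nModels(one), 1)
  expect_equal(modelIds(one), "1")
})

test_that("malformed records and inconsistent topology are hard errors", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 2, seed = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(gen$ensemble, f)
  lines <- readLines(f)

  # corrupt an x coordinate -> format error naming the line
  badLine <- grep("^ATOM", lines)[3]
  bad <- lines
  substr(bad[badLine], 31, 38) <- "  xx.xxx"
  fBad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, fBad)
  expect_error(readEnsemble(fBad), sprintf("line %d", badLine))

  # drop one atom from model 2 -> topology error
  atomIdx <- grep("^ATOM", lines)
  dropIdx <- atomIdx[atomIdx > grep("^MODEL", lines)[2]][5]
  fTopo <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-dropIdx], fTopo)
  expect_error(readEnsemble(fTopo), "topology error")

  # empty ensembles cannot even be constructed; missing files are refused
  expect_error(ConformerEnsemble(atomTable(gen$ensemble),
    array(0, c(nrow(atomTable(gen$ensemble)), 3, 0))), "at least one model")
  expect_error(readEnsemble(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("oversized coordinates are refused by the writer", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 2, seed = 3))
  ens <- gen$ensemble
  ens@coords[1, 1, 1] <- 12345.0
  expect_error(writeEnsemble(ens, withr::local_tempfile(fileext = ".pdb")),
               "8.3f")
})

test_that("score tables parse case-insensitively and strictly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("model_id\tDOPE\tsoap", "m1\t-100\t-5", "m2\t-120\t-6",
               "m3\t-90\t-4"), f)
  sc <- readScores(f)
  expect_equal(sc$model_id, c("m1", "m2", "m3"))
  expect_equal(sc$dope, c(-100, -120, -90))

  writeLines(c("model_id\tdope", "m1\t-1"), f)
  expect_error(readScores(f), "missing column.*soap")

  writeLines(c("model_id\tdope\tsoap", "m1\t-1\t-2", "m2\t-3\t-4",
               "m3\t-5\t-6", "m4\tabc\t-1.0"), f)
  expect_error(readScores(f), "row 4")
})

test_that("loop resolution follows the strict-between-anchors convention", {
  resIds <- c(300, 317:327)  # reference + anchors 318/326 region
  n <- length(resIds)
  xyz <- cbind(3.8 * seq_len(n), 0, 0)
  xyz[2:n, 2] <- c(0, 1, 2, 3, 4, 3, 2, 1, 0, 0, 0)  # gentle arch
  ens <- caTraceEnsemble(resIds, list(xyz))

  spec <- LoopSpec(chain = "A", anchorStart = 318, anchorEnd = 326,
                   referenceResIds = 300)
  sel <- resolveLoop(spec, ens)
  expect_equal(sel@loopResIds, 319:325)   # 7 residues strictly between
  expect_equal(nrow(sel@loopCa), 7)

  specIn <- LoopSpec(chain = "A", anchorStart = 318, anchorEnd = 326,
                     referenceResIds = 300, includeAnchors = TRUE)
  selIn <- resolveLoop(specIn, ens)
  expect_equal(length(selIn@loopResIds), 9)  # anchors counted in

  # reference centroid of a single residue is its CA
  expect_equal(sel@referenceCentroid, xyz[1, ])

  # protein heavy excludes loop AND anchors
  expect_equal(nrow(sel@proteinHeavy), n - 9)

  # missing residue in the loop range is named
  gap <- caTraceEnsemble(setdiff(resIds, 321),
                         list(xyz[resIds != 321, , drop = FALSE]))
  expect_error(resolveLoop(spec, gap), "321")
  expect_error(resolveLoop(LoopSpec("A", 318, 326, referenceResIds = 999),
                           ens), "999")
})

test_that("resolution is independent of atom order within residues", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 2, seed = 5,
                                           regime = "flexible"))
  ens <- gen$ensemble
  perm <- sample(nrow(atomTable(ens)))
  shuffled <- ConformerEnsemble(atomTable(ens)[perm, ],
                                ens@coords[perm, , , drop = FALSE],
                                modelIds = modelIds(ens))
  d1 <- computeDescriptors(resolveLoop(gen$spec, ens, 1))
  d2 <- computeDescriptors(resolveLoop(gen$spec, shuffled, 1))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("LoopSpec validity rejects inconsistent specifications", {
  expect_error(LoopSpec("A", 326, 318, referenceResIds = 1), "anchorStart")
  expect_error(LoopSpec("A", 318, 326, referenceResIds = 320), "outside")
})
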