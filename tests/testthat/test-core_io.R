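test_that("binarization follows the 0 = non-binding encoding strictly", {
  expect_equal(binarizeEc50(c(0, 4.2, 1e-12)),
               c("negative", "positive", "positive"))
  expect_error(binarizeEc50(-1), "negative")
  expect_error(binarizeEc50(c(1, NA)), "NA")
})

test_that("molecule tables round-trip with normalized odor labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,smiles,odor_labels",
               "m1,CCO,sweet;fruity",
               "m2,CCO,",
               "m3,CCO, Sweet ; FRUITY ;"), path)
  mols <- readMoleculeTable(path, validate = FALSE)
  expect_equal(mols$odor_labels[[1]], c("sweet", "fruity"))
  expect_equal(mols$odor_labels[[2]], character(0))
  # trimming + case folding + deduplication, no synonym merging
  expect_equal(mols$odor_labels[[3]], c("sweet", "fruity"))

  out <- withr::local_tempfile(fileext = ".csv")
  writeMoleculeTable(mols, out)
  again <- readMoleculeTable(out, validate = FALSE)
  expect_equal(again, mols)
})

test_that("molecule table schema and SMILES problems are reported by id", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,smiles", "m1,CCO"), path)
  expect_error(readMoleculeTable(path), "odor_labels")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,smiles,odor_labels",
               "m1,CCO,sweet", "m3,not_a_smiles,minty"), path2)
  expect_error(readMoleculeTable(path2, validate = TRUE), "m3")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,smiles,odor_labels",
               "m1,CCO,sweet", "m1,CCC,minty"), path3)
  expect_error(readMoleculeTable(path3, validate = FALSE), "duplicate")
})

test_that("binding tables derive labels, report coverage and round-trip", {
  mols <- tinyMolecules()
  recs <- tinyReceptors()
  grid <- expand.grid(molecule_id = mols$molecule_id,
                      receptor_id = names(recs),
                      stringsAsFactors = FALSE)
  grid$log_ec50 <- 0
  grid$log_ec50[c(1, 5, 9)] <- c(4.5, 3.2, 6.1)

  samples <- bindingSamples(grid, mols, recs)
  expect_equal(nrow(samples), nrow(mols) * length(recs))
  expect_equal(attr(samples, "coverage"), 1)
  expect_equal(sum(samples$label == "positive"), 3)
  expect_true(all((samples$label == "positive") == (samples$log_ec50 > 0)))

  path <- withr::local_tempfile(fileext = ".csv")
  writeBindingTable(samples, path)
  again <- readBindingTable(path, mols, recs)
  expect_equal(again$log_ec50, samples$log_ec50)
  expect_equal(again$label, samples$label)

  bad <- grid; bad$log_ec50[2] <- -0.5
  expect_error(bindingSamples(bad, mols, recs), "negative")
  unknown <- grid; unknown$molecule_id[1] <- "nope"
  expect_error(bindingSamples(unknown, mols, recs), "nope")
})

test_that("profiles require a complete grid and keep panel order", {
  mols <- tinyMolecules()[1:2, ]
  panel <- c("OR1", "OR2", "OR3")
  grid <- expand.grid(molecule_id = mols$molecule_id, receptor_id = panel,
                      stringsAsFactors = FALSE)
  grid$log_ec50 <- c(1, 0, 0, 2, 0, 0)
  grid$label <- binarizeEc50(grid$log_ec50)

  prof <- buildProfiles(grid, panel)
  expect_equal(dim(prof), c(2L, 3L))
  expect_equal(colnames(prof), panel)
  expect_equal(prof["ethanol", "OR1"], 1)
  expect_equal(unname(prof["hexanal", ]), c(0, 2, 0))

  expect_error(buildProfiles(grid[-3, ], panel), "OR2")
})

test_that("receptor FASTA reading validates the alphabet and parses species", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">OR1|mouse", "MKTAYIAK", ">OR2|human", "MSLLTE",
               ">OR3", "MAWTPL"), fa)
  recs <- readReceptorFasta(fa)
  expect_equal(names(recs), c("OR1", "OR2", "OR3"))
  expect_equal(S4Vectors::mcols(recs)$species, c("mouse", "human", "unknown"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">OR1", "MKTXAYIAK"), bad)
  expect_error(readReceptorFasta(bad), "'X' at position 4")
})

test_that("aligned FASTA must be rectangular over the gapped alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">OR1", "MK-TA", ">OR2", "MKQTA"), fa)
  aln <- readAlignedFasta(fa)
  expect_equal(unique(Biostrings::width(aln)), 5L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">OR1", "MKTA", ">OR2", "MK"), bad)
  expect_error(readAlignedFasta(bad), "unequal")
})
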