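test_that("the default study reproduces the reference screen shape", {
  st <- defaultStudy()
  expect_equal(nrow(st$samples), 63 * 61)
  expect_equal(length(unique(st$samples$molecule_id)), 63L)
  expect_equal(length(unique(st$samples$receptor_id)), 61L)
  expect_equal(attr(bindingSamples(st$samples, st$molecules, st$receptors),
                    "coverage"), 1)

  frac <- mean(st$samples$label == "positive")
  expect_lte(abs(frac - 333 / 3843), 0.2 * 333 / 3843)

  pos <- st$samples$log_ec50[st$samples$label == "positive"]
  expect_true(all(pos > 0))
  expect_true(all(pos < 10))
  expect_gt(stats::sd(pos), 0.3)   # non-trivial dynamic range for Model 2
})

test_that("study generation is deterministic in the seed", {
  a <- generateStudy(synthConfig(n_molecules = 20, n_receptors = 16,
                                 positive_rate = 0.12, seed = 9))
  b <- generateStudy(synthConfig(n_molecules = 20, n_receptors = 16,
                                 positive_rate = 0.12, seed = 9))
  expect_identical(a$samples, b$samples)
  expect_identical(a$molecules, b$molecules)
  expect_identical(as.character(a$receptors), as.character(b$receptors))
  c <- generateStudy(synthConfig(n_molecules = 20, n_receptors = 16,
                                 positive_rate = 0.12, seed = 10))
  expect_false(identical(a$samples$log_ec50, c$samples$log_ec50))
})

test_that("odor labels are anchored to binding and the planted partition", {
  st <- defaultStudy()
  labeled <- lengths(st$molecules$odor_labels) > 0
  binds <- rowSums(st$profiles > 0) > 0
  # a molecule carries labels iff it has a planted community; every
  # such molecule binds (binding without a community can arise from
  # detection-noise flip-ins and stays unannotated)
  expect_identical(unname(labeled),
                   unname(lengths(st$true_assignments) > 0))
  expect_true(all(binds[labeled]))
  vocab <- names(communityOf(st$true_partition))
  expect_true(all(unlist(st$molecules$odor_labels) %in% vocab))
})

test_that("community extraction recovers the planted partition", {
  st <- defaultStudy()
  g <- buildOdorGraph(st$molecules)
  p <- greedyModularityPartition(g, weighted = TRUE)
  truth <- communityOf(st$true_partition)
  common <- intersect(names(truth), names(communityOf(p)))
  expect_gte(adjustedRand(communityOf(p)[common], truth[common]), 0.8)
})

test_that("held-out molecules extend the study without entering it", {
  st <- defaultStudy()
  expect_equal(nrow(st$holdout$molecules), 80L)
  expect_length(intersect(st$holdout$molecules$molecule_id,
                          st$molecules$molecule_id), 0)
  expect_equal(colnames(st$holdout$profiles), names(st$receptors))
  expect_false(any(st$holdout$molecules$molecule_id %in%
                     st$samples$molecule_id))
})

test_that("a written study round-trips through the package readers", {
  st <- generateStudy(synthConfig(n_molecules = 12, n_receptors = 10,
                                  positive_rate = 0.15, n_odor_labels = 12,
                                  n_communities = 3, seed = 4))
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  mols <- readMoleculeTable(file.path(dir, "molecules.csv"))
  recs <- readReceptorFasta(file.path(dir, "receptors.fasta"))
  samp <- readBindingTable(file.path(dir, "binding.csv"), mols, recs)
  expect_equal(nrow(samp), 12 * 10)
  expect_equal(samp$label, st$samples$label)
  expect_equal(S4Vectors::mcols(recs)$species,
               S4Vectors::mcols(st$receptors)$species)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$true_partition, 12)
})

test_that("the planted binding signal is learnable from half the grid", {
  st <- defaultStudy()
  mb <- featureMatrix(morganFingerprint(st$molecules))
  mb <- FeatureBlock(mb[, apply(mb, 2, function(z) any(z != z[1])),
                        drop = FALSE], "morgan")
  x <- featureMatrix(joinFeatures(mb, featurizeReceptors(st$receptors, "1AAF"),
                                  st$samples))
  y <- st$samples$label
  set.seed(55)
  train <- sample(nrow(x), nrow(x) %/% 2)
  us <- clusterUndersample(x[train, ], y[train], seed = 56)
  fit <- ranger::ranger(x = x[train, ][keptIndices(us), ],
                        y = factor(y[train][keptIndices(us)]),
                        num.trees = 500, seed = 57, num.threads = 1)
  pred <- as.character(stats::predict(fit, data = x[-train, ],
                                      num.threads = 1)$predictions)
  cc <- confusionCounts(y[-train], pred)
  m <- classificationMetrics(cc$TP, cc$TN, cc$FP, cc$FN)
  expect_gte(m$f_measure, 0.7)
})

test_that("saturating noise destroys the signal (leakage guard)", {
  st <- generateStudy(synthConfig(noise_sd = 100, label_noise_rate = 0.5,
                                  seed = 3))
  mb <- featureMatrix(morganFingerprint(st$molecules))
  mb <- FeatureBlock(mb[, apply(mb, 2, function(z) any(z != z[1])),
                        drop = FALSE], "morgan")
  x <- featureMatrix(joinFeatures(mb, featurizeReceptors(st$receptors, "1AAF"),
                                  st$samples))
  y <- st$samples$label
  set.seed(58)
  train <- sample(nrow(x), nrow(x) %/% 2)
  fit <- glmnet::glmnet(x[train, ], factor(y[train]), family = "binomial",
                        alpha = 0, lambda = 1 / length(train))
  prob <- as.numeric(stats::predict(fit, x[-train, ], type = "response"))
  acc <- mean((prob > 0.5) == (y[-train] == "positive"))
  baseline <- max(mean(y[-train] == "negative"),
                  mean(y[-train] == "positive"))
  expect_lte(abs(acc - baseline), 0.1)
})

test_that("infeasible configurations fail loudly", {
  expect_error(synthConfig(positive_rate = 0), "positive_rate")
  expect_error(synthConfig(n_odor_labels = 3, n_communities = 6))
})
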