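#' Join molecule and receptor descriptor blocks over pairs
#'
#' One row per (molecule, receptor) pair: the molecule's descriptor row
#' concatenated with the receptor's, column names prefixed by the block
#' of origin. The joint design matrix of the binding models.
#'
#' @param molBlock,protBlock [FeatureBlock-class]s covering all ids in
#'   `pairs`.
#' @param pairs data.frame with columns `molecule_id`, `receptor_id`;
#'   rows may repeat.
#' @return a [FeatureBlock-class] of dimension
#'   `nrow(pairs) x (ncol(molBlock) + ncol(protBlock))`.
#' @export
joinFeatures <- function(molBlock, protBlock, pairs) {
  stopifnot(all(c("molecule_id", "receptor_id") %in% names(pairs)))
  mm <- featureMatrix(molBlock); pm <- featureMatrix(protBlock)
  badM <- setdiff(unique(pairs$molecule_id), rownames(mm))
  if (length(badM)) stop("molecule id(s) missing from molecule block: ",
                         paste(utils::head(badM, 5), collapse = ", "))
  badR <- setdiff(unique(pairs$receptor_id), rownames(pm))
  if (length(badR)) stop("receptor id(s) missing from receptor block: ",
                         paste(utils::head(badR, 5), collapse = ", "))
  joint <- cbind(mm[pairs$molecule_id, , drop = FALSE],
                 pm[pairs$receptor_id, , drop = FALSE])
  colnames(joint) <- c(paste0("mol.", colnames(mm)),
                       paste0("prot.", colnames(pm)))
  rownames(joint) <- paste(pairs$molecule_id, pairs$receptor_id, sep = "|")
  FeatureBlock(joint, paste0(blockName(molBlock), "+", blockName(protBlock)))
}

#' Cascade configuration
#'
#' Descriptor variants, method-panel profile, CV fold counts, seed and
#' thresholds for [trainCascade()]. Defaults: Morgan + 1AAF joint
#' descriptors for both binding models (one featurization shared
#' across the cascade), 5x5 nested CV, clustering undersampling on,
#' strict 20% community-share threshold.
#'
#' @param model1Mol,model1Prot descriptor variants for Model 1.
#' @param model2Mol,model2Prot descriptor variants for Model 2.
#' @param profile method-panel profile, `"fast"` or `"full"`.
#' @param methods1,methods2,methods3 optional character vectors
#'   overriding the panel per model.
#' @param outerFolds,innerFolds nested-CV fold counts.
#' @param seed master seed for all randomness.
#' @param undersample rebalance classification training folds.
#' @param communityThreshold strict share threshold of
#'   [assignMoleculeCommunities()].
#' @param weightedGraph extract odor communities with weighted
#'   modularity (co-annotation counts as evidence) rather than the 0/1
#'   adjacency; the default, since a single stray co-annotation should
#'   not weigh as much as many consistent ones.
#' @param species restrict receptors by species tag (`"both"`,
#'   `"mouse"`, `"human"`).
#' @return named list.
#' @export
cascadeConfig <- function(model1Mol = "morgan", model1Prot = "1AAF",
                          model2Mol = "morgan", model2Prot = "1AAF",
                          profile = c("fast", "full"),
                          methods1 = NULL, methods2 = NULL, methods3 = NULL,
                          outerFolds = 5L, innerFolds = 5L, seed = 1L,
                          undersample = TRUE, communityThreshold = 0.2,
                          weightedGraph = TRUE,
                          species = c("both", "mouse", "human")) {
  list(model1Mol = model1Mol, model1Prot = model1Prot,
       model2Mol = model2Mol, model2Prot = model2Prot,
       profile = match.arg(profile),
       methods1 = methods1, methods2 = methods2, methods3 = methods3,
       outerFolds = as.integer(outerFolds), innerFolds = as.integer(innerFolds),
       seed = as.integer(seed), undersample = isTRUE(undersample),
       communityThreshold = communityThreshold,
       weightedGraph = isTRUE(weightedGraph),
       species = match.arg(species))
}

dropConstantColumns <- function(block) {
  m <- featureMatrix(block)
  keep <- apply(m, 2, function(col) any(col != col[1]))
  FeatureBlock(m[, keep, drop = FALSE], blockName(block))
}

refitBest <- function(def, x, y, task, config, seed) {
  if (task == "classification" && config$undersample) {
    us <- clusterUndersample(x, as.character(y),
                             seed = deriveSeed(seed, "refit_us"))
    x <- x[keptIndices(us), , drop = FALSE]
    y <- y[keptIndices(us)]
  }
  tuneAndFit(def, x, y, innerFolds = config$innerFolds, seed = seed)
}

#' Train the three-model odor-prediction cascade
#'
#' Model 1 (binding classifier) is selected by nested CV over the method
#' panel on the full molecule-by-receptor grid, with clustering
#' undersampling of the majority class inside training folds. Model 2
#' (log(EC50) regressor) is selected the same way on the positive pairs
#' only. The odor partition is extracted from the training molecules'
#' label co-annotation graph, molecules are assigned communities by the
#' majority rule, and Model 3 fits one binary classifier per community
#' on the measured activation profiles. Each best method is refit on all
#' of its training data. A community with fewer than 2 positive (or
#' negative) molecules gets no classifier and is reported as "not
#' assessed" at predict time.
#'
#' @param molecules molecule table (see [readMoleculeTable()]); odor
#'   labels are required for Model 3.
#' @param receptors receptor panel ([readReceptorFasta()]).
#' @param samples complete binding grid ([readBindingTable()]).
#' @param config a [cascadeConfig()].
#' @param alignment optional aligned receptor set for the `"alignment"`
#'   protein descriptor.
#' @return a [CascadeModel-class]
#' @export
trainCascade <- function(molecules, receptors, samples,
                         config = cascadeConfig(), alignment = NULL) {
  if (config$species != "both")
    receptors <- receptors[S4Vectors::mcols(receptors)$species == config$species]
  panel <- names(receptors)
  samples <- samples[samples$receptor_id %in% panel, , drop = FALSE]

  molVariants <- unique(c(config$model1Mol, config$model2Mol))
  molBlocks <- lapply(molVariants, function(v)
    dropConstantColumns(featurizeMolecules(molecules, v)))
  names(molBlocks) <- molVariants
  protVariants <- unique(c(config$model1Prot, config$model2Prot))
  protBlocks <- lapply(protVariants, function(v)
    featurizeReceptors(receptors, v, alignment = alignment))
  names(protBlocks) <- protVariants

  # ---- Model 1: binding yes/no on every pair ----
  x1 <- featureMatrix(joinFeatures(molBlocks[[config$model1Mol]],
                                   protBlocks[[config$model1Prot]], samples))
  y1 <- factor(samples$label, levels = c("negative", "positive"))
  panel1 <- methodPanel("classification", profile = config$profile,
                        methods = config$methods1)
  cv1 <- nestedCV(x1, y1, "classification", methods = panel1,
                  outerFolds = config$outerFolds, innerFolds = config$innerFolds,
                  seed = deriveSeed(config$seed, "model1"),
                  undersample = config$undersample)
  fit1 <- refitBest(panel1[[cv1$best]], x1, y1, "classification", config,
                    seed = deriveSeed(config$seed, "model1_refit"))

  # ---- Model 2: log(EC50) on the measured binders only ----
  pos <- samples[samples$label == "positive", , drop = FALSE]
  if (nrow(pos) < 10) stop("too few positive samples to train the regressor")
  x2 <- featureMatrix(joinFeatures(molBlocks[[config$model2Mol]],
                                   protBlocks[[config$model2Prot]], pos))
  y2 <- pos$log_ec50
  panel2 <- methodPanel("regression", profile = config$profile,
                        methods = config$methods2)
  cv2 <- nestedCV(x2, y2, "regression", methods = panel2,
                  outerFolds = config$outerFolds, innerFolds = config$innerFolds,
                  seed = deriveSeed(config$seed, "model2"))
  fit2 <- tuneAndFit(panel2[[cv2$best]], x2, y2,
                     innerFolds = config$innerFolds,
                     seed = deriveSeed(config$seed, "model2_refit"))

  # ---- odor communities and Model 3 ----
  labeled <- molecules[lengths(molecules$odor_labels) > 0, , drop = FALSE]
  if (!nrow(labeled)) stop("no molecule carries odor labels; Model 3 needs them")
  graph <- buildOdorGraph(labeled)
  partition <- greedyModularityPartition(graph,
                                         weighted = config$weightedGraph)
  assignments <- assignMoleculeCommunities(labeled, partition,
                                           threshold = config$communityThreshold)
  profiles <- buildProfiles(samples, panel)
  profLabeled <- profiles[labeled$molecule_id, , drop = FALSE]

  # the odor models are cheap (profile-width designs, few samples), so
  # their panel always includes the linear and tree methods that suit
  # per-community calls; selection is by balanced accuracy, which at
  # these prevalences rewards classifiers that are right on both the
  # present and absent side (plain accuracy rewards never calling the
  # community, F-measure rewards over-calling it)
  methods3 <- config$methods3 %||%
    c("logistic", "svm_linear", "tree", "rf", "xgb")
  panel3 <- methodPanel("classification", methods = methods3)
  communities <- sort(unique(communityOf(partition)))
  model3 <- vector("list", length(communities))
  names(model3) <- paste0("community_", communities)
  cv3 <- vector("list", length(communities))
  names(cv3) <- names(model3)
  for (ci in seq_along(communities)) {
    cLab <- communities[ci]
    y3 <- factor(ifelse(vapply(assignments, function(a) cLab %in% a, TRUE),
                        "positive", "negative"),
                 levels = c("negative", "positive"))
    if (min(table(y3)) < 2L) {
      warning(sprintf("community %d has < 2 molecules on one side; its ",
                      cLab), "classifier is disabled", call. = FALSE)
      next
    }
    of <- min(config$outerFolds, min(table(y3)))
    cv3[[ci]] <- nestedCV(profLabeled, y3, "classification", methods = panel3,
                          outerFolds = of, innerFolds = config$innerFolds,
                          seed = deriveSeed(config$seed, paste0("model3_", cLab)),
                          undersample = config$undersample,
                          selectBy = "balanced_accuracy")
    fit3 <- refitBest(panel3[[cv3[[ci]]$best]], profLabeled, y3,
                      "classification", config,
                      seed = deriveSeed(config$seed, paste0("model3_refit", cLab)))
    model3[[ci]] <- list(method = cv3[[ci]]$best, fit = fit3$fit,
                         params = fit3$params,
                         predict = panel3[[cv3[[ci]]$best]]$predict)
  }

  new("CascadeModel",
      model1 = list(method = cv1$best, fit = fit1$fit, params = fit1$params,
                    predict = panel1[[cv1$best]]$predict),
      model2 = list(method = cv2$best, fit = fit2$fit, params = fit2$params,
                    predict = panel2[[cv2$best]]$predict),
      model3 = model3,
      panel = panel,
      config = config,
      partition = partition,
      training = list(
        cv1 = cv1, cv2 = cv2, cv3 = cv3,
        assignments = assignments,
        molColumns1 = colnames(featureMatrix(molBlocks[[config$model1Mol]])),
        molColumns2 = colnames(featureMatrix(molBlocks[[config$model2Mol]])),
        protRows1 = featureMatrix(protBlocks[[config$model1Prot]]),
        protRows2 = featureMatrix(protBlocks[[config$model2Prot]])))
}

molRowsFor <- function(smiles, moleculeIds, variant, wantedColumns) {
  block <- featurizeMolecules(
    data.frame(molecule_id = moleculeIds, smiles = smiles), variant)
  m <- featureMatrix(block)
  miss <- setdiff(wantedColumns, colnames(m))
  if (length(miss))
    stop("featurization did not reproduce training column(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  m[, wantedColumns, drop = FALSE]
}

#' Predict odor communities for new molecules (three-step cascade)
#'
#' Step 1: the binding classifier scores every (molecule, receptor) pair
#' over the model's receptor panel. Step 2: the regressor predicts
#' log(EC50) for the predicted binders only; every predicted non-binder
#' is set to exactly 0, and regression outputs are floored at 0 so they
#' cannot collide with the non-binding code. Step 3: the per-community
#' classifiers read the assembled activation profile and call each odor
#' community present or absent (disabled classifiers yield NA, "not
#' assessed").
#'
#' @param model a trained [CascadeModel-class].
#' @param smiles character vector of isomeric SMILES (names, if present,
#'   become molecule ids).
#' @return list with `profile` (molecules x receptors log(EC50) matrix),
#'   `binding` (Step-1 label matrix), `communityCalls` (molecules x
#'   communities logical matrix, NA = not assessed) and `communities`
#'   (list of predicted community index vectors).
#' @export
predictOdor <- function(model, smiles) {
  ids <- names(smiles) %||% paste0("query", seq_along(smiles))
  names(smiles) <- NULL
  v <- validateSmiles(smiles, ids)
  if (any(!v$ok))
    stop("unparsable SMILES for: ", paste(ids[!v$ok], collapse = ", "))

  panel <- model@panel
  pairs <- data.frame(molecule_id = rep(ids, each = length(panel)),
                      receptor_id = rep(panel, length(ids)))

  mol1 <- molRowsFor(smiles, ids, model@config$model1Mol,
                     model@training$molColumns1)
  x1 <- cbind(mol1[pairs$molecule_id, , drop = FALSE],
              model@training$protRows1[pairs$receptor_id, , drop = FALSE])
  colnames(x1) <- c(paste0("mol.", colnames(mol1)),
                    paste0("prot.", colnames(model@training$protRows1)))
  bind <- model@model1$predict(model@model1$fit, x1)
  bindMat <- matrix(as.character(bind), nrow = length(ids), byrow = TRUE,
                    dimnames = list(ids, panel))

  profile <- matrix(0, nrow = length(ids), ncol = length(panel),
                    dimnames = list(ids, panel))
  posPairs <- pairs[bind == "positive", , drop = FALSE]
  if (nrow(posPairs)) {
    mol2 <- molRowsFor(smiles, ids, model@config$model2Mol,
                       model@training$molColumns2)
    x2 <- cbind(mol2[posPairs$molecule_id, , drop = FALSE],
                model@training$protRows2[posPairs$receptor_id, , drop = FALSE])
    colnames(x2) <- c(paste0("mol.", colnames(mol2)),
                      paste0("prot.", colnames(model@training$protRows2)))
    ec50 <- pmax(0, model@model2$predict(model@model2$fit, x2))
    profile[cbind(match(posPairs$molecule_id, ids),
                  match(posPairs$receptor_id, panel))] <- ec50
  }

  commNames <- names(model@model3)
  calls <- matrix(NA, nrow = length(ids), ncol = length(commNames),
                  dimnames = list(ids, commNames))
  for (cn in commNames) {
    m3 <- model@model3[[cn]]
    if (is.null(m3)) next   # not assessed
    calls[, cn] <- m3$predict(m3$fit, profile) == "positive"
  }
  communities <- lapply(seq_along(ids), function(i) {
    on <- which(calls[i, ] %in% TRUE)
    as.integer(sub("community_", "", commNames[on]))
  })
  names(communities) <- ids
  list(profile = profile, binding = bindMat, communityCalls = calls,
       communities = communities)
}

#' Write cascade predictions to CSV
#'
#' One row per molecule: `molecule_id`, one predicted log(EC50) column
#' per receptor, then one presence column per odor community (`NA` for
#' communities without a classifier).
#'
#' @param pred a [predictOdor()] result.
#' @param path output CSV path.
#' @export
writePredictions <- function(pred, path) {
  df <- data.frame(molecule_id = rownames(pred$profile),
                   pred$profile, pred$communityCalls + 0,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained cascade bundle
#'
#' Single-file RDS bundle with a manifest recording the configuration
#' and the package version.
#'
#' @param model a [CascadeModel-class]
#' @param path bundle path (.rds)
#' @return `loadCascade` returns the [CascadeModel-class].
#' @export
saveCascade <- function(model, path) {
  saveRDS(list(manifest = list(package = "odorcascade",
                               version = as.character(utils::packageVersion("odorcascade")),
                               config = model@config,
                               created = format(Sys.time(), tz = "UTC")),
               model = model), path)
  invisible(path)
}

#' @rdname saveCascade
#' @export
loadCascade <- function(path) {
  bundle <- readRDS(path)
  stopifnot(is(bundle$model, "CascadeModel"))
  bundle$model
}
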