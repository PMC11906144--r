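# Shared fixtures and independent oracles. Everything is generated in
# code; the expensive seed-0 study and trained cascade are built once
# per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tinyMolecules <- function() {
  out <- data.frame(
    molecule_id = c("ethanol", "hexanal", "benzaldehyde", "limonene"),
    smiles = c("CCO", "CCCCCC=O", "O=Cc1ccccc1", "CC(=C)C1CCC(C)=CC1"),
    stringsAsFactors = FALSE)
  out$odor_labels <- list(c("sweet", "alcoholic"), c("green", "grassy"),
                          c("almond", "sweet"), c("citrus", "fresh"))
  out
}

tinyReceptors <- function() {
  seqs <- Biostrings::AAStringSet(c(
    OR1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    OR2 = "MSLLTEVETYVLSIVPSGPLKAEIAQRLEDV",
    OR3 = "MAWTPLLLLLLSHCTGSLSQPVLTQPPS"))
  S4Vectors::mcols(seqs)$species <- c("mouse", "human", "mouse")
  seqs
}

moleculesFromLabelSets <- function(labelSets) {
  out <- data.frame(molecule_id = sprintf("m%02d", seq_along(labelSets)),
                    smiles = rep("CCO", length(labelSets)),
                    stringsAsFactors = FALSE)
  out$odor_labels <- labelSets
  out
}

# Eq.-style modularity oracle: explicit double sum over node pairs,
# independent of the package's matrix implementation
bruteModularity <- function(A, membership) {
  twoM <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (membership[i] == membership[j])
        q <- q + A[i, j] - k[i] * k[j] / twoM
  unname(q / twoM)
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, maxLab) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (lab in seq_len(maxLab + 1L))
      rec(c(assign, lab), max(maxLab, lab))
  }
  rec(integer(0), 0L)
  out
}

exhaustiveMaxQ <- function(A) {
  n <- nrow(A)
  best <- -Inf
  for (p in allPartitions(n)) {
    q <- bruteModularity(A, p)
    if (q > best) best <- q
  }
  best
}

randomGraphAdjacency <- function(n, pEdge = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < pEdge)
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

twoCliquePlusCross <- function(nCross) {
  A <- matrix(0L, 6, 6, dimnames = list(paste0("v", 1:6), paste0("v", 1:6)))
  A[1:3, 1:3] <- 1L; A[4:6, 4:6] <- 1L; diag(A) <- 0L
  memb <- rep(1:2, each = 3)
  cross <- which(outer(memb, memb, "!=") & upper.tri(A))
  if (nCross > 0) {
    A[sample(cross, nCross)] <- 1L
    A <- pmax(A, t(A))
  }
  A
}

isConnected <- function(A) {
  n <- nrow(A)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE] > 0) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

graphFromAdjacency <- function(A) {
  storage.mode(A) <- "integer"
  new("OdorGraph", weights = A)
}

# adjusted Rand index (Hubert & Arabie), written from the contingency
# table so it does not depend on any clustering package
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nPairs <- comb2(sum(tab))
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}

randomAASequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

defaultStudy <- function() {
  cached("study0", generateStudy(synthConfig(seed = 0), nHoldout = 80))
}

defaultCascade <- function() {
  cached("cascade0", {
    st <- defaultStudy()
    suppressWarnings(trainCascade(st$molecules, st$receptors, st$samples,
                                  config = cascadeConfig(profile = "fast",
                                                         seed = 1)))
  })
}

# map a planted community index to the index it received in a trained
# partition, via the majority vote of its labels
mapPlantedCommunity <- function(planted, truePartition, trainedPartition) {
  truth <- communityOf(truePartition)
  memb <- communityOf(trainedPartition)
  labs <- intersect(names(truth)[truth == planted], names(memb))
  if (!length(labs)) return(NA_integer_)
  as.integer(names(which.max(table(memb[labs]))))
}
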