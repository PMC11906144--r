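# Synthetic study generator: emulates the statistical shape of a small
# molecule x olfactory-receptor screen (a mostly-zero dense log(EC50)
# grid with a planted, feature-determined binding signal) plus odor
# labels whose community structure is a readout of the activation
# profile. Ground truth is returned for recovery tests.

#' Curated odorant-like SMILES
#'
#' A hand-curated list of isomeric SMILES of common odorants (esters,
#' terpenoids, aldehydes, ketones, pyrazines, thiols, lactones,
#' phenolics) used to seed synthetic studies with chemistry that
#' featurizes meaningfully; randomly generated SMILES strings are too
#' often invalid or degenerate.
#'
#' @return character vector of SMILES.
#' @export
odorantSmiles <- function() {
  c(
  # esters
  "CCOC(=O)C", "CCCCOC(=O)C", "CCOC(=O)CC", "CCOC(=O)CCC", "CCOC(=O)CCCCC",
  "COC(=O)c1ccccc1", "CCOC(=O)c1ccccc1", "COC(=O)c1ccccc1O",
  "CC(=O)OCc1ccccc1", "CC(=O)OCCc1ccccc1", "CC(C)CCOC(=O)C",
  "COC(=O)CCCCCCC", "CCCCCOC(=O)C", "CCCCCCOC(=O)C", "CC(=O)OCC(C)C",
  "CCCCOC(=O)CCC", "CCOC(=O)C(C)C", "CCCCCCCCOC(=O)C", "CCOC(=O)CCCCCCC",
  "CCOC(=O)/C=C/C", "CC(=O)OC(C)(C=C)CCC=C(C)C", "CC(=O)OC/C=C(C)/CCC=C(C)C",
  "CCCCCCOC(=O)CCC", "COC(=O)c1ccccc1N", "O=C(OCc1ccccc1)c1ccccc1",
  # alcohols and phenolics
  "CCO", "CCCCCCO", "CC/C=C\\CCO", "CCCCCCCCO", "OCCc1ccccc1",
  "OCc1ccccc1", "CC(C)=CCCC(C)(O)C=C", "CC(C)=CCC/C(C)=C/CO",
  "CC(C)=CCC/C(C)=C\\CO", "CC(CCC=C(C)C)CCO",
  "CC(C)[C@@H]1CC[C@@H](C)C[C@H]1O", "CC(C)[C@H]1CC[C@H](C)C[C@@H]1O",
  "CC1=CCC(CC1)C(C)(C)O", "COc1cc(CC=C)ccc1O", "Cc1ccc(C(C)C)c(O)c1",
  "Cc1ccc(C(C)C)cc1O", "COc1ccccc1O", "COc1cc(C=O)ccc1O",
  # aldehydes
  "CCCCCC=O", "CCCCCCCC=O", "CCCCCCCCC=O", "CCCCCCCCCC=O",
  "O=Cc1ccccc1", "O=C/C=C/c1ccccc1", "CC(C)=CCC/C(C)=C/C=O",
  "CC(CCC=C(C)C)CC=O", "COc1ccc(C=O)cc1", "CC(C)c1ccc(C=O)cc1",
  "O=Cc1ccco1", "CCC(C)C=O", "CC(C)CC=O", "CCC/C=C/C=O",
  # ketones
  "CCCCCC(C)=O", "CCC(=O)CCCC", "CCC(=O)CCCCC", "CC(=O)c1ccccc1",
  "CC1=CCC(CC1=O)C(C)=C", "CC(C)C1CCC(C)CC1=O",
  "CC(=O)/C=C/C1=C(C)CCCC1(C)C", "CC(=O)CCc1ccc(O)cc1", "CC(=O)C(C)=O",
  "CC(O)C(C)=O", "CCCCCCCCCC(C)=O", "CC1(C)C2CCC1(C)C(=O)C2",
  # terpene and aromatic hydrocarbons
  "CC(=C)C1CCC(C)=CC1", "CC(=C)[C@@H]1CCC(C)=CC1", "CC1=CCC2CC1C2(C)C",
  "C=C1CCC2CC1C2(C)C", "CC(C)=CCCC(=C)C=C", "Cc1ccc(C(C)C)cc1",
  "C=Cc1ccccc1", "Cc1ccccc1", "c1ccc2ccccc2c1",
  # pyrazines
  "Cc1cnccn1", "Cc1nccnc1C", "CCc1nccnc1C", "COc1nccnc1CC(C)C",
  "CC(=O)c1cnccn1",
  # sulfur compounds
  "CCS", "SCc1ccco1", "CSC", "CSSC", "C=CCSC", "CCCC(S)CCO", "CSCCC=O",
  # acids
  "CC(=O)O", "CCCC(=O)O", "CCCCCC(=O)O", "CC(C)CC(=O)O",
  "OC(=O)c1ccccc1", "OC(=O)Cc1ccccc1", "CCCCCCCC(=O)O",
  # lactones and heterocycles
  "CCCCCCC1CCC(=O)O1", "O=C1CCCO1", "O=c1ccc2ccccc2o1",
  "CCCCCC1CCCC(=O)O1", "CCCCCC1CCC(=O)O1", "CC12CCC(CC1)C(C)(C)O2",
  "c1ccc2[nH]ccc2c1", "Cc1c[nH]c2ccccc12", "C=CCc1ccc2OCOc2c1",
  # ethers, misc
  "COc1ccc(/C=C/C)cc1", "COc1ccc(CC=C)cc1", "COc1ccccc1",
  "CC1=C(O)C(=O)C=CO1", "CCC1=C(O)C(=O)C=CO1", "CN(C)C",
  "CC(C)=CCC/C(C)=C/CCC(C)(O)C=C", "CC(=O)OCC/C=C\\CC",
  # further esters
  "CCCOC(=O)C", "CC(C)OC(=O)C", "COC(=O)C", "COC(=O)CCC", "COC(=O)CCCCC",
  "CCCOC(=O)CCC", "CC(C)CCOC(=O)CCC", "CCOC(=O)CCCC", "CCOC(=O)CCCCCC",
  "CCOC(=O)CCCCCCCC", "CCOC(=O)CCCCCCCCC", "COC(=O)/C=C/c1ccccc1",
  "CCOC(=O)/C=C/c1ccccc1", "CCOC(=O)Cc1ccccc1", "COC(=O)Cc1ccccc1",
  "CCOC(=O)C(C)O", "CCOC(=O)C(C)CC", "COC(=O)C(C)CC", "CCCC(=O)OCc1ccccc1",
  "CCCC(=O)OCCc1ccccc1", "CCCC(=O)OCC(C)C", "CCOC(=O)c1ccccc1O",
  # further alcohols
  "CCCO", "CC(C)CCO", "CCCCCO", "CCCCCCCO", "CCCCCCCCCO", "CCCCCCCCCCO",
  "CCCCC(CC)CO", "CCC/C=C/CO", "C=CC(O)CCCCC", "CC(C)(O)CCCC(C)C=C",
  "OC/C=C/c1ccccc1", "COc1ccc(CO)cc1", "OCCOc1ccccc1", "OCc1ccc(O)c(OC)c1",
  # further aldehydes
  "CCCCCCC=O", "CCCCCCCCCCC=O", "CCCCCCCCCCCC=O", "CC(C)C=O", "CCCCC=O",
  "CCCCCC/C=C/C=O", "CCCCC/C=C/C=C/C=O", "O=CCc1ccccc1", "CC(C=O)c1ccccc1",
  "Cc1ccc(C=O)cc1", "COc1ccc(C=O)cc1OC", "O=Cc1ccc2OCOc2c1",
  "CC(C=O)Cc1ccc(C(C)(C)C)cc1",
  # further ketones
  "CC(C)=O", "CCC(C)=O", "CCCC(C)=O", "CCCCC(C)=O", "CCCCCCC(C)=O",
  "CCCCCCCC(C)=O", "CCC(=O)CC", "CC(C)CC(C)=O", "O=C(c1ccccc1)c1ccccc1",
  "CC(=O)c1ccc(C)cc1", "CC(=O)/C=C/C1C(C)=CCCC1(C)C",
  "CC1CCC(=C(C)C)C(=O)C1", "CC1(C)C2CCC(C)(C2)C1=O",
  # further terpenes
  "CC1=CC=C(C(C)C)CC1", "CC1=CCC(=C(C)C)CC1", "CC1(C)C2CCC(C2)C1=C",
  "CC1=CCC2C(C1)C2(C)C",
  # further phenolics and ethers
  "Oc1ccccc1", "Cc1ccc(O)cc1", "CCc1ccc(O)cc1", "CCc1ccc(O)c(OC)c1",
  "COc1cc(/C=C/C)ccc1O", "COc1cc(CC=C)ccc1OC", "COc1cccc(OC)c1O",
  "O(c1ccccc1)c1ccccc1", "CCOc1cc(C=O)ccc1O",
  # further N/S heterocycles
  "CCc1cnccn1", "Cc1cnc(C)cn1", "Cc1cnc(C)c(C)n1", "COc1nccnc1C(C)C",
  "CC(=O)c1ccccn1", "c1ccncc1", "CC(=O)c1nccs1", "c1ccc2scnc2c1",
  # further sulfur compounds
  "CS", "CCCS", "C=CCS", "CSSSC", "C=CCSSCC=C", "CSCCCO",
  # further acids
  "CCC(=O)O", "CCCCC(=O)O", "CCCCCCC(=O)O", "CCCCCCCCC(=O)O",
  "CCCCCCCCCC(=O)O", "CCC(C)C(=O)O", "C/C=C(\\C)C(=O)O",
  "OC(=O)/C=C/c1ccccc1", "CC(=O)CCC(=O)O", "CC(O)C(=O)O",
  # further lactones
  "CC1CCC(=O)O1", "CCC1CCC(=O)O1", "CCCCC1CCC(=O)O1", "CCCCCCCC1CCCC(=O)O1",
  "CCCCC1OC(=O)CC1C"
  )
}

# simple homolog series used to extend the molecule set beyond the
# curated list when a config asks for more molecules than it holds
decoratedSmiles <- function(n) {
  series <- function(k) c(
    paste0(strrep("C", k + 2), "O"),                # 1-alkanols
    paste0(strrep("C", k + 2), "C=O"),              # alkanals
    paste0("CCOC(=O)", strrep("C", k + 1)),         # ethyl esters
    paste0("CC(=O)O", strrep("C", k + 2)),          # acetate esters
    paste0(strrep("C", k + 1), "C(C)=O"))           # methyl ketones
  out <- character(0); k <- 3
  while (length(out) < n) { out <- unique(c(out, series(k))); k <- k + 1 }
  out[seq_len(n)]
}

#' Synthetic study configuration
#'
#' Defaults mirror the scale of a published small-molecule/olfactory
#' receptor screen: 63 molecules crossed with 61 receptors (3843
#' pairs), roughly 8.7% positive pairs (333/3843), a 23-label odor
#' vocabulary partitioned into 6 communities. `noise_sd` is the
#' Gaussian noise on binder log(EC50) values (which span [3, 7]);
#' `label_noise_rate` is the per-label probability of being swapped for
#' a random label from the whole vocabulary.
#'
#' @param n_molecules,n_receptors grid dimensions.
#' @param positive_rate fraction of (molecule, receptor) pairs that bind.
#' @param n_odor_labels,n_communities odor vocabulary size and planted
#'   community count.
#' @param noise_sd,label_noise_rate noise levels (see above).
#' @param seed master seed; fixes all randomness of the generator.
#' @return named list.
#' @export
synthConfig <- function(n_molecules = 63L, n_receptors = 61L,
                        positive_rate = 333 / 3843,
                        n_odor_labels = 23L, n_communities = 6L,
                        noise_sd = 0.3, label_noise_rate = 0.02,
                        seed = 0L) {
  stopifnot(positive_rate > 0, positive_rate < 1,
            n_communities <= n_odor_labels)
  list(n_molecules = as.integer(n_molecules),
       n_receptors = as.integer(n_receptors),
       positive_rate = positive_rate,
       n_odor_labels = as.integer(n_odor_labels),
       n_communities = as.integer(n_communities),
       noise_sd = noise_sd, label_noise_rate = label_noise_rate,
       seed = as.integer(seed))
}

# AA sampling weights loosely shaped like globular/membrane protein
# composition (hydrophobics enriched, W/C rare)
aaFreqs <- c(A = 8, C = 2, D = 5, E = 6, F = 5, G = 7, H = 2, I = 6, K = 5,
             L = 10, M = 2, N = 4, P = 5, Q = 4, R = 5, S = 7, T = 5,
             V = 7, W = 1, Y = 3)

#' Generate a synthetic molecule/receptor/odor study
#'
#' Receptors are random canonical-alphabet sequences of GPCR-like
#' length (290-330), drawn in composition families (like OR
#' subfamilies, each with a signature-residue enrichment). Molecules
#' are drawn from [odorantSmiles()] (extended by simple homolog series
#' if needed). Binding follows a planted chemotype/receptor-competence
#' model: a set of mid-prevalence fingerprint bits marks binding
#' chemotypes, one receptor family is binding-competent, and a pair
#' binds iff both sides match, with per-receptor chemotype
#' sensitivities grading the binding strength. Binder log(EC50) is
#' mapped affinely onto [3, 7] plus Gaussian noise (`noise_sd`); the
#' same noise level also drives a detection flip rate, so at 0 the
#' binder set is a deterministic function of the features and as
#' `noise_sd` grows it degrades to random. Each binding molecule's
#' planted odor community is the argmax of standardized per-community
#' linear readouts of its activation profile; its odor labels are drawn
#' from that community's label pool and corrupted at
#' `label_noise_rate`. Molecules that bind nothing carry no labels (as
#' in real screens, where part of the panel has no odor annotation).
#'
#' @param config a [synthConfig()].
#' @param nHoldout additionally generate this many molecules under the
#'   same planted law, returned separately (never part of the study's
#'   binding table) for held-out evaluation of a trained cascade.
#' @return list with `molecules`, `receptors`, `samples` (binding
#'   grid), `profiles`, `true_partition` (an [OdorPartition-class]),
#'   `true_assignments` (list of community index vectors, empty for
#'   non-binding molecules) and `true_scores` (the planted pair
#'   strengths); plus, when `nHoldout > 0`, a `holdout` list with
#'   `molecules`, `profiles` and `true_assignments` for the extra
#'   molecules.
#' @export
generateStudy <- function(config = synthConfig(), nHoldout = 0L) {
  nm <- config$n_molecules; nr <- config$n_receptors
  nTot <- nm + as.integer(nHoldout)

  # receptors, drawn in composition families (like OR subfamilies):
  # each family perturbs the base amino-acid frequencies, so family
  # membership is visible in the 1AAF composition
  set.seed(deriveSeed(config$seed, "receptors"))
  # family count sized so that one family can host the binding-
  # competent pool at roughly the requested positive rate
  poolTarget <- max(2L, round(nr * config$positive_rate / 0.72))
  nFam <- max(2L, min(15L, nr %/% poolTarget))
  family <- sort(rep_len(seq_len(nFam), nr))
  sigResidue <- sample(20L, nFam)   # one signature residue per family
  famFreqs <- lapply(seq_len(nFam), function(f2) {
    fr <- aaFreqs * stats::rlnorm(20, sdlog = 0.25)
    fr[sigResidue[f2]] <- fr[sigResidue[f2]] * 3
    fr / sum(fr)
  })
  lens <- sample(290:330, nr, replace = TRUE)
  seqs <- vapply(seq_len(nr), function(i)
    paste(sample(names(aaFreqs), lens[i], replace = TRUE,
                 prob = famFreqs[[family[i]]]), collapse = ""), "")
  recIds <- sprintf("OR%03d", seq_len(nr))
  receptors <- Biostrings::AAStringSet(seqs)
  names(receptors) <- recIds
  S4Vectors::mcols(receptors)$species <-
    rep(c("mouse", "human"), length.out = nr)

  # molecules
  base <- odorantSmiles()
  set.seed(deriveSeed(config$seed, "molecules"))
  if (nTot <= length(base)) smiles <- sample(base, nTot)
  else smiles <- c(sample(base), decoratedSmiles(nTot - length(base)))
  molIds <- sprintf("mol%03d", seq_len(nTot))
  molecules <- data.frame(molecule_id = molIds, smiles = smiles,
                          stringsAsFactors = FALSE)

  # planted binding signal: one binding-competent receptor family (the
  # "pool") and a set of binding chemotypes (mid-prevalence fingerprint
  # bits). A pair binds iff the molecule carries any chemotype bit and
  # the receptor belongs to the pool — a compact, feature-expressible
  # boundary (chemotype x receptor-subfamily competence). Within the
  # pool, per-receptor sensitivities to each chemotype grade the
  # binding strength, so activation profiles differ across chemotype
  # combinations (what the odor models read).
  fpm <- featureMatrix(morganFingerprint(molecules))
  aaf <- t(vapply(seqs, kmerCounts, numeric(20), k = 1))
  prev <- colMeans(fpm)
  informative <- which(prev >= 0.08 & prev <= 0.35)
  if (length(informative) < 10)
    informative <- which(prev >= 0.05 & prev <= 0.6)
  nMotif <- max(6L, config$n_communities)
  set.seed(deriveSeed(config$seed, "motifs"))
  match <- NULL; bestBalance <- -1L
  for (try in seq_len(200L)) {
    bits <- sample(informative, nMotif)
    pool <- which(family == sample(nFam, 1))
    fmat0 <- fpm[, bits, drop = FALSE]
    w <- seq(1, 0.9, length.out = nMotif)
    # bimodal tuning: each pool receptor is a strong responder to some
    # chemotypes and a weak (but nonzero) responder to the rest, so the
    # profile carries receptor-level contrast between chemotypes. Each
    # chemotype additionally owns one signature receptor that responds
    # strongly to it alone — narrow tuning within the subfamily — so no
    # two chemotypes share the same strong/weak response pattern.
    strong <- matrix(stats::runif(nMotif * length(pool)) < 0.35,
                     nMotif, length(pool))
    for (k in seq_len(nMotif)) {
      j <- 1 + (k - 1) %% length(pool)
      strong[, j] <- FALSE
      strong[k, j] <- TRUE
    }
    hmat0 <- matrix(stats::runif(nMotif * length(pool), 0.05, 0.15),
                    nMotif, length(pool))
    hmat0[strong] <- stats::runif(sum(strong), 1.2, 1.6)
    cand <- matrix(0, nTot, nr)
    cand[, pool] <- sweep(fmat0, 2, w, "*") %*% hmat0
    frac <- mean(cand[seq_len(nm), ] > 1e-9)
    nChemo <- rowSums(fmat0[seq_len(nm), , drop = FALSE] > 0)
    coverage <- mean(nChemo > 0)
    multiFrac <- sum(nChemo > 1) / max(1, sum(nChemo > 0))
    # hard gates: rate near target, molecule coverage, and mostly
    # exclusive chemotype classes (as real chemical classes are; heavy
    # overlap would blur the odor communities). Among admissible draws
    # keep the one whose chemotypes are most evenly represented, so no
    # odor community is anchored on just a couple of molecules.
    if (abs(frac - config$positive_rate) > 0.2 * config$positive_rate ||
        coverage < 0.6 || multiFrac > 0.3) next
    primDet <- apply(fmat0[seq_len(nm), , drop = FALSE] > 0, 1,
                     function(z) if (any(z)) which(z)[1] else NA_integer_)
    balance <- min(tabulate(primDet[!is.na(primDet)], nMotif))
    if (balance > bestBalance) {
      bestBalance <- balance
      match <- cand; fmat <- fmat0; hmat <- hmat0; bestPool <- pool
    }
  }
  if (is.null(match))
    stop("could not plant a binder set near the requested positive_rate; ",
         "the configuration appears infeasible")
  pool <- bestPool
  dimnames(match) <- list(molIds, recIds)
  score <- match
  isPosDet <- match > 1e-9

  # detection noise: pairs flip status at a rate that grows with
  # noise_sd (~0.04 at the default 0.3, 0.5 as noise_sd -> Inf, 0 when
  # noiseless); flips into the binder set are rate-balanced so the
  # expected binder count is preserved
  set.seed(deriveSeed(config$seed, "selection"))
  q <- 0.5 * (1 - exp(-config$noise_sd / 4))
  r1 <- stats::runif(length(match))
  qIn <- q * sum(isPosDet) / max(1, sum(!isPosDet))
  isPos <- ifelse(isPosDet, r1 >= q, r1 < qIn)
  isPos <- matrix(isPos, nTot, nr)
  set.seed(deriveSeed(config$seed, "ec50noise"))
  sPos <- match[isPos]
  rng <- range(sPos)
  ec <- if (diff(rng) < 1e-9) rep(5, length(sPos)) else
    3 + 4 * (sPos - rng[1]) / diff(rng)
  ec <- ec + stats::rnorm(length(sPos), sd = config$noise_sd)
  logEc <- matrix(0, nTot, nr, dimnames = list(molIds, recIds))
  logEc[isPos] <- pmax(0.1, ec)

  mainIds <- molIds[seq_len(nm)]
  samples <- data.frame(
    molecule_id = rep(mainIds, times = nr),
    receptor_id = rep(recIds, each = nm),
    log_ec50 = as.numeric(logEc[seq_len(nm), , drop = FALSE]),
    stringsAsFactors = FALSE)
  samples$label <- binarizeEc50(samples$log_ec50)

  # planted odor vocabulary: n_odor_labels labels split evenly into
  # n_communities communities
  nl <- config$n_odor_labels; nc <- config$n_communities
  labels <- sprintf("note%02d", seq_len(nl))
  planted <- sort(rep_len(seq_len(nc), nl))
  names(planted) <- labels
  truePartition <- new("OdorPartition", membership = as.integer(planted) |>
                         stats::setNames(labels), Q = NA_real_)

  # a molecule's odor communities are the chemotypes it carries (each
  # chemotype c maps to community 1 + (c-1) mod n_communities). This is
  # equivalent to thresholding per-community linear readouts of the
  # noiseless activation profile: the pseudo-inverse of the pool's
  # chemotype sensitivities recovers the chemotype activations from the
  # profile exactly, so "readout_c above threshold" and "chemotype c
  # present" coincide. Molecules with an all-zero profile have no odor
  # readout; like the unannotated part of a real screen, they carry no
  # labels and no planted community. Molecules activating several
  # chemotypes carry several communities (what the majority-share rule
  # downstream is for).
  labeledMol <- rowSums(logEc) > 0
  commOf <- 1L + (seq_len(nMotif) - 1L) %% nc
  trueAssign <- lapply(seq_len(nTot), function(i)
    if (labeledMol[i]) sort(unique(commOf[fmat[i, ] > 0])) else integer(0))
  names(trueAssign) <- molIds

  # odor labels: 4 labels from the primary (strongest-chemotype)
  # community, rotating through its label pool so every label gets
  # used. Label sets reflect the dominant community only — free-text
  # annotations track the salient odor — while true_assignments keeps
  # the full planted community set for evaluation
  set.seed(deriveSeed(config$seed, "labels"))
  pools <- lapply(seq_len(nc), function(c2) sample(labels[planted == c2]))
  cursor <- integer(nc)
  takeLabels <- function(c2, k) {
    pool <- pools[[c2]]
    idx <- (cursor[c2] + seq_len(k) - 1L) %% length(pool) + 1L
    cursor[c2] <<- (cursor[c2] + k) %% length(pool)
    unique(pool[idx])
  }
  odorSets <- lapply(seq_len(nTot), function(i) {
    comms <- trueAssign[[i]]
    if (!length(comms)) return(character(0))
    takeLabels(comms[1L], 4L)
  })
  flip <- function(ls) {
    doFlip <- stats::runif(length(ls)) < config$label_noise_rate
    ls[doFlip] <- sample(labels, sum(doFlip), replace = TRUE)
    unique(ls)
  }
  molecules$odor_labels <- lapply(odorSets, flip)

  main <- seq_len(nm)
  out <- list(molecules = molecules[main, , drop = FALSE],
              receptors = receptors, samples = samples,
              profiles = logEc[main, , drop = FALSE],
              true_partition = truePartition,
              true_assignments = trueAssign[main],
              true_scores = score[main, , drop = FALSE])
  if (nHoldout > 0) {
    extra <- setdiff(seq_len(nTot), main)
    out$holdout <- list(molecules = molecules[extra, , drop = FALSE],
                        profiles = logEc[extra, , drop = FALSE],
                        true_assignments = trueAssign[extra])
  }
  out
}

#' Write a synthetic study to disk
#'
#' Emits the three input files of the package's readers (molecule CSV,
#' receptor FASTA, binding CSV) plus a ground-truth JSON (planted
#' partition and community assignments).
#'
#' @param study a [generateStudy()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMoleculeTable(study$molecules, file.path(dir, "molecules.csv"))
  writeBindingTable(study$samples, file.path(dir, "binding.csv"))
  fa <- file.path(dir, "receptors.fasta")
  sp <- S4Vectors::mcols(study$receptors)$species
  writeLines(paste0(">", names(study$receptors), "|", sp, "\n",
                    as.character(study$receptors)), fa)
  jsonlite::write_json(
    list(true_partition = as.list(communityOf(study$true_partition)),
         true_assignments = study$true_assignments),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
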