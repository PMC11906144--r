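# Molecular featurization. The descriptor computations themselves are
# delegated to RDKit through a bundled Python helper (inst/python/
# mol_features.py): stereo-aware Morgan hashing, the RDKit path
# fingerprint, the 166 MACCS substructure keys and the full 2D
# physicochemical descriptor list have no native R implementation.
# Results are cached per session keyed by task, parameters and SMILES.

molFeatureCache <- new.env(parent = emptyenv())

pythonBinary <- function() {
  py <- Sys.getenv("ODORCASCADE_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) stop("no 'python' executable on PATH; the molecular ",
                        "featurization backend requires Python with rdkit")
  py
}

runMolBackend <- function(task, molecule_id, smiles, args = character()) {
  key <- paste(task, paste(args, collapse = ","),
               paste(smiles, collapse = "\r"), sep = "\n")
  hit <- molFeatureCache[[digestKey(key)]]
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)

  script <- system.file("python", "mol_features.py", package = "odorcascade",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(data.frame(molecule_id = molecule_id, smiles = smiles),
                   fin, row.names = FALSE, quote = TRUE)
  res <- suppressWarnings(system2(pythonBinary(),
                c(script, "--task", task, "--input", fin, "--output", fout, args),
                stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0)
    stop("molecular featurization backend failed: ",
         paste(res, collapse = " "))
  value <- utils::read.csv(fout, check.names = FALSE, stringsAsFactors = FALSE)
  molFeatureCache[[digestKey(key)]] <- list(key = key, value = value)
  value
}

# cheap deterministic string key (no digest dependency); collisions are
# guarded by re-checking the full key on lookup
digestKey <- function(s) {
  ints <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (blk in split(ints, ceiling(seq_along(ints) / 4096))) {
    h1 <- (h1 * 31 + sum(blk * (seq_along(blk) %% 97 + 1))) %% 2147483647
    h2 <- (h2 * 17 + sum(blk)) %% 2147483647
  }
  paste0("k", h1, "_", h2, "_", length(ints))
}

validateSmiles <- function(smiles, molecule_id = seq_along(smiles)) {
  runMolBackend("validate", molecule_id, smiles)
}

checkMolecules <- function(molecules) {
  if (!is.data.frame(molecules) || !nrow(molecules))
    stop("'molecules' must be a non-empty molecule table")
  stopifnot(all(c("molecule_id", "smiles") %in% names(molecules)))
  invisible(molecules)
}

molBlock <- function(molecules, task, blockName, args = character()) {
  checkMolecules(molecules)
  df <- runMolBackend(task, molecules$molecule_id, molecules$smiles, args)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  FeatureBlock(m, blockName)
}

#' Molecular descriptor blocks
#'
#' The four molecular descriptor families used by the binding models,
#' all computed from isomeric SMILES with stereochemistry retained:
#'
#' * `physchemDescriptors()` — the backend's full 2D physicochemical
#'   descriptor list (~200 columns: MolWt, LogP, TPSA, counts, ...);
#'   columns with non-finite values are dropped with a warning.
#' * `morganFingerprint()` — hashed circular (Morgan) fingerprint,
#'   binary, `nBits` columns (default 2048) at `radius` 2, with
#'   chirality folded into the hash so enantiomer SMILES can receive
#'   different rows.
#' * `rdkitFingerprint()` — the backend's path-based fingerprint at its
#'   defaults (2048 bits).
#' * `maccsKeys()` — the 166 MACCS substructure keys (the backend's
#'   dummy leading bit is dropped).
#'
#' @param molecules molecule table (see [readMoleculeTable()]).
#' @param nBits fingerprint length (positive integer).
#' @param radius Morgan radius (non-negative integer).
#' @return a [FeatureBlock-class] with one row per molecule.
#' @examples
#' \dontrun{
#' mols <- data.frame(molecule_id = "ethanol", smiles = "CCO")
#' dim(morganFingerprint(mols))   # 1 x 2048
#' dim(maccsKeys(mols))           # 1 x 166
#' }
#' @export
physchemDescriptors <- function(molecules) {
  molBlock(molecules, "physchem", "physchem")
}

#' @rdname physchemDescriptors
#' @export
morganFingerprint <- function(molecules, nBits = 2048L, radius = 2L) {
  if (length(nBits) != 1L || nBits <= 0) stop("nBits must be a positive integer")
  if (length(radius) != 1L || radius < 0) stop("radius must be non-negative")
  molBlock(molecules, "morgan", "morgan",
           c("--n-bits", as.integer(nBits), "--radius", as.integer(radius)))
}

#' @rdname physchemDescriptors
#' @export
rdkitFingerprint <- function(molecules) {
  molBlock(molecules, "rdkitfp", "rdkit")
}

#' @rdname physchemDescriptors
#' @export
maccsKeys <- function(molecules) {
  molBlock(molecules, "maccs", "maccs")
}

#' Compute a molecular descriptor block by name
#'
#' @param molecules molecule table.
#' @param variant one of `"physchem"`, `"morgan"`, `"rdkit"`, `"maccs"`.
#' @return a [FeatureBlock-class]
#' @export
featurizeMolecules <- function(molecules,
                               variant = c("morgan", "physchem", "rdkit", "maccs")) {
  variant <- match.arg(variant)
  switch(variant,
         physchem = physchemDescriptors(molecules),
         morgan   = morganFingerprint(molecules),
         rdkit    = rdkitFingerprint(molecules),
         maccs    = maccsKeys(molecules))
}
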