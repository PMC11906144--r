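#' Binarize a log(EC50) value into a binding label
#'
#' The binding tables encode "no binding" as a log(EC50) of exactly 0;
#' any strictly positive value is a measured binder. Negative values are
#' invalid under this encoding and rejected.
#'
#' @param log_ec50 numeric vector of non-negative log(EC50) values.
#' @return character vector, `"positive"` where `log_ec50 > 0`,
#'   `"negative"` where it equals 0.
#' @examples
#' binarizeEc50(c(0, 4.2, 1e-12))
#' @export
binarizeEc50 <- function(log_ec50) {
  if (!is.numeric(log_ec50)) stop("log_ec50 must be numeric")
  if (any(is.na(log_ec50))) stop("log_ec50 must not contain NA")
  if (any(log_ec50 < 0))
    stop("negative log(EC50) found; the encoding reserves 0 for non-binding ",
         "and admits no negative values")
  ifelse(log_ec50 > 0, "positive", "negative")
}

normalizeOdorLabels <- function(raw) {
  lapply(strsplit(as.character(raw), ";", fixed = TRUE), function(tok) {
    tok <- tolower(trimws(tok))
    unique(tok[nzchar(tok)])
  })
}

#' Read a molecule table
#'
#' CSV with columns `molecule_id`, `smiles` (isomeric SMILES) and
#' `odor_labels` (';'-separated free-text odor notes, possibly empty).
#' Labels are trimmed, case-folded and de-duplicated; no synonym merging
#' is performed (relatedness is handled downstream by odor communities).
#' With `validate = TRUE`, every SMILES is parsed by the cheminformatics
#' backend and rows that fail are reported together by molecule id.
#'
#' @param path CSV file path.
#' @param validate check SMILES parseability (requires the Python/RDKit
#'   backend; see the package README).
#' @return data.frame with columns `molecule_id`, `smiles` and a
#'   list-column `odor_labels`.
#' @export
readMoleculeTable <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("molecule_id", "smiles", "odor_labels")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("molecule table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$molecule_id))
    stop("duplicate molecule_id: ",
         paste(unique(df$molecule_id[duplicated(df$molecule_id)]), collapse = ", "))
  out <- data.frame(molecule_id = df$molecule_id, smiles = df$smiles,
                    stringsAsFactors = FALSE)
  out$odor_labels <- normalizeOdorLabels(df$odor_labels)
  if (validate) {
    v <- validateSmiles(out$smiles, out$molecule_id)
    if (any(!v$ok))
      stop("unparsable SMILES for molecule(s): ",
           paste(v$molecule_id[!v$ok], collapse = ", "))
  }
  out
}

#' @rdname readMoleculeTable
#' @param molecules data.frame as returned by `readMoleculeTable`.
#' @export
writeMoleculeTable <- function(molecules, path) {
  df <- data.frame(
    molecule_id = molecules$molecule_id,
    smiles = molecules$smiles,
    odor_labels = vapply(molecules$odor_labels, paste, "", collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a receptor panel from FASTA
#'
#' Sequences must use the 20-letter canonical amino-acid alphabet.
#' A species tag (`mouse`, `human` or `unknown`) is read from the second
#' '|'-separated field of each FASTA header when present; it is metadata
#' only and never enters featurization.
#'
#' @param path FASTA file.
#' @return [Biostrings::AAStringSet] named by receptor id, with a
#'   `species` column in `S4Vectors::mcols()`.
#' @export
readReceptorFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  ids <- trimws(vapply(strsplit(ids, "\\s+"), `[[`, "", 1))
  if (anyDuplicated(ids))
    stop("duplicate receptor_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  species <- vapply(parts, function(p)
    if (length(p) >= 2 && tolower(trimws(p[2])) %in% c("mouse", "human"))
      tolower(trimws(p[2])) else "unknown", "")
  names(seqs) <- ids
  S4Vectors::mcols(seqs)$species <- species
  if (any(Biostrings::width(seqs) == 0)) stop("empty receptor sequence")
  checkCanonicalAA(as.character(seqs), ids)
  seqs
}

checkCanonicalAA <- function(seqchars, ids, allowGap = FALSE) {
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], if (allowGap) "-")
  for (i in seq_along(seqchars)) {
    ch <- strsplit(seqchars[[i]], "")[[1]]
    bad <- which(!ch %in% alphabet)
    if (length(bad))
      stop(sprintf("non-canonical residue '%s' at position %d in sequence '%s'",
                   ch[bad[1]], bad[1], ids[i]))
  }
  invisible(TRUE)
}

#' Read a pre-computed multiple alignment of the receptor panel
#'
#' Aligned FASTA with '-' gaps; all sequences must share one width.
#' Computing the alignment is out of scope here: tools such as MAFFT
#' produce the input.
#'
#' @param path aligned FASTA file.
#' @return [Biostrings::AAStringSet] of equal-width gapped sequences.
#' @export
readAlignedFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "[| ]"), `[[`, "", 1)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("aligned sequences have unequal lengths: ",
         paste(utils::head(paste0(names(seqs), "=", w), 4), collapse = ", "))
  chars <- as.character(seqs)
  if (any(vapply(chars, function(s) all(strsplit(s, "")[[1]] == "-"), TRUE)))
    stop("alignment contains an all-gap sequence")
  checkCanonicalAA(chars, names(seqs), allowGap = TRUE)
  seqs
}

#' Read a binding table against known molecules and receptors
#'
#' CSV with columns `molecule_id`, `receptor_id`, `log_ec50`. Every id
#' must reference a known molecule/receptor; log(EC50) must be
#' non-negative (0 encodes non-binding). The derived binary label is
#' attached, and the fraction of the full molecule-by-receptor grid that
#' is present is reported as attribute `"coverage"`.
#'
#' @param path CSV file.
#' @param molecules molecule table (see [readMoleculeTable()]).
#' @param receptors receptor panel (see [readReceptorFasta()]).
#' @return data.frame `molecule_id, receptor_id, log_ec50, label` with
#'   attribute `coverage`.
#' @export
readBindingTable <- function(path, molecules, receptors) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "receptor_id", "log_ec50")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("binding table is missing column(s): ", paste(miss, collapse = ", "))
  df$log_ec50 <- as.numeric(df$log_ec50)
  bindingSamples(df, molecules, receptors)
}

#' @rdname readBindingTable
#' @param df in-memory data.frame with the binding-table columns.
#' @export
bindingSamples <- function(df, molecules, receptors) {
  unknownMol <- setdiff(df$molecule_id, molecules$molecule_id)
  if (length(unknownMol))
    stop("unknown molecule_id in binding table: ",
         paste(utils::head(unknownMol, 5), collapse = ", "))
  unknownRec <- setdiff(df$receptor_id, names(receptors))
  if (length(unknownRec))
    stop("unknown receptor_id in binding table: ",
         paste(utils::head(unknownRec, 5), collapse = ", "))
  if (anyDuplicated(df[c("molecule_id", "receptor_id")]))
    stop("duplicate (molecule_id, receptor_id) pair in binding table")
  out <- data.frame(molecule_id = df$molecule_id, receptor_id = df$receptor_id,
                    log_ec50 = df$log_ec50, stringsAsFactors = FALSE)
  out$label <- binarizeEc50(out$log_ec50)
  attr(out, "coverage") <-
    nrow(out) / (nrow(molecules) * length(receptors))
  out
}

#' @rdname readBindingTable
#' @param samples binding samples data.frame.
#' @export
writeBindingTable <- function(samples, path) {
  utils::write.csv(samples[c("molecule_id", "receptor_id", "log_ec50")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Assemble per-molecule receptor activation profiles
#'
#' Turns a complete molecule-by-receptor binding grid into one activation
#' profile per molecule: the ordered vector of log(EC50) over the fixed
#' receptor panel (0 where the molecule does not bind). An incomplete
#' grid is an error — an unmeasured pair must not be conflated with a
#' measured non-binder.
#'
#' @param samples binding samples (see [readBindingTable()]).
#' @param panel ordered receptor ids fixing the profile column order.
#' @return numeric matrix, molecules x receptors, colnames in panel order.
#' @export
buildProfiles <- function(samples, panel) {
  if (anyDuplicated(panel)) stop("panel ids must be unique")
  samples <- samples[samples$receptor_id %in% panel, , drop = FALSE]
  mols <- unique(samples$molecule_id)
  prof <- matrix(NA_real_, nrow = length(mols), ncol = length(panel),
                 dimnames = list(mols, panel))
  prof[cbind(match(samples$molecule_id, mols),
             match(samples$receptor_id, panel))] <- samples$log_ec50
  if (anyNA(prof)) {
    idx <- which(is.na(prof), arr.ind = TRUE)
    miss <- paste0("(", rownames(prof)[idx[, 1]], ", ", colnames(prof)[idx[, 2]], ")")
    stop("incomplete binding grid; missing pair(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" and %d more", length(miss) - 5) else "")
  }
  prof
}
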