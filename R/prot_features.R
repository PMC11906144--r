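AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' k-mer vocabulary over the canonical amino-acid alphabet
#'
#' All `20^k` k-mers in lexicographic order; the fixed column vocabulary
#' of the kAAF descriptor blocks, identical across receptor panels and
#' at train/predict time.
#'
#' @param k k-mer length (1, 2 or 3 in practice).
#' @return character vector of length `20^k`.
#' @export
kmerVocabulary <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  out <- AA_ALPHABET
  if (k > 1) for (i in 2:k)
    out <- as.vector(t(outer(out, AA_ALPHABET, paste0)))
  out
}

seqToIndices <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("non-canonical residue '%s' at position %d", ch[p], p))
  }
  idx
}

#' Overlapping k-mer counts of an amino-acid sequence (kAAF)
#'
#' Counts every length-`k` window of the sequence over the full `20^k`
#' vocabulary: k = 1 is plain amino-acid composition (1AAF), k = 2 counts
#' adjacent pairs (2AAF), k = 3 consecutive triples (3AAF). The counts
#' always sum to `nchar(sequence) - k + 1`.
#'
#' @param sequence amino-acid string over the 20-letter canonical alphabet.
#' @param k window length; must not exceed the sequence length.
#' @return named integer (counts) or numeric (proportions) vector of
#'   length `20^k` in the [kmerVocabulary()] order.
#' @examples
#' kmerCounts("AAG", 2)[c("AA", "AG")]
#' sum(kmerProportions("AAG", 1))  # 1
#' @export
kmerCounts <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  L <- nchar(sequence)
  if (L < k) stop(sprintf("sequence of length %d is shorter than k = %d", L, k))
  idx0 <- seqToIndices(sequence) - 1L
  nwin <- L - k + 1L
  code <- integer(nwin)          # base-20 code of each window, 0-based
  for (j in seq_len(k))
    code <- code + idx0[j:(j + nwin - 1L)] * 20L^(k - j)
  counts <- tabulate(code + 1L, nbins = 20L^k)
  names(counts) <- kmerVocabulary(k)
  counts
}

#' @rdname kmerCounts
#' @export
kmerProportions <- function(sequence, k) {
  counts <- kmerCounts(sequence, k)
  counts / sum(counts)
}

#' One-hot encoding of a receptor multiple alignment
#'
#' Each receptor row is the concatenation, over alignment positions, of
#' a 21-symbol indicator (20 amino acids plus the gap '-'): the
#' two-dimensional residue-by-position matrix of the alignment
#' rearranged into one dimension. Exactly one slot per position block
#' is 1.
#'
#' @param alignment equal-width gapped [Biostrings::AAStringSet]
#'   (see [readAlignedFasta()]).
#' @return a [FeatureBlock-class] of dimension
#'   `n_receptors x (alignment_width * 21)`.
#' @export
alignmentOneHot <- function(alignment) {
  chars <- as.character(alignment)
  w <- unique(nchar(chars))
  if (length(w) != 1L)
    stop("aligned sequences have unequal lengths")
  symbols <- c(AA_ALPHABET, "-")
  nSym <- length(symbols)
  m <- matrix(0, nrow = length(chars), ncol = w * nSym,
              dimnames = list(names(alignment),
                              paste0("pos", rep(seq_len(w), each = nSym), "_",
                                     rep(symbols, w))))
  for (i in seq_along(chars)) {
    ch <- strsplit(chars[[i]], "")[[1]]
    sym <- match(ch, symbols)
    if (anyNA(sym)) {
      p <- which(is.na(sym))[1]
      stop(sprintf("unknown symbol '%s' at alignment position %d in '%s'",
                   ch[p], p, names(alignment)[i]))
    }
    m[i, (seq_len(w) - 1L) * nSym + sym] <- 1
  }
  FeatureBlock(m, "alignment")
}

#' Receptor descriptor blocks
#'
#' The six k-mer amino-acid-frequency variants (counts `1AAF`/`2AAF`/
#' `3AAF` and proportions `1AAFperc`/`2AAFperc`/`3AAFperc`) and the
#' flattened alignment one-hot. Proportion variants are emitted on the
#' `[0, 1]` scale (each row sums to 1); set `percentScale = TRUE` for
#' 0–100.
#'
#' @param receptors [Biostrings::AAStringSet] of receptor sequences.
#' @param variant descriptor variant name.
#' @param alignment equal-width gapped [Biostrings::AAStringSet];
#'   required for (and only for) `variant = "alignment"`, and must cover
#'   every receptor.
#' @param percentScale emit proportion variants as percentages (0–100).
#' @return a [FeatureBlock-class] with one row per receptor.
#' @examples
#' \dontrun{
#' recs <- Biostrings::AAStringSet(c(r1 = "ACDE", r2 = "AACD"))
#' dim(featurizeReceptors(recs, "1AAF"))  # 2 x 20
#' }
#' @export
featurizeReceptors <- function(receptors,
    variant = c("1AAF", "2AAF", "3AAF", "1AAFperc", "2AAFperc", "3AAFperc",
                "alignment"),
    alignment = NULL, percentScale = FALSE) {
  variant <- match.arg(variant)
  if (variant == "alignment") {
    if (is.null(alignment))
      stop("variant 'alignment' requires a pre-computed multiple alignment")
    miss <- setdiff(names(receptors), names(alignment))
    if (length(miss))
      stop("alignment does not cover receptor(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    return(alignmentOneHot(alignment[names(receptors)]))
  }
  k <- as.integer(substr(variant, 1, 1))
  perc <- grepl("perc$", variant)
  fn <- if (perc) kmerProportions else kmerCounts
  rows <- t(vapply(as.character(receptors), fn, numeric(20^k), k = k))
  rownames(rows) <- names(receptors)
  if (perc && percentScale) rows <- rows * 100
  FeatureBlock(rows, variant)
}
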