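#' Construct a FeatureBlock, pruning non-finite columns
#'
#' Columns containing any non-finite value (NA/NaN/Inf) are dropped with
#' a warning before construction, so downstream models never see missing
#' descriptors.
#'
#' @param values numeric matrix with row and column names.
#' @param blockName descriptor-family name.
#' @return a [FeatureBlock-class]
#' @export
FeatureBlock <- function(values, blockName) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  bad <- apply(values, 2, function(col) any(!is.finite(col)))
  if (any(bad)) {
    warning(sprintf("dropping %d feature column(s) with non-finite values from '%s': %s",
                    sum(bad), blockName,
                    paste(utils::head(colnames(values)[bad], 5), collapse = ", ")),
            call. = FALSE)
    values <- values[, !bad, drop = FALSE]
  }
  new("FeatureBlock", values = values, blockName = blockName)
}

#' Write / read a FeatureBlock as CSV
#'
#' Plain CSV with the entity identifier in the first column (`row_id`).
#'
#' @param x a [FeatureBlock-class]
#' @param path file path
#' @param blockName descriptor-family name to attach on read
#' @return `readFeatureBlock` returns a [FeatureBlock-class];
#'   `writeFeatureBlock` returns `path` invisibly.
#' @export
writeFeatureBlock <- function(x, path) {
  df <- data.frame(row_id = rowIds(x), featureMatrix(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureBlock
#' @export
readFeatureBlock <- function(path, blockName = "block") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  FeatureBlock(m, blockName)
}

# Derive a stream-specific 31-bit seed from a master seed and a label, so
# sub-generators (binding noise, label noise, fold shuffles, ...) draw from
# independent reproducible streams.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
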