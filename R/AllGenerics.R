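#' @rdname FeatureBlock-class
#' @param object,x a \code{FeatureBlock}
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureBlock-class
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))

#' @rdname FeatureBlock-class
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @rdname OdorGraph-class
#' @param x an \code{OdorGraph}
#' @param weighted logical; return co-annotation counts instead of 0/1
#' @export
setGeneric("adjacencyMatrix", function(x, weighted = FALSE)
  standardGeneric("adjacencyMatrix"))

#' @rdname OdorGraph-class
#' @export
setGeneric("edgeCount", function(x, weighted = FALSE) standardGeneric("edgeCount"))

#' @rdname OdorPartition-class
#' @param x an \code{OdorPartition}
#' @export
setGeneric("communityOf", function(x) standardGeneric("communityOf"))

#' @rdname OdorPartition-class
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname OdorPartition-class
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname UndersampleResult-class
#' @param x an \code{UndersampleResult}
#' @export
setGeneric("keptIndices", function(x) standardGeneric("keptIndices"))

#' @rdname CascadeModel-class
#' @param x a \code{CascadeModel}
#' @export
setGeneric("receptorPanel", function(x) standardGeneric("receptorPanel"))

#' @rdname CascadeModel-class
#' @export
setGeneric("odorPartition", function(x) standardGeneric("odorPartition"))

# ---- accessors -------------------------------------------------------------

#' @rdname FeatureBlock-class
#' @export
setMethod("featureMatrix", "FeatureBlock", function(x) x@values)

#' @rdname FeatureBlock-class
#' @export
setMethod("blockName", "FeatureBlock", function(x) x@blockName)

#' @rdname FeatureBlock-class
#' @export
setMethod("rowIds", "FeatureBlock", function(x) rownames(x@values))

#' @rdname FeatureBlock-class
#' @export
setMethod("dim", "FeatureBlock", function(x) dim(x@values))

#' @rdname OdorGraph-class
#' @export
setMethod("adjacencyMatrix", "OdorGraph", function(x, weighted = FALSE) {
  if (weighted) x@weights else (x@weights > 0) + 0L
})

#' @rdname OdorGraph-class
#' @export
setMethod("edgeCount", "OdorGraph", function(x, weighted = FALSE) {
  sum(adjacencyMatrix(x, weighted = weighted)) / 2
})

#' @rdname OdorPartition-class
#' @export
setMethod("communityOf", "OdorPartition", function(x) x@membership)

#' @rdname OdorPartition-class
#' @export
setMethod("nCommunities", "OdorPartition", function(x)
  length(unique(x@membership)))

#' @rdname OdorPartition-class
#' @export
setMethod("modularityQ", "OdorPartition", function(x) x@Q)

#' @rdname UndersampleResult-class
#' @export
setMethod("keptIndices", "UndersampleResult", function(x) x@keptIndices)

#' @rdname CascadeModel-class
#' @export
setMethod("receptorPanel", "CascadeModel", function(x) x@panel)

#' @rdname CascadeModel-class
#' @export
setMethod("odorPartition", "CascadeModel", function(x) x@partition)

# ---- show ------------------------------------------------------------------

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock '%s': %d x %d\n", object@blockName,
              nrow(object@values), ncol(object@values)))
  cat("  rows: ", paste(utils::head(rownames(object@values), 3), collapse = ", "),
      if (nrow(object@values) > 3) ", ..." else "", "\n", sep = "")
})

setMethod("show", "OdorGraph", function(object) {
  cat(sprintf("OdorGraph: %d odor labels, %d edges (total co-annotation weight %d)\n",
              nrow(object@weights), edgeCount(object),
              as.integer(edgeCount(object, weighted = TRUE))))
})

setMethod("show", "OdorPartition", function(object) {
  cat(sprintf("OdorPartition: %d labels in %d communities (Q = %s)\n",
              length(object@membership), nCommunities(object),
              format(object@Q, digits = 4)))
  print(table(community = object@membership))
})

setMethod("show", "UndersampleResult", function(object) {
  cat(sprintf("UndersampleResult: majority %d -> %d; %d samples kept\n",
              object@nMajorityBefore, object@nMajorityAfter,
              length(object@keptIndices)))
})

setMethod("show", "CascadeModel", function(object) {
  on3 <- vapply(object@model3, Negate(is.null), logical(1))
  cat("CascadeModel\n")
  cat(sprintf("  receptor panel : %d receptors\n", length(object@panel)))
  cat(sprintf("  Model 1 (bind) : %s\n", object@model1$method))
  cat(sprintf("  Model 2 (EC50) : %s\n", object@model2$method))
  cat(sprintf("  Model 3 (odor) : %d/%d community classifiers (%s)\n",
              sum(on3), length(object@model3),
              paste(unique(vapply(object@model3[on3], `[[`, "", "method")),
                    collapse = ", ")))
  cat(sprintf("  odor partition : %d communities, Q = %s\n",
              nCommunities(object@partition),
              format(object@partition@Q, digits = 4)))
})
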