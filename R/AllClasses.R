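#' @import methods
NULL

#' FeatureBlock: a named descriptor matrix
#'
#' A rectangular block of numeric descriptors for a set of entities
#' (molecules or receptors). Rows are entities, columns are a fixed,
#' uniquely named feature vocabulary; the block carries a name recording
#' which descriptor family it holds (e.g. \code{"morgan"}, \code{"1AAF"}).
#'
#' @slot values numeric matrix; rownames are entity identifiers, colnames
#'   the feature vocabulary.
#' @slot blockName single character, the descriptor family.
#'
#' @seealso [morganFingerprint()], [featurizeReceptors()], [joinFeatures()]
#' @export
setClass("FeatureBlock",
  representation(values = "matrix", blockName = "character"))

setValidity("FeatureBlock", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@blockName) != 1L) msg <- c(msg, "blockName must be a single string")
  if (is.null(rownames(v))) msg <- c(msg, "values must have rownames (entity ids)")
  if (is.null(colnames(v))) msg <- c(msg, "values must have colnames (feature names)")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "feature names must be unique")
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.numeric(v) && any(!is.finite(v)))
    msg <- c(msg, "values must be finite (non-finite columns are dropped at construction)")
  if (length(msg)) msg else TRUE
})

#' OdorGraph: odor-label co-annotation graph
#'
#' Undirected graph whose nodes are odor labels; two labels are joined by
#' an edge when at least one molecule is annotated with both, with edge
#' weight the number of such co-annotating molecules. Stored as a
#' symmetric integer weight matrix with a zero diagonal.
#'
#' @slot weights symmetric integer matrix of co-annotation counts;
#'   dimnames are the odor labels; diagonal is zero.
#'
#' @seealso [buildOdorGraph()], [graphModularity()], [greedyModularityPartition()]
#' @export
setClass("OdorGraph", representation(weights = "matrix"))

setValidity("OdorGraph", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weight matrix must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "weight matrix must have matching dimnames (odor labels)")
  if (!isTRUE(all.equal(w, t(w)))) msg <- c(msg, "weight matrix must be symmetric")
  if (any(diag(w) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' OdorPartition: a community assignment of odor labels
#'
#' @slot membership named integer vector mapping each odor label to a
#'   community index in \code{1..nCommunities}; communities are numbered
#'   by descending size.
#' @slot Q modularity of this partition on the graph it was computed from
#'   (\code{NA} when constructed without a graph).
#'
#' @seealso [greedyModularityPartition()], [assignMoleculeCommunities()]
#' @export
setClass("OdorPartition",
  representation(membership = "integer", Q = "numeric"))

setValidity("OdorPartition", function(object) {
  m <- object@membership
  msg <- character()
  if (is.null(names(m))) msg <- c(msg, "membership must be named by odor label")
  if (length(m) && (any(is.na(m)) || any(m < 1L)))
    msg <- c(msg, "membership must be positive integers")
  if (length(object@Q) != 1L) msg <- c(msg, "Q must be a single numeric")
  if (!is.na(object@Q) && (object@Q < -1 - 1e-9 || object@Q > 1 + 1e-9))
    msg <- c(msg, "Q must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' UndersampleResult: outcome of clustering undersampling
#'
#' @slot keptIndices integer indices (into the original sample list) that
#'   survive undersampling: all minority samples plus one k-means++
#'   cluster representative per majority cluster.
#' @slot nMajorityBefore,nMajorityAfter majority-class counts before and
#'   after reduction.
#' @slot clusterAssignments integer cluster index for each original
#'   majority sample (in original order).
#'
#' @seealso [clusterUndersample()]
#' @export
setClass("UndersampleResult",
  representation(keptIndices = "integer", nMajorityBefore = "integer",
                 nMajorityAfter = "integer", clusterAssignments = "integer"))

setValidity("UndersampleResult", function(object) {
  msg <- character()
  if (object@nMajorityAfter > object@nMajorityBefore)
    msg <- c(msg, "undersampling cannot increase the majority class")
  if (anyDuplicated(object@keptIndices)) msg <- c(msg, "keptIndices must be unique")
  if (length(msg)) msg else TRUE
})

#' CascadeModel: the trained three-model odor-prediction cascade
#'
#' Bundles the binding classifier (Model 1), the binding-strength
#' regressor (Model 2), the per-community odor classifiers (Model 3),
#' the fixed receptor panel order, the odor partition used at training,
#' and the featurization configuration needed to reproduce feature
#' columns exactly at predict time.
#'
#' @slot model1,model2 fitted-method wrappers (list with the method name,
#'   fit object and chosen hyperparameters).
#' @slot model3 named list of fitted-method wrappers, one per odor
#'   community; a community with too few positive molecules is stored as
#'   \code{NULL} (reported as "not assessed" at predict time).
#' @slot panel ordered receptor identifiers; profile columns follow this
#'   order everywhere.
#' @slot config cascade configuration (see [cascadeConfig()]).
#' @slot partition [OdorPartition-class] built from the training molecules.
#' @slot training list of nested-CV summaries and featurization state
#'   (receptor feature rows, descriptor column vocabularies, dropped
#'   columns) captured at training time.
#'
#' @seealso [trainCascade()], [predictOdor()]
#' @export
setClass("CascadeModel",
  representation(model1 = "list", model2 = "list", model3 = "list",
                 panel = "character", config = "list",
                 partition = "OdorPartition", training = "list"))

setValidity("CascadeModel", function(object) {
  if (!length(object@panel)) return("receptor panel must be non-empty")
  if (anyDuplicated(object@panel)) return("receptor panel ids must be unique")
  TRUE
})
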