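#' Build the odor-label co-annotation graph
#'
#' Nodes are the distinct odor labels carried by the molecules; two
#' labels are connected iff at least one molecule is annotated with
#' both, with edge weight the number of such molecules. Labels that are
#' never co-annotated become isolated nodes.
#'
#' @param molecules molecule table with an `odor_labels` list-column
#'   (see [readMoleculeTable()]); at least one molecule must carry a label.
#' @return an [OdorGraph-class]
#' @export
buildOdorGraph <- function(molecules) {
  labelSets <- molecules$odor_labels
  labelSets <- lapply(labelSets, unique)
  nodes <- sort(unique(unlist(labelSets)))
  if (!length(nodes)) stop("no odor labels present on any molecule")
  w <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (ls in labelSets) {
    if (length(ls) < 2) next
    idx <- match(ls, nodes)
    pairs <- utils::combn(sort(idx), 2)
    w[t(pairs)] <- w[t(pairs)] + 1L
  }
  w <- w + t(w)
  new("OdorGraph", weights = w)
}

membershipVector <- function(partition, nodes) {
  m <- if (is(partition, "OdorPartition")) communityOf(partition) else partition
  if (is.null(names(m))) stop("membership must be named by odor label")
  miss <- setdiff(nodes, names(m))
  if (length(miss))
    stop("partition does not cover node(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  m[nodes]
}

#' Modularity of a partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(C_i, C_j), with A
#' the 0/1 adjacency matrix, k the degrees and m the edge count. With
#' `weighted = TRUE` the co-annotation counts replace A and m becomes
#' the total weight (the standard weighted generalization); the default
#' follows the unweighted definition.
#'
#' @param graph an [OdorGraph-class] with at least one edge.
#' @param partition an [OdorPartition-class] or a named membership
#'   vector covering all nodes.
#' @param weighted use co-annotation weights instead of 0/1 adjacency.
#' @return modularity Q in `[-1, 1]`.
#' @examples
#' \dontrun{
#' g <- buildOdorGraph(mols)
#' graphModularity(g, greedyModularityPartition(g))
#' }
#' @export
graphModularity <- function(graph, partition, weighted = FALSE) {
  A <- adjacencyMatrix(graph, weighted = weighted)
  storage.mode(A) <- "double"
  twoM <- sum(A)
  if (twoM == 0) stop("modularity is undefined on an edgeless graph")
  memb <- membershipVector(partition, rownames(A))
  k <- rowSums(A)
  delta <- outer(memb, memb, "==")
  sum((A - outer(k, k) / twoM) * delta) / twoM
}

relabelBySize <- function(memb, nodes) {
  # communities numbered 1..n by descending size; ties by first member
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.vector(sizes[names(first)]), as.vector(first))
  newId <- integer(length(first))
  newId[ord] <- seq_along(ord)
  names(newId) <- names(first)
  out <- newId[as.character(memb)]
  names(out) <- nodes
  out
}

#' Greedy modularity maximization (agglomerative CNM scheme)
#'
#' Starts from singleton communities and repeatedly merges the community
#' pair with the largest modularity gain (among equal gains, the
#' lexicographically smallest community-id pair), stopping when no merge
#' improves Q. Isolated labels remain their own communities. The gain
#' bookkeeping works on community-level edge-weight and degree
#' aggregates: merging communities c and d changes Q by
#' `2 * (w_cd/2m - (k_c/2m)(k_d/2m))`.
#'
#' @param graph an [OdorGraph-class] with at least one edge.
#' @param weighted maximize the weighted modularity instead of the 0/1
#'   definition.
#' @param keepTrace attach an attribute `"trace"` with the incremental Q
#'   and the membership snapshot after every accepted merge (used to
#'   audit the bookkeeping against from-scratch recomputation).
#' @return an [OdorPartition-class]; communities are renumbered 1..n by
#'   descending size.
#' @export
greedyModularityPartition <- function(graph, weighted = FALSE, keepTrace = FALSE) {
  A <- adjacencyMatrix(graph, weighted = weighted)
  storage.mode(A) <- "double"
  nodes <- rownames(A)
  n <- length(nodes)
  twoM <- sum(A)
  if (twoM == 0) stop("community extraction is undefined on an edgeless graph")

  comm <- seq_len(n)              # community id of each node (id = smallest member)
  B <- A                          # between/within community weights (single count)
  kc <- rowSums(A)                # community degree sums
  active <- rep(TRUE, n)
  Qinc <- -sum(kc^2) / twoM^2     # singleton-partition modularity
  traceQ <- numeric(0); traceMemb <- list()

  repeat {
    act <- which(active)
    if (length(act) < 2) break
    Bact <- B[act, act, drop = FALSE]
    gain <- 2 * (Bact / twoM - outer(kc[act], kc[act]) / twoM^2)
    gain[lower.tri(gain, diag = TRUE)] <- -Inf
    gain[Bact == 0] <- -Inf       # only connected community pairs can gain
    best <- max(gain)
    if (best <= 1e-12) break
    cand <- which(gain >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- act[cand[1, 1]]; j <- act[cand[1, 2]]   # i < j by construction

    # merge j into i: within weight of the union is within(i) + within(j)
    # + cross(i,j); all other community pairs just pool their cross weights
    comm[comm == j] <- i
    newRow <- B[i, ] + B[j, ]
    newRow[i] <- B[i, i] + B[j, j] + B[i, j]
    B[i, ] <- newRow; B[, i] <- newRow
    B[j, ] <- 0; B[, j] <- 0
    kc[i] <- kc[i] + kc[j]; kc[j] <- 0
    active[j] <- FALSE
    Qinc <- Qinc + best
    if (keepTrace) {
      traceQ <- c(traceQ, Qinc)
      snap <- comm; names(snap) <- nodes
      traceMemb <- c(traceMemb, list(snap))
    }
  }

  memb <- relabelBySize(comm, nodes)
  part <- new("OdorPartition", membership = memb,
              Q = graphModularity(graph, memb, weighted = weighted))
  if (keepTrace) attr(part, "trace") <- list(Q = traceQ, membership = traceMemb)
  part
}

#' Assign a molecule's odor labels to communities (majority rule)
#'
#' Counts a molecule's labels per community and keeps every community
#' holding strictly more than `threshold` (default 20%) of them, so a
#' molecule with nine labels in one community and one stray label in
#' another is read as carrying only the majority community. If no
#' community clears the threshold (a perfect many-way tie), the largest
#' share wins, ties broken by the smallest community index. Labels
#' absent from the partition are skipped with a warning.
#'
#' @param molecules molecule table (or a single row of it).
#' @param partition an [OdorPartition-class].
#' @param threshold strict share threshold (default 0.2).
#' @return named list (by molecule_id) of integer community-index
#'   vectors; empty when a molecule has no recognized labels.
#' @export
assignMoleculeCommunities <- function(molecules, partition, threshold = 0.2) {
  memb <- communityOf(partition)
  out <- lapply(seq_len(nrow(molecules)), function(i) {
    labels <- molecules$odor_labels[[i]]
    known <- labels %in% names(memb)
    if (any(!known))
      warning(sprintf("molecule '%s': skipping label(s) not in partition: %s",
                      molecules$molecule_id[i],
                      paste(labels[!known], collapse = ", ")), call. = FALSE)
    labels <- labels[known]
    if (!length(labels)) {
      warning(sprintf("molecule '%s' has no recognized odor labels",
                      molecules$molecule_id[i]), call. = FALSE)
      return(integer(0))
    }
    shares <- table(memb[labels]) / length(labels)
    keep <- as.integer(names(shares)[shares > threshold])
    if (!length(keep)) {
      top <- max(shares)
      keep <- min(as.integer(names(shares)[shares >= top - 1e-12]))
    }
    sort(keep)
  })
  names(out) <- molecules$molecule_id
  out
}

#' Export a partition / graph to CSV
#'
#' `writePartition` writes two columns (`odor_label`, `community_index`);
#' `writeEdgeList` writes the co-annotation edges (`label_a`, `label_b`,
#' `weight`).
#'
#' @param partition an [OdorPartition-class]
#' @param graph an [OdorGraph-class]
#' @param path output CSV path
#' @export
writePartition <- function(partition, path) {
  memb <- communityOf(partition)
  utils::write.csv(data.frame(odor_label = names(memb),
                              community_index = as.integer(memb)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
writeEdgeList <- function(graph, path) {
  w <- graph@weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(label_a = rownames(w)[idx[, 1]],
                              label_b = colnames(w)[idx[, 2]],
                              weight = w[idx]),
                   path, row.names = FALSE)
  invisible(path)
}
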