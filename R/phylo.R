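#' Identity-derived distance matrix
#'
#' Converts an all-against-all percent-identity matrix into the distance
#' matrix used for average-distance tree building: `d = 100 - identity`,
#' clipped to `[0, 100]`, zero diagonal.
#'
#' @param identity symmetric numeric matrix of identities with labels.
#' @return symmetric distance matrix (same labels).
#' @export
distances_from_identity <- function(identity) {
  stopifnot(is.matrix(identity), nrow(identity) == ncol(identity))
  if (max(abs(identity - t(identity))) > 1e-8)
    stop("identity matrix is not symmetric")
  d <- pmin(pmax(100 - identity, 0), 100)
  diag(d) <- 0
  d
}

#' Average-distance (UPGMA) tree
#'
#' Classic unweighted pair-group agglomeration with arithmetic means:
#' repeatedly merge the pair of clusters at minimal distance, at height
#' `dmin / 2`; distances from the merged cluster are size-weighted means.
#' Ties are broken by the smallest (row, column) index pair in the current
#' label order, so the result is deterministic. The output is ultrametric
#' by construction (average linkage is monotone).
#'
#' @param d symmetric distance matrix with zero diagonal, at least two
#'   labelled rows.
#' @return an object of class `upgma_tree`: a list with hclust-style
#'   `merge` and `height` (cophenetic heights, i.e. `2 x` merge height),
#'   `node_height` (merge heights), `labels` and `order`.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(d)) # ((A:1,B:1):3,C:4);
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2) stop("upgma: need at least 2 labels")
  if (max(abs(d - t(d))) > 1e-8) stop("upgma: matrix is not symmetric")
  if (any(!is.finite(d)) || any(d < 0))
    stop("upgma: distances must be finite and non-negative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters: id (<0 leaf, >0 internal node), size
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minleaf <- seq_len(n)   # smallest original leaf index in each cluster
  cur <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(ids)
    best <- c(NA_integer_, NA_integer_); dmin <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        if (cur[i, j] < dmin) { dmin <- cur[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    # child with the smallest original leaf index first (stable output)
    merge[step, ] <- if (minleaf[i] <= minleaf[j]) c(ids[i], ids[j]) else
      c(ids[j], ids[i])
    height[step] <- dmin
    # size-weighted mean distances to the merged cluster
    newd <- (sizes[i] * cur[i, ] + sizes[j] * cur[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    minleaf <- c(minleaf[keep], min(minleaf[i], minleaf[j]))
  }
  order <- leaf_order(merge, n)
  structure(list(merge = merge, height = height, node_height = height / 2,
                 labels = labels, order = order),
            class = "upgma_tree")
}

leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  as.integer(expand(n - 1L))
}

as_hclust <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  structure(list(merge = tree$merge, height = tree$height,
                 order = tree$order, labels = tree$labels,
                 method = "upgma", call = NULL, dist.method = "identity"),
            class = "hclust")
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' Branch lengths are differences of merge heights, so cophenetic path
#' lengths between leaves equal the input distances reconstructed by the
#' clustering (`2 x` merge height of the connecting node).
#'
#' @param tree an `upgma_tree`.
#' @return an [ape::phylo] object.
#' @export
as_phylo <- function(tree) {
  ape::as.phylo(as_hclust(tree))
}

#' Serialise a UPGMA tree as Newick
#'
#' @param tree an `upgma_tree`.
#' @return a Newick string terminated by `";"`.
#' @export
to_newick <- function(tree) {
  ape::write.tree(as_phylo(tree))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree with", length(x$labels), "leaves; root height",
      format(max(x$node_height)), "\n")
  invisible(x)
}

#' Cut a UPGMA tree into flat clusters
#'
#' Leaves connected through merges strictly below height `h` (in merge
#' height units, i.e. half-cophenetic distance) form one cluster. `h = 0`
#' yields singletons.
#'
#' @param tree an `upgma_tree`.
#' @param h non-negative cut height.
#' @return list of character vectors partitioning the leaf labels, ordered
#'   by first leaf appearance.
#' @export
cut_clusters <- function(tree, h) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (h < 0) stop("cut_clusters: negative height")
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(tree$merge[node, 1]), members(tree$merge[node, 2]))
  }
  for (step in seq_len(n - 1)) {
    if (tree$node_height[step] < h) {
      leaves <- members(step)
      r <- find(leaves[1])
      for (l in leaves[-1]) parent[find(l)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(tree$labels, factor(roots, levels = unique(roots)))
}

#' Cophenetic distances of a UPGMA tree
#'
#' @param tree an `upgma_tree`.
#' @return symmetric matrix of leaf-to-leaf path lengths (twice the merge
#'   height of the connecting node), labelled and in input label order.
#' @export
cophenetic_distances <- function(tree) {
  ph <- as_phylo(tree)
  m <- stats::cophenetic(ph)
  m[tree$labels, tree$labels]
}

#' Random ultrametric distance matrix
#'
#' Simulation utility: builds a random rooted ultrametric tree over `n`
#' leaves (random merge order, strictly increasing merge heights) and
#' returns its cophenetic distance matrix. UPGMA reconstructs such a
#' matrix exactly, which makes this the natural correctness probe for
#' average-distance clustering.
#'
#' @param n number of leaves (>= 2).
#' @param max_height largest merge height (default 50).
#' @return symmetric ultrametric matrix with labels `L1..Ln`.
#' @export
random_ultrametric_matrix <- function(n, max_height = 50) {
  stopifnot(n >= 2)
  heights <- sort(runif(n - 1, min = 1e-3, max = max_height))
  groups <- as.list(seq_len(n))
  d <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    pick <- sample.int(length(groups), 2)
    a <- groups[[pick[1]]]; b <- groups[[pick[2]]]
    d[a, b] <- d[b, a] <- 2 * heights[step]
    groups[[pick[1]]] <- c(a, b)
    groups[[pick[2]]] <- NULL
  }
  labs <- paste0("L", seq_len(n))
  dimnames(d) <- list(labs, labs)
  d
}
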