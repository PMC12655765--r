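# Similarity -> distance -> Ward.D2 tree -> inertia-based cluster count.

#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise complement `d = 1 - s` (the standard transform for
#' similarities bounded in `[0, 1]`: order-reversing, range-preserving),
#' with the diagonal forced to zero.
#'
#' @param S Symmetric numeric matrix with values in `[0, 1]`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10,
                        check.attributes = FALSE)))
    stop("similarity matrix must be symmetric")
  if (any(S < -1e-12 | S > 1 + 1e-12, na.rm = TRUE))
    stop("similarity values must lie in [0, 1]")
  D <- 1 - S
  diag(D) <- 0
  D
}

#' Ward.D2 agglomerative clustering
#'
#' Hierarchical agglomeration under the Ward criterion in its D2
#' convention (squared distances inside the objective, merge heights
#' reported on the distance scale), as implemented by [stats::hclust()].
#'
#' @param D Symmetric distance matrix (zero diagonal) or a `dist` object,
#'   n >= 2, no missing values.
#' @return An object of class `hclust`.
#' @export
ward_cluster <- function(D) {
  if (is.matrix(D)) {
    stopifnot(nrow(D) >= 2L)
    if (anyNA(D)) stop("distance matrix contains missing values")
    D <- stats::as.dist(D)
  }
  if (anyNA(D)) stop("distance matrix contains missing values")
  stats::hclust(D, method = "ward.D2")
}

#' Select the number of clusters by highest relative loss of inertia
#'
#' Let `h(k)` be the merge height traversed when the partition coarsens
#' from `k` to `k - 1` clusters (the k-th largest merge height). The
#' chosen `k` maximizes the regularized ratio
#' `(h(k) + eps) / (h(k + 1) + eps)` over `[k_min, k_max]`: the partition
#' just before the largest relative jump in merge cost. The additive
#' `eps` (1\% of the largest merge height) keeps the criterion from
#' firing on a negligible height that happens to sit above an exactly
#' zero one. Ties break toward the smallest `k`; a degenerate tree with
#' all merge heights equal returns `k_min` with a warning, and a two-leaf
#' tree returns 2.
#'
#' @param tree An `hclust` tree.
#' @param k_min,k_max Search range; `k_min < k_max <= n - 1`.
#' @return The selected number of clusters (integer).
#' @export
select_k_by_inertia <- function(tree, k_min = 2L, k_max = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (n == 2L) return(2L)
  if (is.null(k_max)) k_max <- n - 1L
  stopifnot(k_min >= 2L, k_min < k_max, k_max <= n - 1L)
  h <- tree$height                       # ascending, length n - 1
  if (diff(range(h)) < 1e-15 || max(h) <= 0) {
    warning("degenerate tree: all merge heights equal; returning k_min")
    return(as.integer(k_min))
  }
  eps <- 0.01 * max(h)
  height_at <- function(k) h[n - k + 1L]  # merge taking k -> k-1 clusters
  ks <- seq(k_min, k_max)
  ratio <- vapply(ks, function(k) {
    (height_at(k) + eps) / (height_at(k + 1L) + eps)
  }, numeric(1))
  as.integer(ks[which.max(ratio)])       # which.max takes first = smallest k
}

#' Cut a tree into k clusters
#'
#' Wraps [stats::cutree()] with stable label numbering: clusters are
#' numbered by the order in which their first member appears among the
#' tree's leaf ids.
#'
#' @param tree An `hclust` tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector (id -> cluster label in `1..k`).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) stop("'k' must lie in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  stats::setNames(match(raw, unique(raw)), names(raw))
}

#' Cophenetic correlation of a tree with its source distances
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair first joins);
#' measures how faithfully the dendrogram preserves the distance matrix.
#'
#' @param tree An `hclust` tree.
#' @param D The distance matrix (or `dist`) the tree was built from.
#' @return A correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, D) {
  stopifnot(inherits(tree, "hclust"))
  if (is.matrix(D)) D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (n < 3L) stop("cophenetic correlation needs at least 3 leaves")
  stats::cor(as.vector(D), as.vector(stats::cophenetic(tree)))
}

#' Export a tree as Newick text
#'
#' Ultrametric Newick with branch lengths taken from the merge heights:
#' each branch length is the parent's merge height minus the child's
#' (leaves sit at height 0), so two leaves merging at height `h` yield
#' `(a:h,b:h);`.
#'
#' @param tree An `hclust` tree.
#' @param path Optional file to write the string to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
export_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  node_str <- function(i, parent_h) {
    if (i < 0) {                              # leaf (hclust convention)
      sprintf("%s:%s", tree$labels[-i], fmt(parent_h))
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[i, 1], h), node_str(tree$merge[i, 2], h),
              fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  s <- sprintf("(%s,%s);",
               node_str(tree$merge[root, 1], h),
               node_str(tree$merge[root, 2], h))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Export a similarity matrix reordered by dendrogram leaf order
#'
#' The heatmap-ready artifact: rows and columns permuted to the tree's
#' leaf order.
#'
#' @param S Similarity matrix whose dimnames match the tree labels.
#' @param tree An `hclust` tree over the same ids.
#' @param path Optional TSV output path.
#' @return The reordered matrix (invisibly if written).
#' @export
export_ordered_matrix <- function(S, tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"),
            setequal(rownames(S), tree$labels))
  ord <- tree$labels[tree$order]
  out <- S[ord, ord]
  if (!is.null(path)) {
    write_matrix_tsv(out, path, id_col = "drug_id")
    return(invisible(out))
  }
  out
}
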