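# Set-similarity coefficients on per-drug target sets.
#
# The B-index is the package's central statistic: for two non-empty sets
# it weights the shared elements by the reciprocal size of each set,
#   B(x, y) = 1/2 * |intersection| * (1/|x| + 1/|y|),
# so an overlap counts for more when it comes out of a small set. By the
# AM-HM inequality B >= Dice, with equality only for equally sized sets,
# and the chain russell_rao <= jaccard <= dice <= b_index holds for all
# set pairs within a universe.

as_set <- function(x) unique(as.character(x))

#' B-index set similarity
#'
#' \eqn{B(x, y) = \tfrac{1}{2}|x \cap y|\,(1/|x| + 1/|y|)}: the mean of
#' the two conditional overlap proportions. Ranges from 0 (disjoint) to 1,
#' attained iff `x == y`. By convention any comparison involving an empty
#' set returns 0 (the index is defined for non-empty sets).
#'
#' @param x,y Vectors interpreted as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' b_index(letters[1:4], letters[3:11])   # sizes 4 and 9, sharing 2
#' @export
b_index <- function(x, y) {
  x <- as_set(x); y <- as_set(y)
  i <- length(intersect(x, y))
  if (i == 0L) return(0)
  0.5 * i * (1 / length(x) + 1 / length(y))
}

#' Jaccard set similarity
#'
#' \eqn{|x \cap y| / |x \cup y|}; 0 by convention when both sets are
#' empty.
#'
#' @inheritParams b_index
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(x, y) {
  x <- as_set(x); y <- as_set(y)
  u <- length(union(x, y))
  if (u == 0L) return(0)
  length(intersect(x, y)) / u
}

#' Sorensen-Dice set similarity
#'
#' \eqn{2|x \cap y| / (|x| + |y|)}; 0 by convention when both sets are
#' empty.
#'
#' @inheritParams b_index
#' @return A number in `[0, 1]`.
#' @export
dice <- function(x, y) {
  x <- as_set(x); y <- as_set(y)
  s <- length(x) + length(y)
  if (s == 0L) return(0)
  2 * length(intersect(x, y)) / s
}

#' Russell-Rao similarity
#'
#' \eqn{|x \cap y| / |U|} for an explicit attribute universe `U`; the
#' most conservative member of the coefficient chain.
#'
#' @inheritParams b_index
#' @param universe Non-empty superset of both `x` and `y`.
#' @return A number in `[0, 1]`.
#' @export
russell_rao <- function(x, y, universe) {
  x <- as_set(x); y <- as_set(y); universe <- as_set(universe)
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  if (!all(x %in% universe) || !all(y %in% universe))
    stop("both sets must be subsets of 'universe'")
  length(intersect(x, y)) / length(universe)
}

#' Pairwise drug-drug similarity matrix
#'
#' Builds the symmetric drug x drug matrix of a chosen set-similarity
#' coefficient over a target-set map. Drugs with empty target sets are
#' dropped with a warning (the coefficients are defined on non-empty
#' sets); the diagonal is 1.
#'
#' @param sets Named list: drug id -> character vector of gene ids.
#' @param index One of `"b_index"`, `"jaccard"`, `"dice"`,
#'   `"russell_rao"`.
#' @param universe Gene universe, required for `"russell_rao"` (default:
#'   the union of all sets).
#' @return Symmetric numeric matrix with drug ids as dimnames and
#'   attribute `"index_name"`.
#' @export
pairwise_similarity <- function(sets,
                                index = c("b_index", "jaccard", "dice",
                                          "russell_rao"),
                                universe = NULL) {
  index <- match.arg(index)
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  empty <- lengths(lapply(sets, as_set)) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d drug(s) with empty target sets: %s",
                    sum(empty),
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no drugs with non-empty target sets")
  if (is.null(universe)) universe <- unique(unlist(sets))
  f <- switch(index,
              b_index = b_index, jaccard = jaccard, dice = dice,
              russell_rao = function(x, y) russell_rao(x, y, universe))
  ids <- names(sets)
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L))
      for (j in seq((i + 1L), length(ids))) {
        m[i, j] <- m[j, i] <- f(sets[[i]], sets[[j]])
      }
  }
  attr(m, "index_name") <- index
  m
}

#' Per-pair similarity report
#'
#' One row per unordered drug pair with set sizes, shared-target count and
#' the B-index, Jaccard and Sorensen-Dice coefficients. Unlike
#' [pairwise_similarity()], drugs with empty sets are kept (their
#' coefficients are 0 by convention) so the pair accounting covers all
#' `choose(n, 2)` pairs. The counts of pairs with and without shared
#' targets are attached as attribute `"summary"`.
#'
#' @param sets Named list: drug id -> character vector of gene ids.
#' @return A data.frame with columns `drug_a`, `drug_b`, `size_a`,
#'   `size_b`, `shared`, `b_index`, `jaccard`, `dice`.
#' @export
pair_report <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, as_set)
  ids <- names(sets)
  pairs <- utils::combn(length(ids), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    x <- sets[[ij[1]]]; y <- sets[[ij[2]]]
    data.frame(drug_a = ids[ij[1]], drug_b = ids[ij[2]],
               size_a = length(x), size_b = length(y),
               shared = length(intersect(x, y)),
               b_index = b_index(x, y), jaccard = jaccard(x, y),
               dice = dice(x, y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    n_pairs = nrow(out),
    n_shared_pos = sum(out$shared >= 1L),
    n_shared_zero = sum(out$shared == 0L))
  out
}

#' Write a pair report as TSV
#'
#' Coefficients are rounded to 3 decimals in the emitted table (full
#' precision is retained in the in-memory report); a comment footer
#' records the shared/disjoint pair counts.
#'
#' @param report Output of [pair_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_report <- function(report, path) {
  out <- report
  for (cl in c("b_index", "jaccard", "dice"))
    out[[cl]] <- round(out[[cl]], 3)
  write_tsv(out, path)
  s <- attr(report, "summary")
  cat(sprintf("# pairs=%d shared_ge1=%d shared_eq0=%d\n",
              s$n_pairs, s$n_shared_pos, s$n_shared_zero),
      file = path, append = TRUE)
  invisible(path)
}
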