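# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive reimplementation, kept separate from
# the package code paths it checks.

# Holm step-down, written out literally: sort, scale by (m - i + 1),
# running maximum, cap at 1, unsort.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, run)
  }
  adj
}

# Adjusted Rand index straight from the contingency-table formula.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(0)
  (sij - expected) / (maxi - expected)
}

# Cophenetic distance matrix rebuilt by walking the merge list.
cophenetic_oracle <- function(tree) {
  n <- length(tree$order)
  D <- matrix(0, n, n)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    grab <- function(ref) if (ref < 0) -ref else members[[ref]]
    left <- grab(tree$merge[i, 1])
    right <- grab(tree$merge[i, 2])
    for (l in left) for (r in right) D[l, r] <- D[r, l] <- tree$height[i]
    members[[i]] <- c(left, right)
  }
  dimnames(D) <- list(tree$labels, tree$labels)
  D
}

# Two sets with prescribed sizes and intersection, over disjoint symbols.
make_sets <- function(size_x, size_y, shared) {
  stopifnot(shared <= size_x, shared <= size_y)
  common <- sprintf("s%03d", seq_len(shared))
  x <- c(common, sprintf("x%03d", seq_len(size_x - shared)))
  y <- c(common, sprintf("y%03d", seq_len(size_y - shared)))
  list(x = x, y = y)
}

# Random subset of a universe (possibly empty unless min_size > 0).
random_set <- function(universe, min_size = 0) {
  k <- sample(min_size:length(universe), 1)
  if (k == 0) character(0) else sample(universe, k)
}

# Shared small panel used by several expensive tests; built once per run.
recovery_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bp <- build_target_blueprint(15, 200, 5, c(6, 10), 0.85, seed = 101)
      cache <<- list(
        blueprint = bp,
        panel = generate_panel(panel_config(
          n_genes = 200, n_drugs = 15, blueprint = bp, seed = 101)))
    }
    cache
  }
})

fixture_smiles <- function() {
  system.file("extdata", "anticancer_drugs.smi", package = "bindexnet")
}
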