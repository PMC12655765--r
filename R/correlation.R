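# Drug-gene correlation screen: Pearson/Spearman across cell lines,
# Holm family-wise error control, CellMiner-style retention thresholds.

#' Pearson correlation with pairwise-complete deletion
#'
#' Product-moment correlation on the positions present in both vectors,
#' with a two-sided p-value from the t transform on `n - 2` degrees of
#' freedom. Pairs that cannot be tested (fewer than 3 complete
#' observations, or zero variance in either vector) are returned flagged
#' rather than raising an error, so a screen over many pairs can proceed.
#'
#' @param x,y Numeric vectors of equal length, possibly with `NA`s.
#' @return A list with `r`, `p`, `n` (complete observations) and
#'   `testable` (logical).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) < .Machine$double.eps ||
      stats::sd(y[ok]) < .Machine$double.eps)
    return(list(r = NA_real_, p = NA_real_, n = n, testable = FALSE))
  r <- stats::cor(x[ok], y[ok])
  list(r = r, p = r_to_p(r, n), n = n, testable = TRUE)
}

#' Spearman correlation with pairwise-complete deletion
#'
#' Pearson correlation applied to mid-ranks of the pairwise-complete
#' values; ties receive average ranks. The two-sided p-value uses the same
#' t approximation as [pearson_correlation()].
#'
#' @inheritParams pearson_correlation
#' @return A list with `rho`, `p`, `n` and `testable`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(rho = NA_real_, p = NA_real_, n = n, testable = FALSE))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) < .Machine$double.eps ||
      stats::sd(ry) < .Machine$double.eps)
    return(list(rho = NA_real_, p = NA_real_, n = n, testable = FALSE))
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = r_to_p(rho, n), n = n, testable = TRUE)
}

# two-sided p from the t transform of a correlation coefficient
r_to_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, df = n - 2)
}

#' Retention policy for the correlation screen
#'
#' Encapsulates the thresholds of the screen: a correlation coefficient of
#' at least `r_threshold` (0.334, the conventional moderate-association
#' cutoff for a 60-line panel) and a Holm-adjusted p-value of at most
#' `alpha`. Both comparisons are inclusive. `coefficient_mode` selects
#' which coefficient the retention rule tests; `sign_mode = "positive"`
#' keeps positive correlations only.
#'
#' @param r_threshold Coefficient threshold (default 0.334).
#' @param alpha Family-wise error level for the Holm-adjusted p (default
#'   0.05).
#' @param coefficient_mode One of `"pearson"`, `"spearman"`, `"either"`,
#'   `"both"` (default `"pearson"`).
#' @param sign_mode `"positive"` (default) or `"both"` (threshold applied
#'   to `|r|`).
#' @param min_n_obs Minimum non-missing observations per drug for QC
#'   (default 40).
#' @param min_sd Minimum activity standard deviation per drug for QC.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(r_threshold = 0.334, alpha = 0.05,
                          coefficient_mode = c("pearson", "spearman",
                                               "either", "both"),
                          sign_mode = c("positive", "both"),
                          min_n_obs = 40L, min_sd = 1e-8) {
  stopifnot_scalar_number(r_threshold, "r_threshold", -1, 1)
  stopifnot_scalar_number(alpha, "alpha", 0, 1)
  stopifnot(min_n_obs >= 3, min_sd >= 0)
  structure(
    list(r_threshold = r_threshold, alpha = alpha,
         coefficient_mode = match.arg(coefficient_mode),
         sign_mode = match.arg(sign_mode),
         min_n_obs = as.integer(min_n_obs), min_sd = min_sd),
    class = "filter_policy")
}

#' Drop drugs with weak or untestable activity profiles
#'
#' Quality-control step preceding the correlation screen: removes drug
#' rows with fewer than `min_n_obs` non-missing values or with standard
#' deviation below `min_sd` (flat profiles carry no discriminating
#' signal). The removal log is attached as attribute `"removed"`.
#'
#' @param activity Drugs x cell lines numeric matrix.
#' @param policy A [filter_policy()] supplying `min_n_obs` and `min_sd`.
#' @return The reduced activity matrix; errors if no drug survives.
#' @export
qc_filter_drugs <- function(activity, policy = filter_policy()) {
  stopifnot(is.matrix(activity), !is.null(rownames(activity)))
  n_obs <- rowSums(!is.na(activity))
  sds <- apply(activity, 1L, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  reason <- ifelse(n_obs < policy$min_n_obs, "too_few_observations",
                   ifelse(sds < policy$min_sd, "flat_profile", NA))
  keep <- is.na(reason)
  if (!any(keep))
    stop("qc_filter_drugs: all drugs removed; check the activity matrix")
  removed <- data.frame(drug_id = rownames(activity)[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- activity[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Correlate every drug against every gene
#'
#' Computes Pearson and Spearman correlations for each (drug, gene) pair
#' across the shared cell lines, using pairwise-complete deletion, and
#' applies Holm step-down adjustment to the p-values. By default the Holm
#' family is *per drug* (all genes tested against that drug), matching
#' per-compound reporting conventions; `holm_scope = "global"` treats the
#' whole screen as one family.
#'
#' @param expression Genes x cell lines matrix.
#' @param activity Drugs x cell lines matrix; the cell-line columns must
#'   be identical in content and order to `expression`.
#' @param holm_scope `"per_drug"` (default) or `"global"`.
#' @return A data.frame of correlation records with columns `drug_id`,
#'   `gene_id`, `n_obs`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `holm_p` (Holm-adjusted `pearson_p`),
#'   `spearman_holm_p` and `testable`. Untestable pairs carry `NA`
#'   coefficients and are excluded from the Holm families.
#' @export
correlate_all <- function(expression, activity,
                          holm_scope = c("per_drug", "global")) {
  holm_scope <- match.arg(holm_scope)
  stopifnot(is.matrix(expression), is.matrix(activity))
  if (!identical(colnames(expression), colnames(activity))) {
    bad <- union(setdiff(colnames(expression), colnames(activity)),
                 setdiff(colnames(activity), colnames(expression)))
    stop("cell-line columns differ between expression and activity",
         if (length(bad)) paste0(": ", paste(bad, collapse = ", "))
         else " (ordering mismatch)")
  }

  if (!anyNA(expression) && !anyNA(activity)) {
    rec <- correlate_all_complete(expression, activity)
  } else {
    rec <- correlate_all_pairwise(expression, activity)
  }

  rec$holm_p <- NA_real_
  rec$spearman_holm_p <- NA_real_
  idx <- which(rec$testable)
  if (length(idx)) {
    if (holm_scope == "global") {
      rec$holm_p[idx] <- holm_adjust(rec$pearson_p[idx])
      rec$spearman_holm_p[idx] <- holm_adjust(rec$spearman_p[idx])
    } else {
      for (d in unique(rec$drug_id)) {
        i <- idx[rec$drug_id[idx] == d]
        if (!length(i)) next
        rec$holm_p[i] <- holm_adjust(rec$pearson_p[i])
        rec$spearman_holm_p[i] <- holm_adjust(rec$spearman_p[i])
      }
    }
  }
  rec
}

# fast path: no missing data anywhere -> full matrix algebra
correlate_all_complete <- function(expression, activity) {
  n <- ncol(expression)
  zrows <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (n - 1))
    list(z = (m - mu) / ifelse(s > 0, s, Inf), ok = s > .Machine$double.eps)
  }
  ze <- zrows(expression)
  za <- zrows(activity)
  r <- tcrossprod(za$z, ze$z) / (n - 1)          # drugs x genes
  rk <- function(m) t(apply(m, 1L, rank, ties.method = "average"))
  zre <- zrows(rk(expression))
  zra <- zrows(rk(activity))
  rho <- tcrossprod(zra$z, zre$z) / (n - 1)
  testable <- outer(za$ok, ze$ok, `&`)
  r[!testable] <- NA_real_
  rho[!testable] <- NA_real_
  # row-major over drugs: one block of genes per drug
  data.frame(
    drug_id = rep(rownames(activity), each = nrow(expression)),
    gene_id = rep(rownames(expression), times = nrow(activity)),
    n_obs = n,
    pearson_r = as.vector(t(r)),
    pearson_p = as.vector(t(ifelse(testable, r_to_p(r, n), NA_real_))),
    spearman_rho = as.vector(t(rho)),
    spearman_p = as.vector(t(ifelse(testable, r_to_p(rho, n), NA_real_))),
    testable = as.vector(t(testable)),
    stringsAsFactors = FALSE)
}

# general path: per-pair complete-case ranks and correlations
correlate_all_pairwise <- function(expression, activity) {
  out <- vector("list", nrow(activity))
  for (i in seq_len(nrow(activity))) {
    a <- activity[i, ]
    rows <- lapply(seq_len(nrow(expression)), function(j) {
      p <- pearson_correlation(a, expression[j, ])
      s <- spearman_correlation(a, expression[j, ])
      data.frame(drug_id = rownames(activity)[i],
                 gene_id = rownames(expression)[j],
                 n_obs = p$n, pearson_r = p$r, pearson_p = p$p,
                 spearman_rho = s$rho, spearman_p = s$p,
                 testable = p$testable && s$testable,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Holm step-down adjustment
#'
#' Family-wise error rate control: p-values are sorted ascending, the
#' i-th smallest is multiplied by `m - i + 1`, a running maximum is
#' enforced, values are capped at 1 and returned in the original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (no `NA`s).
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "holm")
}

# retention mask under a policy; records must carry holm columns
retained_mask <- function(records, policy) {
  meets <- function(coef, adj_p) {
    val <- if (policy$sign_mode == "both") abs(coef) else coef
    !is.na(coef) & !is.na(adj_p) &
      val >= policy$r_threshold & adj_p <= policy$alpha
  }
  pe <- meets(records$pearson_r, records$holm_p)
  sp <- meets(records$spearman_rho, records$spearman_holm_p)
  ok <- switch(policy$coefficient_mode,
               pearson = pe, spearman = sp,
               either = pe | sp, both = pe & sp)
  ok & records$testable
}

#' Filter correlation records under a retention policy
#'
#' Applies the coefficient threshold, Holm-adjusted significance level and
#' sign rule of `policy` (all comparisons inclusive) and returns the
#' retained records sorted by drug and then by descending Pearson r. An
#' empty result is allowed.
#'
#' @param records Output of [correlate_all()].
#' @param policy A [filter_policy()].
#' @return The retained subset of `records`.
#' @export
filter_records <- function(records, policy = filter_policy()) {
  keep <- records[retained_mask(records, policy), , drop = FALSE]
  keep[order(keep$drug_id, -keep$pearson_r), , drop = FALSE]
}
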