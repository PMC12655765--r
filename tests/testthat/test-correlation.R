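test_that("pearson correlation matches hand computations", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  # cov = 4/3, var_x = var_y = 5/3 -> r = 4/5
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  res <- pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$n, 4L)
  # symmetric in its arguments
  expect_equal(res$r, pearson_correlation(c(1, 3, 2, 4), c(1, 2, 3, 4))$r)
})

test_that("pearson p-value equals the t-transform reference", {
  set.seed(1)
  x <- rnorm(20)
  y <- rnorm(20)
  res <- pearson_correlation(x, y)
  expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("spearman correlation uses mid-ranks", {
  expect_equal(spearman_correlation(c(1, 2, 3), c(1, 4, 9))$rho, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(9, 4, 1))$rho, -1)
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  # ties: mid-ranks agree with stats::cor(method = "spearman")
  x <- c(1, 2, 2, 3, 4, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_correlation(x, y)$rho,
               cor(x, y, method = "spearman"))
})

test_that("untestable pairs are flagged, not raised", {
  expect_false(pearson_correlation(c(1, 2), c(3, 4))$testable)
  expect_false(pearson_correlation(c(1, 1, 1, 1), c(1, 2, 3, 4))$testable)
  r <- pearson_correlation(c(1, 2, NA, NA, NA), c(1, NA, 2, 3, 4))
  expect_false(r$testable)
  expect_equal(r$n, 1L)
})

test_that("pairwise deletion uses exactly the shared positions", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, NA, 5, 9, 1, 13)
  res <- pearson_correlation(x, y)
  keep <- !is.na(x) & !is.na(y)
  expect_equal(res$n, sum(keep))
  expect_equal(res$r, cor(x[keep], y[keep]))
})

test_that("QC drops empty, flat and sparse drug rows", {
  act <- rbind(
    good1 = rnorm(60), good2 = rnorm(60),
    allna = rep(NA_real_, 60),
    flat = rep(0.3, 60),
    sparse = c(rnorm(10), rep(NA_real_, 50)),
    good3 = rnorm(60), good4 = rnorm(60))
  colnames(act) <- sprintf("cell%02d", 1:60)
  out <- qc_filter_drugs(act, filter_policy())
  expect_setequal(rownames(out), c("good1", "good2", "good3", "good4"))
  removed <- attr(out, "removed")
  expect_setequal(removed$drug_id, c("allna", "flat", "sparse"))
  expect_error(qc_filter_drugs(act[c("allna", "flat"), ], filter_policy()),
               "all drugs removed")
})

test_that("correlate_all yields one record per pair and matches per-pair results", {
  set.seed(20)
  expr <- matrix(rnorm(3 * 30), 3,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:30)))
  act <- matrix(rnorm(2 * 30), 2,
                dimnames = list(paste0("d", 1:2), paste0("c", 1:30)))
  rec <- correlate_all(expr, act)
  expect_equal(nrow(rec), 6L)
  for (i in seq_len(nrow(rec))) {
    ref <- pearson_correlation(act[rec$drug_id[i], ],
                               expr[rec$gene_id[i], ])
    expect_equal(rec$pearson_r[i], ref$r, tolerance = 1e-12)
    expect_equal(rec$pearson_p[i], ref$p, tolerance = 1e-12)
    refs <- spearman_correlation(act[rec$drug_id[i], ],
                                 expr[rec$gene_id[i], ])
    expect_equal(rec$spearman_rho[i], refs$rho, tolerance = 1e-12)
  }
})

test_that("fast and pairwise correlation paths agree in the presence of NAs", {
  set.seed(21)
  expr <- matrix(rnorm(4 * 40), 4,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:40)))
  act <- matrix(rnorm(3 * 40), 3,
                dimnames = list(paste0("d", 1:3), paste0("c", 1:40)))
  complete <- correlate_all(expr, act)
  expr_na <- expr
  expr_na[1, 1] <- NA               # forces the general path
  with_na <- correlate_all(expr_na, act)
  other <- with_na$gene_id != "g1"
  expect_equal(with_na$pearson_r[other], complete$pearson_r[other],
               tolerance = 1e-12)
  expect_equal(with_na$spearman_rho[other], complete$spearman_rho[other],
               tolerance = 1e-12)
  expect_equal(with_na$n_obs[with_na$gene_id == "g1"], rep(39L, 3))
})

test_that("cell-line mismatch is reported by id", {
  expr <- matrix(rnorm(6), 2, dimnames = list(c("g1", "g2"),
                                              c("a", "b", "c")))
  act <- matrix(rnorm(6), 2, dimnames = list(c("d1", "d2"),
                                             c("a", "b", "x")))
  expect_error(correlate_all(expr, act), "x")
})

test_that("planted anchors surface with their exact correlation", {
  fx <- recovery_panel()
  rec <- correlate_all(fx$panel$expression, fx$panel$activity)
  for (d in names(fx$blueprint$assignments)) {
    anchor <- fx$blueprint$assignments[[d]][1]
    row <- rec[rec$drug_id == d & rec$gene_id == anchor, ]
    expect_equal(row$pearson_r, 0.6, tolerance = 1e-12)
  }
})

test_that("holm_adjust matches the worked step-down examples", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(0.05, 0.05)), c(0.10, 0.10))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("holm_adjust agrees with a brute-force oracle on random vectors", {
  set.seed(99)
  bad <- 0L
  for (i in 1:1000) {
    p <- runif(sample(1:25, 1))
    if (max(abs(holm_adjust(p) - holm_oracle(p))) > 1e-12) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("holm output brackets raw and Bonferroni p and ignores input order", {
  set.seed(100)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    h <- holm_adjust(p)
    m <- length(p)
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= pmin(1, m * p) + 1e-15))
    perm <- sample(m)
    expect_equal(holm_adjust(p[perm])[order(perm)], h, tolerance = 1e-15)
  }
})

test_that("retention thresholds are inclusive and sign-aware", {
  rec <- data.frame(
    drug_id = "d1", gene_id = paste0("g", 1:4),
    n_obs = 60L,
    pearson_r = c(0.334, 0.333, -0.9, 0.5),
    pearson_p = c(1e-4, 1e-4, 1e-9, 1e-4),
    spearman_rho = c(0.3, 0.3, -0.9, 0.5),
    spearman_p = c(0.01, 0.01, 1e-9, 1e-4),
    holm_p = c(0.05, 0.001, 1e-8, 0.051),
    spearman_holm_p = c(0.5, 0.5, 1e-8, 0.01),
    testable = TRUE, stringsAsFactors = FALSE)
  kept <- filter_records(rec, filter_policy())
  # boundary pair retained; sub-threshold r, negative r, p > alpha dropped
  expect_identical(kept$gene_id, "g1")
  both_signs <- filter_records(rec, filter_policy(sign_mode = "both"))
  expect_setequal(both_signs$gene_id, c("g1", "g3"))
})

test_that("coefficient modes combine the two tests as configured", {
  rec <- data.frame(
    drug_id = "d1", gene_id = paste0("g", 1:3),
    n_obs = 60L,
    pearson_r = c(0.5, 0.2, 0.5),
    pearson_p = 1e-4, spearman_rho = c(0.2, 0.5, 0.5),
    spearman_p = 1e-4,
    holm_p = c(0.01, 0.01, 0.01), spearman_holm_p = c(0.01, 0.01, 0.01),
    testable = TRUE, stringsAsFactors = FALSE)
  expect_identical(
    filter_records(rec, filter_policy(coefficient_mode = "pearson"))$gene_id,
    c("g1", "g3"))
  expect_setequal(
    filter_records(rec, filter_policy(coefficient_mode = "spearman"))$gene_id,
    c("g2", "g3"))
  expect_setequal(
    filter_records(rec, filter_policy(coefficient_mode = "either"))$gene_id,
    c("g1", "g2", "g3"))
  expect_identical(
    filter_records(rec, filter_policy(coefficient_mode = "both"))$gene_id,
    "g3")
})

test_that("every planted truth pair passes the default filter", {
  fx <- recovery_panel()
  rec <- correlate_all(fx$panel$expression, fx$panel$activity)
  kept <- filter_records(rec, filter_policy())
  key <- paste(kept$drug_id, kept$gene_id)
  for (d in names(fx$blueprint$assignments))
    for (g in fx$blueprint$assignments[[d]])
      expect_true(paste(d, g) %in% key)
})

test_that("family-wise error stays controlled on null panels", {
  hits <- vapply(1:200, function(i) {
    p <- generate_panel(panel_config(
      n_genes = 100, n_drugs = 5, blueprint = empty_blueprint(5, 100),
      seed = 5000L + i))
    rec <- correlate_all(p$expression, p$activity, holm_scope = "global")
    nrow(filter_records(rec, filter_policy())) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
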