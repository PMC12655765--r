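test_that("b_index reproduces the worked size-asymmetry example", {
  s <- make_sets(4, 40, 2)
  # half the intersection weighted by each reciprocal size:
  # 0.5 * 2 * (1/4 + 1/40) = 0.275
  expect_equal(b_index(s$x, s$y), 0.275)
  expect_equal(dice(s$x, s$y), 4 / 44)
  expect_equal(jaccard(s$x, s$y), 2 / 42)
})

test_that("coefficients reproduce the published drug-pair table", {
  cases <- list(
    #            |x| |y| shared  b      jaccard
    cytarabine_gemcitabine = c(4, 9, 3, 0.542, 0.300),
    carmustine_lomustine = c(27, 29, 20, 0.715, 0.556),
    afatinib_dacomitinib = c(9, 9, 5, 0.556, 0.385),
    afatinib_neratinib = c(9, 6, 5, 0.694, 0.500),
    dacomitinib_neratinib = c(9, 6, 3, 0.417, 0.250))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    s <- make_sets(cs[1], cs[2], cs[3])
    expect_equal(b_index(s$x, s$y), cs[4], tolerance = 1e-3, label = nm)
    expect_equal(jaccard(s$x, s$y), cs[5], tolerance = 1e-3, label = nm)
  }
  # disjoint non-empty sets (the neratinib-tucatinib case)
  s0 <- make_sets(6, 8, 0)
  expect_identical(b_index(s0$x, s0$y), 0)
  expect_identical(jaccard(s0$x, s0$y), 0)
})

test_that("identity, bounds and empty-set conventions hold", {
  x <- letters[1:5]
  expect_equal(b_index(x, x), 1)
  expect_equal(dice(x, x), 1)
  expect_equal(jaccard(x, x), 1)
  expect_equal(russell_rao(x, x, x), 1)
  expect_identical(b_index(character(0), character(0)), 0)
  expect_identical(b_index(character(0), x), 0)
  expect_identical(dice(character(0), character(0)), 0)
  expect_identical(jaccard(character(0), character(0)), 0)
  expect_error(russell_rao(x, x, character(0)), "universe")
  expect_error(russell_rao(c(x, "zz"), x, x), "subsets")
})

test_that("b_index equals 1 iff the sets are equal, 0 iff disjoint", {
  set.seed(7)
  universe <- sprintf("u%02d", 1:12)
  for (i in 1:300) {
    x <- random_set(universe, min_size = 1)
    y <- random_set(universe, min_size = 1)
    b <- b_index(x, y)
    expect_identical(b == 1, setequal(x, y))
    expect_identical(b == 0, length(intersect(x, y)) == 0L)
    expect_gte(b, 0)
    expect_lte(b, 1)
    expect_equal(b, b_index(y, x))
  }
})

test_that("ordering chain russell_rao <= jaccard <= dice <= b_index holds", {
  set.seed(8)
  universe <- sprintf("u%02d", 1:20)
  chain_viol <- 0L
  am_hm_viol <- 0L
  for (i in 1:10000) {
    x <- random_set(universe, min_size = 1)
    y <- random_set(universe, min_size = 1)
    rr <- russell_rao(x, y, universe)
    jc <- jaccard(x, y)
    dc <- dice(x, y)
    bi <- b_index(x, y)
    if (!(rr <= jc + 1e-15 && jc <= dc + 1e-15 && dc <= bi + 1e-15))
      chain_viol <- chain_viol + 1L
    # AM-HM: b_index == dice only for equally sized sets (or no overlap)
    if (length(intersect(x, y)) > 0 &&
        (abs(bi - dc) < 1e-12) != (length(unique(x)) == length(unique(y))))
      am_hm_viol <- am_hm_viol + 1L
  }
  expect_identical(chain_viol, 0L)
  expect_identical(am_hm_viol, 0L)
})

test_that("1 - b_index is not a metric: a violating triple exists", {
  # brute-force search over tiny subsets finds a triangle violation
  universe <- letters[1:4]
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(universe, k, simplify = FALSE)), recursive = FALSE)
  found <- NULL
  for (x in subsets) for (y in subsets) for (z in subsets) {
    d <- function(a, b) 1 - b_index(a, b)
    if (d(x, z) > d(x, y) + d(y, z) + 1e-12) {
      found <- list(x = x, y = y, z = z)
      break
    }
  }
  expect_false(is.null(found))
  # and the canonical small witness violates directly
  expect_gt(1 - b_index("a", "b"),
            (1 - b_index("a", c("a", "b"))) +
              (1 - b_index(c("a", "b"), "b")))
})

test_that("pairwise_similarity builds symmetric unit-diagonal matrices", {
  sets <- list(d1 = c("A", "B", "C", "D"),
               d2 = c("A", "B", "C", "E", "F", "G", "H", "I", "J"),
               d3 = c("Z"))
  S <- pairwise_similarity(sets)
  expect_identical(dim(S), c(3L, 3L))
  expect_equal(S, t(S), ignore_attr = TRUE)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S["d1", "d2"], b_index(sets$d1, sets$d2))
  expect_equal(S["d1", "d3"], 0)
  expect_identical(attr(S, "index_name"), "b_index")

  single <- pairwise_similarity(sets[1])
  expect_identical(dim(single), c(1L, 1L))
  expect_equal(single[1, 1], 1)

  expect_warning(S2 <- pairwise_similarity(c(sets, list(d4 = character(0)))),
                 "empty")
  expect_identical(dim(S2), c(3L, 3L))

  Srr <- pairwise_similarity(sets, index = "russell_rao",
                             universe = LETTERS)
  expect_equal(Srr["d1", "d2"], 3 / 26)
})

test_that("pair_report accounts for every unordered pair", {
  sets <- list(d1 = c("A", "B", "C", "D"),
               d2 = c("A", "B", "C", "E", "F", "G", "H", "I", "J"),
               d3 = c("Q"), d4 = character(0))
  rep <- pair_report(sets)
  expect_equal(nrow(rep), choose(4, 2))
  row <- rep[rep$drug_a == "d1" & rep$drug_b == "d2", ]
  expect_equal(row$shared, 3)
  expect_equal(row$jaccard, 0.3)
  expect_equal(row$b_index, 0.5 * 3 * (1 / 4 + 1 / 9))
  s <- attr(rep, "summary")
  expect_equal(s$n_shared_pos + s$n_shared_zero, choose(4, 2))
  expect_equal(s$n_shared_pos, 1)
  # empty-set drug participates with zero similarity
  expect_true(all(rep$b_index[rep$drug_a == "d4" | rep$drug_b == "d4"] == 0))
})

test_that("a 124-drug map yields the full 7626-pair accounting", {
  set.seed(9)
  sets <- setNames(lapply(1:124, function(i)
    sample(sprintf("g%03d", 1:399), sample(3:30, 1))),
    sprintf("drug%03d", 1:124))
  rep <- pair_report(sets)
  expect_equal(nrow(rep), 7626)
  s <- attr(rep, "summary")
  expect_equal(s$n_shared_pos + s$n_shared_zero, 7626)
})

test_that("within a fully sharing family the matrix block is 1", {
  bp <- build_target_blueprint(4, 60, 2, c(5, 5), shared_fraction = 1,
                               seed = 12)
  S <- pairwise_similarity(bp$assignments)
  fams <- split(names(bp$families), bp$families)
  for (members in fams)
    expect_equal(unname(S[members, members]),
                 matrix(1, length(members), length(members)))
})

test_that("pair report TSV rounds to 3 decimals and appends the footer", {
  sets <- list(d1 = c("A", "B", "C", "D"), d2 = c("A", LETTERS[5:12]))
  path <- tempfile(fileext = ".tsv")
  write_pair_report(pair_report(sets), path)
  tab <- read.delim(path, comment.char = "#")
  expect_equal(tab$b_index, round(0.5 * (1 / 4 + 1 / 9), 3))
  expect_match(readLines(path)[3], "shared_ge1=1")
})
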