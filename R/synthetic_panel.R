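# Synthetic pharmacogenomic panels with planted structure.
#
# The generator emulates the statistical shape of an NCI-60-style screen:
# standardized expression and activity profiles over 60 cell lines grouped
# into 9 tissue types, drug-gene correlations planted at an exact in-sample
# value, and drug families whose target sets overlap by construction.

#' Default tissue composition of the simulated panel
#'
#' Nine tissue-of-origin groups whose counts sum to 60, mirroring the
#' composition of the NCI-60 cell-line panel (breast, CNS, colon, leukemia,
#' melanoma, non-small-cell lung, ovarian, prostate, renal).
#'
#' @return Named integer vector of cell-line counts per tissue.
#' @export
default_tissue_counts <- function() {
  c(breast = 5L, cns = 6L, colon = 7L, leukemia = 6L, melanoma = 10L,
    lung = 9L, ovarian = 7L, prostate = 2L, renal = 8L)
}

#' Construct ground-truth drug target assignments
#'
#' Partitions drugs into families and assigns each drug a target gene set
#' composed of a family-core set (shared by every drug in the family) plus
#' drug-private genes. Families draw from disjoint gene pools, so drugs in
#' different families never share a target. The blueprint is the ground
#' truth against which network recovery and cluster recovery are scored.
#'
#' @param n_drugs,n_genes,n_families Positive integers; `n_families <=
#'   n_drugs`.
#' @param targets_per_drug Integer range `c(min, max)` for per-drug target
#'   set sizes.
#' @param shared_fraction Fraction (in `[0, 1]`) of the smallest set size in
#'   a family that forms the shared family core. At 1 all drugs in a family
#'   have identical sets; at 0 all target sets are private and disjoint.
#' @param seed Integer seed; the blueprint is deterministic given all
#'   arguments.
#' @return An object of class `target_blueprint`: a list with
#'   `assignments` (named list, drug id -> character vector of gene ids,
#'   family-core genes first), `families` (named character vector, drug id
#'   -> family name), and `gene_ids` (the full gene universe).
#' @export
build_target_blueprint <- function(n_drugs, n_genes, n_families,
                                   targets_per_drug = c(5L, 10L),
                                   shared_fraction = 0.5,
                                   seed = 1L) {
  stopifnot(n_drugs >= 1, n_genes >= 1, n_families >= 1,
            n_families <= n_drugs)
  stopifnot_scalar_number(shared_fraction, "shared_fraction", 0, 1)
  targets_per_drug <- as.integer(round(targets_per_drug))
  if (length(targets_per_drug) == 1L)
    targets_per_drug <- rep(targets_per_drug, 2L)
  if (targets_per_drug[1] < 1L || targets_per_drug[2] > n_genes ||
      targets_per_drug[1] > targets_per_drug[2])
    stop("'targets_per_drug' range must lie within [1, n_genes]")

  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  fam_names <- sprintf("family%02d", seq_len(n_families))

  with_seed(seed, {
    # near-equal family sizes
    fam_sizes <- diff(round(seq(0, n_drugs, length.out = n_families + 1L)))
    fam_of <- rep(fam_names, fam_sizes)
    size_range <- seq(targets_per_drug[1], targets_per_drug[2])
    set_sizes <- if (length(size_range) == 1L)
      rep(size_range, n_drugs)
    else sample(size_range, n_drugs, replace = TRUE)

    pool <- sample(gene_ids)   # shuffled; families consume disjoint blocks
    cursor <- 0L
    take <- function(k) {
      if (cursor + k > n_genes)
        stop("gene pool exhausted: blueprint needs more than 'n_genes' genes")
      out <- pool[(cursor + 1L):(cursor + k)]
      cursor <<- cursor + k
      out
    }

    assignments <- stats::setNames(vector("list", n_drugs), drug_ids)
    for (f in fam_names) {
      members <- which(fam_of == f)
      sizes <- set_sizes[members]
      core_size <- as.integer(round(shared_fraction * min(sizes)))
      if (shared_fraction > 0 && core_size < 1L) core_size <- 1L
      core <- if (core_size > 0L) take(core_size) else character(0)
      for (i in members) {
        private <- take(set_sizes[i] - core_size)
        assignments[[i]] <- c(core, private)
      }
    }
    structure(
      list(assignments = assignments,
           families = stats::setNames(fam_of, drug_ids),
           gene_ids = gene_ids),
      class = "target_blueprint")
  })
}

#' An empty target blueprint (pure-noise panel)
#'
#' @param n_genes Size of the gene universe.
#' @param n_drugs Number of drugs (all with empty target sets).
#' @return A `target_blueprint` with empty assignments, used for null
#'   panels in false-positive-rate studies.
#' @export
empty_blueprint <- function(n_drugs, n_genes) {
  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  structure(
    list(assignments = stats::setNames(
           rep(list(character(0)), n_drugs), drug_ids),
         families = stats::setNames(rep(NA_character_, n_drugs), drug_ids),
         gene_ids = sprintf("gene%04d", seq_len(n_genes))),
    class = "target_blueprint")
}

#' @export
print.target_blueprint <- function(x, ...) {
  cat(sprintf("target_blueprint: %d drugs, %d genes in universe, %d families\n",
              length(x$assignments), length(x$gene_ids),
              length(unique(stats::na.omit(x$families)))))
  cat(sprintf("  target-set sizes: %s\n",
              paste(range(lengths(x$assignments)), collapse = "-")))
  invisible(x)
}

#' Generate a vector with an exact in-sample Pearson correlation
#'
#' Builds a standardized profile whose *sample* Pearson correlation with
#' `gene_profile` equals `r` to machine precision: the gene profile is
#' standardized, Gaussian noise is drawn and its in-sample projection onto
#' the profile removed, the residual standardized, and the two combined as
#' \eqn{r \hat g + \sqrt{1 - r^2}\,\hat e}. The exact construction removes
#' Monte-Carlo variability from downstream recovery tests.
#'
#' @param gene_profile Numeric vector with at least 3 non-missing values and
#'   nonzero variance. Positions missing in the input are missing in the
#'   output.
#' @param r Target sample correlation in `[-1, 1]`.
#' @param seed Optional integer seed for the noise draw.
#' @return Standardized numeric vector of the same length with sample
#'   correlation exactly `r` against `gene_profile`.
#' @export
plant_correlated_profile <- function(gene_profile, r, seed = NULL) {
  stopifnot_scalar_number(r, "r", -1, 1)
  ok <- !is.na(gene_profile)
  if (sum(ok) < 3L) stop("'gene_profile' needs >= 3 non-missing values")
  g <- gene_profile[ok]
  if (stats::sd(g) < .Machine$double.eps)
    stop("'gene_profile' is constant; correlation is undefined")
  ghat <- zscore(g)
  with_seed(seed, {
    n <- length(g)
    repeat {
      z <- stats::rnorm(n)
      # remove in-sample projection onto ghat (centred inner product)
      z <- z - mean(z)
      e <- z - ghat * sum(z * ghat) / sum(ghat * ghat)
      if (stats::sd(e) > 1e-12) break
    }
    ehat <- zscore(e)
    out <- rep(NA_real_, length(gene_profile))
    out[ok] <- r * ghat + sqrt(1 - r^2) * ehat
    out
  })
}

#' Panel generation settings
#'
#' @param n_cell_lines Number of cell lines (default 60).
#' @param tissue_counts Named integer vector of cell lines per tissue;
#'   counts must sum to `n_cell_lines`. Tissue labels are metadata carried
#'   through to profile tables and exports; they do not affect generation.
#' @param n_genes,n_drugs Panel dimensions.
#' @param blueprint A [build_target_blueprint()] result (or
#'   [empty_blueprint()]); its drug/gene universe must match `n_drugs` /
#'   `n_genes`.
#' @param planted_r Sample correlation (in `(0, 1]`) planted between each
#'   drug's activity profile and its designated anchor gene; default 0.6.
#' @param missing_rate Fraction of cells masked to `NA` after planting
#'   (default 0). Planted correlations are exact only at 0.
#' @param seed Integer seed; the panel is fully deterministic given the
#'   configuration.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_cell_lines = 60L,
                         tissue_counts = default_tissue_counts(),
                         n_genes = 120L, n_drugs = 12L,
                         blueprint = NULL,
                         planted_r = 0.6, missing_rate = 0,
                         seed = 1L) {
  stopifnot(n_cell_lines >= 3, n_genes >= 1, n_drugs >= 1)
  stopifnot_scalar_number(planted_r, "planted_r", lo = 0, hi = 1)
  if (planted_r <= 0) stop("'planted_r' must be in (0, 1]")
  stopifnot_scalar_number(missing_rate, "missing_rate", 0, 1)
  if (missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  if (n_cell_lines != 60L && identical(tissue_counts, default_tissue_counts()))
    tissue_counts <- c(panel = as.integer(n_cell_lines))
  if (sum(tissue_counts) != n_cell_lines)
    stop("'tissue_counts' must sum to 'n_cell_lines'")
  if (is.null(blueprint))
    blueprint <- build_target_blueprint(
      n_drugs, n_genes, n_families = max(1L, n_drugs %/% 3L), seed = seed)
  structure(
    list(n_cell_lines = as.integer(n_cell_lines),
         tissue_counts = tissue_counts,
         n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
         blueprint = blueprint, planted_r = planted_r,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "panel_config")
}

#' Generate a synthetic expression/activity panel
#'
#' Produces standardized gene-expression and drug-activity matrices over a
#' shared set of cell lines. For every drug with targets in the blueprint,
#' the first gene of its target set is the *anchor*: the drug's activity
#' profile is constructed from the anchor's expression by
#' [plant_correlated_profile()] so their sample Pearson correlation equals
#' `planted_r` exactly. The remaining target genes of each family are drawn
#' around a family latent factor and rejection-checked so every truth
#' (drug, gene) pair attains sample `|r| >= planted_r - 0.15`. Non-target
#' genes and target-free drugs are independent Gaussian noise. Missing
#' values are masked after planting; all rows are standardized over their
#' non-missing entries.
#'
#' @param config A [panel_config()].
#' @return An object of class `synthetic_panel`: a list with `expression`
#'   (genes x cell lines), `activity` (drugs x cell lines), `truth` (the
#'   blueprint), `tissues` (factor per cell line) and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  bp <- config$blueprint
  if (length(bp$assignments) != config$n_drugs)
    stop("blueprint drug count does not match 'n_drugs'")
  if (!all(unlist(bp$assignments) %in%
           sprintf("gene%04d", seq_len(config$n_genes))))
    stop("blueprint references genes outside the configured gene universe")

  n <- config$n_cell_lines
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  drug_ids <- names(bp$assignments)
  cell_ids <- sprintf("cell%02d", seq_len(n))
  tissues <- factor(rep(names(config$tissue_counts), config$tissue_counts),
                    levels = names(config$tissue_counts))

  with_seed(config$seed, {
    expr <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes,
                   dimnames = list(gene_ids, cell_ids))
    expr <- t(apply(expr, 1L, zscore))
    dimnames(expr) <- list(gene_ids, cell_ids)
    act <- matrix(stats::rnorm(config$n_drugs * n), nrow = config$n_drugs,
                  dimnames = list(drug_ids, cell_ids))
    act <- t(apply(act, 1L, zscore))
    dimnames(act) <- list(drug_ids, cell_ids)

    # correlation of non-anchor target genes with the family latent factor;
    # high enough that activity-gene correlations clear planted_r - 0.15
    # with margin, and enforced below by rejection in any case
    rho_gene <- 0.95
    fams <- split(drug_ids[lengths(bp$assignments) > 0],
                  bp$families[lengths(bp$assignments) > 0])
    for (f in names(fams)) {
      members <- fams[[f]]
      union_genes <- unique(unlist(bp$assignments[members]))
      latent <- zscore(stats::rnorm(n))
      for (g in union_genes)
        expr[g, ] <- plant_correlated_profile(latent, rho_gene)
      for (d in members) {
        anchor <- bp$assignments[[d]][1]
        act[d, ] <- plant_correlated_profile(expr[anchor, ], config$planted_r)
      }
      # rejection: redraw any target gene whose realized correlation with a
      # targeting drug's activity falls below the guarantee
      floor_r <- config$planted_r - 0.15
      for (iter in seq_len(200L)) {
        bad <- character(0)
        for (d in members) {
          genes <- setdiff(bp$assignments[[d]], bp$assignments[[d]][1])
          if (!length(genes)) next
          rr <- abs(as.vector(stats::cor(act[d, ], t(expr[genes, ,
                                                          drop = FALSE]))))
          bad <- union(bad, genes[rr < floor_r])
        }
        # anchors of other drugs may appear as non-anchor targets; never
        # redraw a gene that is some drug's anchor (its correlation is exact)
        anchors <- vapply(bp$assignments[members], `[`, "", 1L)
        bad <- setdiff(bad, anchors)
        if (!length(bad)) break
        if (iter == 200L)
          stop("failed to realize planted correlations; ",
               "check 'planted_r' feasibility")
        for (g in bad)
          expr[g, ] <- plant_correlated_profile(latent, rho_gene)
      }
    }

    if (config$missing_rate > 0) {
      mask_m <- function(m) {
        drop_n <- stats::rbinom(1L, length(m), config$missing_rate)
        m[sample(length(m), drop_n)] <- NA_real_
        m
      }
      expr <- mask_m(expr)
      act <- mask_m(act)
      expr <- t(apply(expr, 1L, function(x)
        if (sum(!is.na(x)) >= 2 && stats::sd(x, na.rm = TRUE) > 0)
          zscore(x) else x))
      act <- t(apply(act, 1L, function(x)
        if (sum(!is.na(x)) >= 2 && stats::sd(x, na.rm = TRUE) > 0)
          zscore(x) else x))
      dimnames(expr) <- list(gene_ids, cell_ids)
      dimnames(act) <- list(drug_ids, cell_ids)
    }

    structure(
      list(expression = expr, activity = act, truth = bp,
           tissues = stats::setNames(tissues, cell_ids), config = config),
      class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "synthetic_panel: %d genes x %d cell lines, %d drugs (planted r = %g)\n",
    nrow(x$expression), ncol(x$expression), nrow(x$activity),
    x$config$planted_r))
  invisible(x)
}

#' Write a synthetic panel to an output directory
#'
#' Emits `expression.tsv` and `activity.tsv` (matrix dialect of
#' [write_matrix_tsv()]), `blueprint.tsv` (drug, gene, family),
#' `config.yaml`, and `manifest.yaml` recording the seed and MD5 checksums.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(panel$expression, file.path(dir, "expression.tsv"),
                   id_col = "gene_id")
  write_matrix_tsv(panel$activity, file.path(dir, "activity.tsv"),
                   id_col = "drug_id")
  bp <- panel$truth
  write_tsv(data.frame(
    drug_id = rep(names(bp$assignments), lengths(bp$assignments)),
    gene_id = unlist(bp$assignments, use.names = FALSE),
    family = rep(unname(bp$families), lengths(bp$assignments)),
    stringsAsFactors = FALSE), file.path(dir, "blueprint.tsv"))
  cfg <- panel$config
  yaml::write_yaml(list(
    n_cell_lines = cfg$n_cell_lines,
    tissue_counts = as.list(cfg$tissue_counts),
    n_genes = cfg$n_genes, n_drugs = cfg$n_drugs,
    planted_r = cfg$planted_r, missing_rate = cfg$missing_rate,
    seed = cfg$seed), file.path(dir, "config.yaml"))
  files <- c("expression.tsv", "activity.tsv", "blueprint.tsv", "config.yaml")
  yaml::write_yaml(list(
    seed = cfg$seed,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files))),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
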