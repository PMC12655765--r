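# End-to-end orchestration: panel -> QC -> correlation screen -> network
# -> target sets -> similarity -> clustering (-> structural concordance),
# with every artifact written under one output directory and a run report
# that reconciles the stage outputs.

#' Assemble a pipeline run configuration
#'
#' In `"synthetic"` mode a seeded panel is generated from the supplied
#' dimensions; in `"real"` mode the expression/activity matrices are read
#' from TSV files in the dialect of [write_matrix_tsv()]. The resolved
#' configuration is written next to the outputs for reproducibility.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param outdir Output directory for all artifacts.
#' @param seed Integer seed recorded in the report and driving all
#'   randomness.
#' @param n_cell_lines,n_genes,n_drugs,n_families,targets_per_drug,
#'   shared_fraction,planted_r,missing_rate Synthetic-panel parameters
#'   (see [panel_config()] and [build_target_blueprint()]).
#' @param blueprint Optional pre-built blueprint overriding the family
#'   parameters.
#' @param expression_file,activity_file,annotation_file Real-mode inputs;
#'   the annotation TSV (`gene_id`, `category`) is optional in either
#'   mode.
#' @param policy Retention policy, a [filter_policy()].
#' @param holm_scope `"per_drug"` or `"global"`.
#' @param index Set-similarity coefficient for the drug matrix.
#' @param k `"auto"` (inertia criterion) or an integer cluster count.
#' @param k_min,k_max Search range for the inertia criterion.
#' @param smiles_file Optional SMILES file enabling the structural
#'   cross-validation stage.
#' @param verbose Emit stage messages to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       outdir = tempfile("bindexnet_run_"),
                       seed = 1L,
                       n_cell_lines = 60L, n_genes = 120L, n_drugs = 12L,
                       n_families = 4L, targets_per_drug = c(5L, 10L),
                       shared_fraction = 0.8, planted_r = 0.6,
                       missing_rate = 0, blueprint = NULL,
                       expression_file = NULL, activity_file = NULL,
                       annotation_file = NULL,
                       policy = filter_policy(),
                       holm_scope = c("per_drug", "global"),
                       index = "b_index",
                       k = "auto", k_min = 2L, k_max = NULL,
                       smiles_file = NULL, verbose = TRUE) {
  mode <- match.arg(mode)
  holm_scope <- match.arg(holm_scope)
  if (mode == "real") {
    for (f in c(expression_file, activity_file))
      if (is.null(f) || !file.exists(f))
        stop("real mode requires existing 'expression_file' and ",
             "'activity_file'")
  }
  structure(
    list(mode = mode, outdir = outdir, seed = as.integer(seed),
         n_cell_lines = n_cell_lines, n_genes = n_genes,
         n_drugs = n_drugs, n_families = n_families,
         targets_per_drug = targets_per_drug,
         shared_fraction = shared_fraction, planted_r = planted_r,
         missing_rate = missing_rate, blueprint = blueprint,
         expression_file = expression_file,
         activity_file = activity_file,
         annotation_file = annotation_file,
         policy = policy, holm_scope = holm_scope, index = index,
         k = k, k_min = k_min, k_max = k_max,
         smiles_file = smiles_file, verbose = verbose),
    class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes: panel generation or loading, drug QC, the drug-gene
#' correlation screen with Holm control, retention filtering, bipartite
#' network assembly, per-drug target sets, the drug-drug similarity
#' matrix and pair report, similarity-to-distance conversion, Ward.D2
#' clustering with inertia-based (or fixed) cluster count, and - when a
#' SMILES file is configured - structural similarity and cluster
#' concordance. All artifacts are written under `config$outdir`.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: stage counts, the chosen
#'   cluster count, the file manifest with MD5 checksums, and the
#'   stage results themselves in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose)
    message(sprintf("[bindexnet] %s", sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  if (config$mode == "synthetic") {
    say("generating synthetic panel (seed %d)", config$seed)
    panel <- stage("simulate", {
      bp <- config$blueprint %||% build_target_blueprint(
        config$n_drugs, config$n_genes, config$n_families,
        config$targets_per_drug, config$shared_fraction,
        seed = config$seed)
      generate_panel(panel_config(
        n_cell_lines = config$n_cell_lines, n_genes = config$n_genes,
        n_drugs = config$n_drugs, blueprint = bp,
        planted_r = config$planted_r, missing_rate = config$missing_rate,
        seed = config$seed))
    })
    write_panel(panel, file.path(config$outdir, "panel"))
    expression <- panel$expression
    activity <- panel$activity
  } else {
    say("loading matrices")
    panel <- NULL
    expression <- stage("load", read_matrix_tsv(config$expression_file))
    activity <- stage("load", read_matrix_tsv(config$activity_file))
  }
  annotations <- if (!is.null(config$annotation_file))
    utils::read.delim(config$annotation_file, stringsAsFactors = FALSE)

  # --- correlation screen -------------------------------------------------
  n_drugs_in <- nrow(activity)
  activity <- stage("qc", qc_filter_drugs(activity, config$policy))
  say("QC kept %d of %d drugs", nrow(activity), n_drugs_in)
  records <- stage("correlate",
                   correlate_all(expression, activity,
                                 holm_scope = config$holm_scope))
  write_correlations(records, file.path(config$outdir, "correlations.tsv"),
                     config$policy)
  retained <- stage("filter", filter_records(records, config$policy))
  say("retained %d of %d tested pairs", nrow(retained),
      sum(records$testable))

  # --- network ------------------------------------------------------------
  network <- stage("network", build_network(retained, annotations))
  write_network_graphml(network, file.path(config$outdir, "network.graphml"))
  write_network_sif(network, file.path(config$outdir, "network.sif"))
  write_edge_table(network, file.path(config$outdir, "edges.tsv"))
  sets <- target_sets(network)
  # pair accounting covers every post-QC drug, including target-free ones
  all_sets <- stats::setNames(
    lapply(rownames(activity), function(d) sets[[d]] %||% character(0)),
    rownames(activity))
  write_target_sets(all_sets, file.path(config$outdir, "targets.tsv"))

  # --- similarity + clustering -------------------------------------------
  report_pairs <- if (length(all_sets) >= 2L)
    stage("similarity", pair_report(all_sets))
  if (!is.null(report_pairs))
    write_pair_report(report_pairs, file.path(config$outdir, "pairs.tsv"))
  clust <- NULL
  S <- NULL
  if (sum(lengths(all_sets) > 0) >= 3L) {
    S <- stage("similarity", suppressWarnings(
      pairwise_similarity(all_sets, index = config$index)))
    write_similarity_tsv(S, file.path(config$outdir, "similarity.tsv"))
    tree <- stage("cluster", ward_cluster(to_distance(S)))
    k <- if (identical(config$k, "auto")) {
      k_max <- config$k_max %||% (nrow(S) - 1L)
      select_k_by_inertia(tree, config$k_min, k_max)
    } else as.integer(config$k)
    partition <- cut_tree(tree, k)
    say("clustered %d drugs into k = %d groups", nrow(S), k)
    export_tree(tree, file.path(config$outdir, "tree.nwk"))
    export_ordered_matrix(S, tree,
                          file.path(config$outdir, "similarity_ordered.tsv"))
    write_tsv(data.frame(drug_id = names(partition),
                         cluster = unname(partition)),
              file.path(config$outdir, "clusters.tsv"))
    clust <- list(tree = tree, k = k, partition = partition)
  } else say("fewer than 3 drugs with targets; skipping clustering")

  # --- structural cross-validation ---------------------------------------
  structural <- NULL
  if (!is.null(config$smiles_file)) {
    say("structural similarity from %s", config$smiles_file)
    compounds <- stage("structure", load_compounds(config$smiles_file))
    structural <- stage("structure", pairwise_structural(compounds))
    write_tsv(structural$pairs,
              file.path(config$outdir, "structural_pairs.tsv"))
    pick <- best_structural_matrix(structural$similarity)
    Ssel <- structural$similarity[[pick]]
    Ssel <- ifelse(is.na(Ssel), 0, Ssel)
    stree <- stats::hclust(stats::as.dist(to_distance(Ssel)),
                           method = "average")
    structural$matrix_used <- as.character(pick)
    if (!is.null(clust)) {
      common <- intersect(names(clust$partition), stree$labels)
      if (length(common) >= 3L) {
        sp <- cut_tree(stree, min(clust$k, length(common) - 1L))
        structural$concordance <- cluster_concordance(
          clust$partition[common], sp[common])
        say("structural concordance ARI = %.3f",
            structural$concordance$adjusted_rand)
      }
    }
  }

  # --- report -------------------------------------------------------------
  counts <- list(
    drugs_in = n_drugs_in,
    drugs_after_qc = nrow(activity),
    genes = nrow(expression),
    tested_pairs = sum(records$testable),
    retained_edges = nrow(retained),
    network_drug_nodes = sum(igraph::V(network)$kind == "drug"),
    network_gene_nodes = sum(igraph::V(network)$kind == "gene"),
    network_edges = igraph::ecount(network),
    pairs_shared_ge1 = if (!is.null(report_pairs))
      attr(report_pairs, "summary")$n_shared_pos else NA_integer_,
    pairs_shared_eq0 = if (!is.null(report_pairs))
      attr(report_pairs, "summary")$n_shared_zero else NA_integer_,
    k = if (!is.null(clust)) clust$k else NA_integer_)
  stopifnot(counts$retained_edges == counts$network_edges)
  if (!is.null(report_pairs))
    stopifnot(counts$pairs_shared_ge1 + counts$pairs_shared_eq0 ==
                choose(counts$drugs_after_qc, 2))

  resolved <- config[setdiff(names(config), c("blueprint", "policy"))]
  resolved$policy <- unclass(config$policy)
  yaml::write_yaml(lapply(resolved, function(x)
    if (is.null(x)) "" else x), file.path(config$outdir, "config.yaml"))
  files <- list.files(config$outdir, recursive = TRUE)
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))

  structure(
    list(seed = config$seed, counts = counts, manifest = manifest,
         outdir = config$outdir,
         results = list(panel = panel, records = records,
                        retained = retained, network = network,
                        target_sets = all_sets, similarity = S,
                        pair_report = report_pairs,
                        clustering = clust, structural = structural)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  c_ <- x$counts
  cat("bindexnet run report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  drugs: %d in, %d after QC; genes: %d\n",
              c_$drugs_in, c_$drugs_after_qc, c_$genes))
  cat(sprintf("  tested pairs: %d; retained edges: %d\n",
              c_$tested_pairs, c_$retained_edges))
  cat(sprintf("  network: %d drug nodes, %d gene nodes, %d edges\n",
              c_$network_drug_nodes, c_$network_gene_nodes,
              c_$network_edges))
  if (!is.na(c_$pairs_shared_ge1))
    cat(sprintf("  drug pairs: %d sharing >= 1 target, %d disjoint\n",
                c_$pairs_shared_ge1, c_$pairs_shared_eq0))
  if (!is.na(c_$k)) cat(sprintf("  clusters: k = %d\n", c_$k))
  cat(sprintf("  artifacts: %d files under %s\n", nrow(x$manifest),
              x$outdir))
  invisible(x)
}

#' Aligned activity/expression profile table for one drug-gene pair
#'
#' Emits the per-cell-line table behind a profile plot: activity and
#' expression z-scores side by side, ordered by tissue group in the
#' configured label order.
#'
#' @param expression,activity Profile matrices sharing cell-line columns.
#' @param drug_id,gene_id Row ids to extract.
#' @param tissue_labels Factor (or character) of tissue per cell line, in
#'   panel column order; its level order defines the output ordering.
#' @return A data.frame with columns `cell_line`, `tissue`, `activity_z`,
#'   `expression_z`, one row per cell line.
#' @export
profile_pair_table <- function(expression, activity, drug_id, gene_id,
                               tissue_labels) {
  if (!gene_id %in% rownames(expression))
    stop("unknown gene id: ", gene_id)
  if (!drug_id %in% rownames(activity))
    stop("unknown drug id: ", drug_id)
  stopifnot(identical(colnames(expression), colnames(activity)),
            length(tissue_labels) == ncol(expression))
  if (!is.factor(tissue_labels))
    tissue_labels <- factor(tissue_labels, levels = unique(tissue_labels))
  df <- data.frame(cell_line = colnames(expression),
                   tissue = tissue_labels,
                   activity_z = activity[drug_id, ],
                   expression_z = expression[gene_id, ],
                   stringsAsFactors = FALSE)
  df[order(df$tissue), , drop = FALSE]
}
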