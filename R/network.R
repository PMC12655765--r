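# Bipartite drug-gene network assembly and export (igraph-backed).
#
# Node attributes: `kind` ("drug"/"gene"), `category` (gene class:
# oncogene/tsg/fusion/other; NA for drugs), and the igraph bipartite
# `type` flag (FALSE = drug, TRUE = gene). Edge attributes: `weight`
# (signed Pearson r) and `holm_p`.

GENE_CATEGORIES <- c("oncogene", "tsg", "fusion", "other")

#' Build a bipartite drug-gene network from retained correlations
#'
#' Node sets are exactly the drugs and genes appearing in the retained
#' records (drugs or genes with no retained edge do not enter the
#' network); there is one edge per record, weighted by the signed Pearson
#' correlation. Gene categories come from the annotation table; genes
#' without an annotation default to `"other"`.
#'
#' @param records Retained correlation records (see [filter_records()]).
#' @param annotations Optional data.frame with columns `gene_id` and
#'   `category` (one of `"oncogene"`, `"tsg"`, `"fusion"`, `"other"`).
#' @return An igraph object with the attribute scheme described above.
#' @export
build_network <- function(records, annotations = NULL) {
  if (nrow(records) &&
      anyDuplicated(records[, c("drug_id", "gene_id")]))
    stop("duplicate (drug, gene) records")
  if (!is.null(annotations)) {
    stopifnot(all(c("gene_id", "category") %in% names(annotations)))
    bad <- setdiff(unique(annotations$category), GENE_CATEGORIES)
    if (length(bad))
      stop("unknown gene categories: ", paste(bad, collapse = ", "))
  }
  drugs <- unique(records$drug_id)
  genes <- unique(records$gene_id)
  cat_of <- stats::setNames(rep("other", length(genes)), genes)
  if (!is.null(annotations)) {
    hit <- intersect(genes, annotations$gene_id)
    cat_of[hit] <- annotations$category[match(hit, annotations$gene_id)]
  }
  vertices <- data.frame(
    name = c(drugs, genes),
    kind = rep(c("drug", "gene"), c(length(drugs), length(genes))),
    category = c(rep(NA_character_, length(drugs)), unname(cat_of)),
    type = rep(c(FALSE, TRUE), c(length(drugs), length(genes))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = records$drug_id, to = records$gene_id,
                      weight = records$pearson_r,
                      holm_p = records$holm_p,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  assert_bipartite(g)
  g
}

# structural check used on every construction and import
assert_bipartite <- function(g) {
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    kind <- igraph::V(g)$kind
    if (any(kind[ends[, 1]] == kind[ends[, 2]]))
      stop("network is not bipartite: an edge joins two nodes of one kind")
  }
  if (igraph::vcount(g) > 0 && any(igraph::degree(g) == 0))
    stop("network contains isolated nodes")
  invisible(g)
}

#' Per-drug target sets of a network
#'
#' @param network A bipartite network from [build_network()].
#' @return Named list mapping each drug id to the character vector of its
#'   gene neighbours.
#' @export
target_sets <- function(network) {
  drugs <- igraph::V(network)$name[igraph::V(network)$kind == "drug"]
  out <- lapply(drugs, function(d)
    igraph::neighbors(network, d)$name)
  stats::setNames(out, drugs)
}

#' Induced subnetwork for a set of drugs
#'
#' Keeps the chosen drugs and all their gene neighbours (e.g. the drug
#' groups examined as subnetworks after clustering).
#'
#' @param network A bipartite network.
#' @param drugs Character vector of drug ids present in the network.
#' @return The induced bipartite subgraph.
#' @export
extract_subnetwork <- function(network, drugs) {
  have <- igraph::V(network)$name[igraph::V(network)$kind == "drug"]
  missing <- setdiff(drugs, have)
  if (length(missing))
    stop("unknown drug id(s): ", paste(missing, collapse = ", "))
  genes <- unique(unlist(lapply(drugs, function(d)
    igraph::neighbors(network, d)$name)))
  sub <- igraph::induced_subgraph(network, c(drugs, genes))
  assert_bipartite(sub)
  sub
}

#' Node degree summary
#'
#' @param network A bipartite network.
#' @return A data.frame with columns `node`, `type` (drug/gene) and
#'   `degree`; drug degrees and gene degrees each sum to the edge count.
#' @export
degree_summary <- function(network) {
  if (igraph::vcount(network) == 0)
    return(data.frame(node = character(0), type = character(0),
                      degree = integer(0), stringsAsFactors = FALSE))
  data.frame(node = igraph::V(network)$name,
             type = igraph::V(network)$kind,
             degree = unname(igraph::degree(network)),
             stringsAsFactors = FALSE)
}

#' Export a network
#'
#' `write_network_graphml()` writes GraphML preserving the node `kind`,
#' gene `category` and edge `weight`/`holm_p` attributes;
#' `read_network_graphml()` reads it back and re-checks bipartiteness.
#' `write_network_sif()` writes the simple interaction format
#' (`drug targets gene`); `write_edge_table()` writes a flat TSV.
#'
#' @param network A bipartite network.
#' @param path Output path.
#' @return `path` (writers, invisibly) or an igraph object (reader).
#' @export
write_network_graphml <- function(network, path) {
  g <- network
  # GraphML cannot carry NA strings; encode drug category explicitly
  igraph::V(g)$category <- ifelse(is.na(igraph::V(g)$category), "",
                                  igraph::V(g)$category)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::V(g)$category <- ifelse(igraph::V(g)$category == "",
                                  NA_character_, igraph::V(g)$category)
  igraph::V(g)$type <- igraph::V(g)$kind == "gene"
  assert_bipartite(g)
  g
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  ends <- igraph::ends(network, igraph::E(network))
  kind <- igraph::V(network)$kind[match(ends[, 1], igraph::V(network)$name)]
  drug_first <- ifelse(kind == "drug", 1L, 2L)
  lines <- vapply(seq_len(nrow(ends)), function(i) {
    d <- ends[i, drug_first[i]]
    g <- ends[i, 3L - drug_first[i]]
    paste(d, "targets", g, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_table <- function(network, path) {
  ends <- igraph::ends(network, igraph::E(network))
  kind <- igraph::V(network)$kind[match(ends[, 1], igraph::V(network)$name)]
  drug_first <- kind == "drug"
  df <- data.frame(
    drug_id = ifelse(drug_first, ends[, 1], ends[, 2]),
    gene_id = ifelse(drug_first, ends[, 2], ends[, 1]),
    weight = igraph::E(network)$weight,
    holm_p = igraph::E(network)$holm_p,
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
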