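# Chemical structural similarity from SMILES: path-based fingerprint
# Tanimoto, maximum-common-substructure coefficients, and concordance of
# structural clustering with pharmacogenomic clustering.

#' Load compounds from a SMILES file
#'
#' Accepts `.smi` dialect (one `SMILES<whitespace>id` per line; `#` lines
#' and blanks skipped) or a TSV with the same two columns. Each SMILES is
#' parsed to a molecule; lines that fail to parse (or parse to zero heavy
#' atoms) are collected in the attribute `"errors"` rather than aborting
#' the load.
#'
#' @param path Path to the SMILES file.
#' @return A list of `compound` records (fields `drug_id`, `smiles`,
#'   `atoms`, `bonds`, `n_heavy`), with attribute `"errors"` (data.frame
#'   of skipped lines). Zero valid records is an error.
#' @export
load_compounds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # tolerate a header row from TSV exports
  if (length(lines) && grepl("^smiles\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) stop("no compound lines in ", path)
  recs <- list()
  errs <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    smi <- tok[1]
    id <- if (length(tok) >= 2L) tok[2] else sprintf("cmpd%03d", i)
    rec <- tryCatch(parse_compound(id, smi), error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = i, id = id, smiles = smi, message = conditionMessage(rec),
        stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (!length(recs)) stop("no valid compounds parsed from ", path)
  names(recs) <- vapply(recs, `[[`, "", "drug_id")
  attr(recs, "errors") <- if (length(errs)) do.call(rbind, errs)
    else data.frame(line = integer(0), id = character(0),
                    smiles = character(0), message = character(0))
  recs
}

#' Parse a single SMILES string into a compound record
#'
#' @param drug_id Compound identifier.
#' @param smiles SMILES string; must parse to at least one heavy atom.
#' @return A `compound` record: `drug_id`, `smiles`, `atoms` (element
#'   symbols of heavy atoms), `bonds` (data.frame `a`, `b`, `order`) and
#'   `n_heavy`.
#' @export
parse_compound <- function(drug_id, smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, drug_id)))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L)
    stop("SMILES parsed to zero atoms: ", smiles)
  elements <- gsub("_\\d+$", "", rownames(ab))
  heavy <- which(toupper(elements) != "H")
  if (!length(heavy)) stop("SMILES has no heavy atoms: ", smiles)
  bb <- ChemmineR::bondblock(mol)
  if (!is.null(bb) && length(dim(bb)) != 2L) bb <- NULL  # atom-only molecule
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    idx <- match(seq_len(nrow(ab)), heavy)   # old index -> heavy index
    keep <- bb[, 1] %in% heavy & bb[, 2] %in% heavy
    data.frame(a = idx[bb[keep, 1]], b = idx[bb[keep, 2]],
               order = as.integer(bb[keep, 3]))
  }
  structure(list(drug_id = drug_id, smiles = smiles,
                 atoms = elements[heavy], bonds = bonds,
                 n_heavy = length(heavy)),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("compound %s: %d heavy atoms, %d bonds (%s)\n",
              x$drug_id, x$n_heavy, nrow(x$bonds), x$smiles))
  invisible(x)
}

# binary fingerprint via Open Babel; FP2 is the 1024-bit path-based kind
ob_fingerprint <- function(smiles, fp_kind = "FP2") {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)[[1]]
  as.logical(ChemmineOB::fingerprint_OB(list(mol), fp_kind))
}

#' Fingerprint Tanimoto similarity
#'
#' Bit-set intersection over union of binary molecular fingerprints. The
#' default `"FP2"` is the path-based 1024-bit fingerprint (linear
#' fragments up to length 7); `"FP3"`, `"FP4"` and `"MACCS"` are also
#' accepted. Different fingerprint dialects give systematically different
#' absolute values, so Tanimoto values should only be compared within one
#' kind.
#'
#' @param a,b `compound` records (or SMILES strings).
#' @param fp_kind Fingerprint kind understood by Open Babel.
#' @return Tanimoto coefficient in `[0, 1]`.
#' @export
fingerprint_tanimoto <- function(a, b, fp_kind = "FP2") {
  sa <- if (inherits(a, "compound")) a$smiles else a
  sb <- if (inherits(b, "compound")) b$smiles else b
  fa <- ob_fingerprint(sa, fp_kind)
  fb <- ob_fingerprint(sb, fp_kind)
  u <- sum(fa | fb)
  if (u == 0L) return(0)
  sum(fa & fb) / u
}

#' Maximum common substructure coefficients
#'
#' Finds a maximum common connected substructure between two molecules by
#' exact backtracking over atom mappings (elements must match, bond
#' orders must match on mapped bonds, and adjacency is preserved in both
#' directions), and derives
#' `mcs_tanimoto = m / (n_a + n_b - m)` and
#' `mcs_overlap = m / min(n_a, n_b)`,
#' where `m` is the MCS heavy-atom count and `n` the heavy-atom counts.
#' Small label mismatches can be tolerated via the budgets
#' `atom_mismatch` / `bond_mismatch`. The search is exponential in the
#' worst case; if `max_steps` is exhausted the pair is flagged
#' (`timeout = TRUE`) and the coefficients are `NA`.
#'
#' @param a,b `compound` records.
#' @param atom_mismatch,bond_mismatch Number of element / bond-order
#'   mismatches tolerated inside the mapping (default 0).
#' @param max_steps Search-node budget before giving up.
#' @return One-row data.frame: `drug_a`, `drug_b`, `mcs_atoms`,
#'   `mcs_tanimoto`, `mcs_overlap`, `timeout`.
#' @export
mcs_coefficients <- function(a, b, atom_mismatch = 0L, bond_mismatch = 0L,
                             max_steps = 2e5) {
  stopifnot(inherits(a, "compound"), inherits(b, "compound"))
  # canonical order (smaller molecule drives the search) keeps the result
  # symmetric even under the step cap
  swap <- a$n_heavy > b$n_heavy ||
    (a$n_heavy == b$n_heavy && a$drug_id > b$drug_id)
  g1 <- if (swap) b else a
  g2 <- if (swap) a else b
  m <- mcs_size(g1, g2, atom_mismatch, bond_mismatch, max_steps)
  out <- data.frame(drug_a = a$drug_id, drug_b = b$drug_id,
                    mcs_atoms = NA_integer_, mcs_tanimoto = NA_real_,
                    mcs_overlap = NA_real_, timeout = is.na(m),
                    stringsAsFactors = FALSE)
  if (!is.na(m)) {
    out$mcs_atoms <- m
    out$mcs_tanimoto <- m / (a$n_heavy + b$n_heavy - m)
    out$mcs_overlap <- m / min(a$n_heavy, b$n_heavy)
  }
  out
}

# adjacency structure for the MCS search
mol_adj <- function(g) {
  n <- g$n_heavy
  ord <- matrix(0L, n, n)
  if (nrow(g$bonds))
    for (i in seq_len(nrow(g$bonds))) {
      ord[g$bonds$a[i], g$bonds$b[i]] <- g$bonds$order[i]
      ord[g$bonds$b[i], g$bonds$a[i]] <- g$bonds$order[i]
    }
  ord
}

# Exact maximum common connected induced substructure (atom count), by
# seeded McGregor-style backtracking with a best-so-far bound.
# Returns NA if the step budget is exhausted.
mcs_size <- function(g1, g2, atom_mismatch = 0L, bond_mismatch = 0L,
                     max_steps = 2e5) {
  n1 <- g1$n_heavy; n2 <- g2$n_heavy
  A1 <- mol_adj(g1); A2 <- mol_adj(g2)
  el1 <- g1$atoms; el2 <- g2$atoms
  best <- 0L
  steps <- 0L
  overrun <- FALSE

  extend <- function(map, used2, am_left, bm_left) {
    # map: integer vector length n1, 0 = unmapped
    size <- sum(map > 0L)
    if (size > best) best <<- size
    if (steps >= max_steps) { overrun <<- TRUE; return() }
    steps <<- steps + 1L
    if (size + min(n1 - size, n2 - sum(used2)) <= best) return()
    mapped1 <- which(map > 0L)
    # frontier: unmapped atoms adjacent to the mapped set (connectedness)
    cand1 <- which(map == 0L &
                   colSums(A1[mapped1, , drop = FALSE] > 0) > 0)
    if (!length(cand1)) return()
    a <- cand1[1]                      # fixed pivot: complete search, less
                                       # duplication than trying all pivots
    nbr_a <- which(A1[a, ] > 0 & map > 0L)
    for (b in which(!used2)) {
      am_cost <- as.integer(el1[a] != el2[b])
      if (am_cost > am_left) next
      # induced consistency against every mapped atom
      ok <- TRUE; bm_cost <- 0L
      for (a2 in mapped1) {
        o1 <- A1[a, a2]; o2 <- A2[b, map[a2]]
        if ((o1 > 0) != (o2 > 0)) { ok <- FALSE; break }
        if (o1 > 0 && o1 != o2) bm_cost <- bm_cost + 1L
      }
      if (!ok || bm_cost > bm_left) next
      if (!any(A2[b, map[nbr_a]] > 0) && length(nbr_a)) next
      map[a] <- b; used2[b] <- TRUE
      extend(map, used2, am_left - am_cost, bm_left - bm_cost)
      map[a] <- 0L; used2[b] <- FALSE
    }
    # also allow skipping atom a entirely (it need not be in the MCS):
    # mark as excluded by searching the remaining frontier without it
    map[a] <- -1L
    extend(map, used2, am_left, bm_left)
  }

  # seeds: every compatible atom pair (connected growth from each seed)
  for (a in seq_len(n1)) {
    for (b in seq_len(n2)) {
      if (atom_mismatch == 0L && el1[a] != el2[b]) next
      map <- integer(n1)
      used2 <- logical(n2)
      map[a] <- b; used2[b] <- TRUE
      am0 <- atom_mismatch - as.integer(el1[a] != el2[b])
      if (am0 < 0L) next
      extend(map, used2, am0, bond_mismatch)
      if (overrun) return(NA_integer_)
    }
  }
  best
}

#' Pairwise structural similarity over a compound set
#'
#' Computes the fingerprint-Tanimoto, MCS-Tanimoto and MCS-overlap
#' coefficients for every compound pair. Returns symmetric matrices (unit
#' diagonal) and the full square pair table with one row per *ordered*
#' pair, self-comparisons included (`n^2` rows for `n` compounds).
#'
#' @param records Compound list from [load_compounds()].
#' @param fp_kind Fingerprint kind (see [fingerprint_tanimoto()]).
#' @param atom_mismatch,bond_mismatch,max_steps Passed to
#'   [mcs_coefficients()].
#' @return A list with `similarity` (named list of three matrices) and
#'   `pairs` (data.frame with `drug_a`, `drug_b`, `fp_tanimoto`,
#'   `mcs_atoms`, `mcs_tanimoto`, `mcs_overlap`).
#' @export
pairwise_structural <- function(records, fp_kind = "FP2",
                                atom_mismatch = 0L, bond_mismatch = 0L,
                                max_steps = 2e5) {
  stopifnot(length(records) >= 2L)
  ids <- vapply(records, `[[`, "", "drug_id")
  n <- length(ids)
  fps <- lapply(records, function(r) ob_fingerprint(r$smiles, fp_kind))
  tan <- function(fa, fb) {
    u <- sum(fa | fb); if (u == 0L) 0 else sum(fa & fb) / u
  }
  M_fp <- diag(1, n); M_mt <- diag(1, n); M_mo <- diag(1, n)
  MA <- matrix(NA_integer_, n, n)
  diag(MA) <- vapply(records, `[[`, 0L, "n_heavy")
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    M_fp[i, j] <- M_fp[j, i] <- tan(fps[[i]], fps[[j]])
    mc <- mcs_coefficients(records[[i]], records[[j]], atom_mismatch,
                           bond_mismatch, max_steps)
    MA[i, j] <- MA[j, i] <- mc$mcs_atoms
    M_mt[i, j] <- M_mt[j, i] <- mc$mcs_tanimoto
    M_mo[i, j] <- M_mo[j, i] <- mc$mcs_overlap
  }
  dimnames(M_fp) <- dimnames(M_mt) <- dimnames(M_mo) <-
    dimnames(MA) <- list(ids, ids)
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))   # row-major in i
  pairs <- data.frame(
    drug_a = ids[idx$i], drug_b = ids[idx$j],
    fp_tanimoto = M_fp[cbind(idx$i, idx$j)],
    mcs_atoms = MA[cbind(idx$i, idx$j)],
    mcs_tanimoto = M_mt[cbind(idx$i, idx$j)],
    mcs_overlap = M_mo[cbind(idx$i, idx$j)],
    stringsAsFactors = FALSE)
  list(similarity = list(fp_tanimoto = M_fp, mcs_tanimoto = M_mt,
                         mcs_overlap = M_mo),
       pairs = pairs)
}

#' Pick the structural matrix that best supports a hierarchy
#'
#' Clusters each candidate similarity matrix with average linkage and
#' returns the name of the one with the highest cophenetic correlation
#' (i.e. whose pairwise distances a dendrogram preserves best).
#'
#' @param sim_list Named list of similarity matrices in `[0, 1]`.
#' @return The name of the selected matrix, with the per-matrix
#'   cophenetic correlations attached as attribute `"cophenetic"`.
#' @export
best_structural_matrix <- function(sim_list) {
  stopifnot(length(sim_list) >= 1L, !is.null(names(sim_list)))
  cc <- vapply(sim_list, function(S) {
    S <- ifelse(is.na(S), 0, S)
    D <- to_distance(S)
    tr <- stats::hclust(stats::as.dist(D), method = "average")
    cophenetic_correlation(tr, D)
  }, numeric(1))
  structure(names(cc)[which.max(cc)], cophenetic = cc)
}

#' Concordance of two partitions
#'
#' Adjusted Rand index (chance-corrected pair agreement) plus the full
#' contingency table between two clusterings of the same items, used to
#' score pharmacogenomic clusters against structural clusters.
#'
#' @param p1,p2 Named vectors of cluster labels over the same ids.
#' @return A list with `adjusted_rand` and `contingency`.
#' @export
cluster_concordance <- function(p1, p2) {
  stopifnot(!is.null(names(p1)), !is.null(names(p2)))
  if (!setequal(names(p1), names(p2)))
    stop("partitions cover different id sets")
  p2 <- p2[names(p1)]
  list(adjusted_rand = mclust::adjustedRandIndex(p1, p2),
       contingency = table(cluster1 = p1, cluster2 = p2))
}
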