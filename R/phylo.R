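# Distance-based tree building, reference-vote subfamily assignment, and
# gene-structure statistics.

clamp_negative_edges <- function(phy) {
  # Negative NJ branch lengths are set to zero and the deficit moved to the
  # sister edge sharing the same parent node, preserving path lengths
  # through the parent as far as possible.
  el <- phy$edge.length
  for (i in seq_along(el)) {
    if (el[i] < 0) {
      parent <- phy$edge[i, 1]
      sisters <- which(phy$edge[, 1] == parent & seq_along(el) != i)
      if (length(sisters)) {
        el[sisters[1]] <- el[sisters[1]] + el[i]
      }
      el[i] <- 0
    }
  }
  el[el < 0] <- 0
  phy$edge.length <- el
  phy
}

pdistance_from_characters <- function(x) {
  # x: matrix of single characters, rows = taxa. Proportion of differing
  # columns; columns where either row has a gap are ignored for that pair.
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- x[i, ] != "-" & x[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(x[i, ok] != x[j, ok]) else 0
    }
  }
  d
}

#' Neighbor-joining tree with optional nonparametric bootstrap
#'
#' Canonical NJ agglomeration via [ape::nj]; negative branch lengths are
#' clamped to zero with the deficit transferred to the sister edge. When an
#' alignment is supplied and `bootstrap_n > 0`, columns are resampled with
#' replacement, p-distances recomputed, and each internal edge is annotated
#' with the percentage of replicates containing its bipartition
#' (`ape::boot.phylo`).
#'
#' @param d Symmetric distance matrix with >= 3 labelled rows.
#' @param bootstrap_n Number of bootstrap replicates (default 0 = none).
#' @param alignment Optional character matrix (taxa x aligned columns, gaps
#'   as `"-"`) from which `d` was derived; required when `bootstrap_n > 0`.
#' @param seed RNG seed for the resampling.
#' @return An [ape::phylo] tree; bootstrap supports (0-100) in
#'   `$node.label` when computed.
#' @export
nj_tree <- function(d, bootstrap_n = 0, alignment = NULL, seed = 17) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (nrow(d) < 3) stop("need >= 3 leaves")
  phy <- clamp_negative_edges(ape::nj(as.dist(d)))
  if (bootstrap_n > 0) {
    if (is.null(alignment)) {
      stop("bootstrap requires the source alignment (taxa x columns matrix)")
    }
    if (!all(rownames(alignment) %in% rownames(d))) {
      stop("alignment rows must match distance-matrix labels")
    }
    alignment <- alignment[rownames(d), , drop = FALSE]
    counts <- withr::with_seed(seed, ape::boot.phylo(
      phy, alignment,
      function(xx) clamp_negative_edges(ape::nj(as.dist(pdistance_from_characters(xx)))),
      B = bootstrap_n, quiet = TRUE))
    counts[is.na(counts)] <- bootstrap_n  # trivial (root) bipartition
    phy$node.label <- round(100 * counts / bootstrap_n)
  }
  phy
}

#' Assign subfamilies by k-nearest labelled references
#'
#' Each query is assigned the majority label among its `k` nearest
#' references by p-distance (1 - alignment identity). Vote ties are broken
#' in favour of the label with the smaller minimum distance; residual ties
#' are flagged ambiguous. Missing catalog subfamilies in the reference set
#' raise a warning, not an error.
#'
#' @param queries Named character vector / `AAStringSet` of query proteins.
#' @param references Named character vector / `AAStringSet` of reference
#'   proteins.
#' @param labels Character vector of subfamily labels, one per reference
#'   (recycled from `names(references)` patterns is not attempted).
#' @param k Number of neighbours (default 3).
#' @param catalog Subfamily catalog used for the completeness warning.
#' @return Data frame with `gene_id`, `subfamily`, `family` (group label),
#'   `support` (vote fraction), `ambiguous`.
#' @export
assign_subfamily <- function(queries, references, labels, k = 3,
                             catalog = SUBFAMILY_CATALOG) {
  if (k < 1) stop("k must be >= 1")
  if (length(labels) != length(references)) {
    stop("one label per reference required")
  }
  missing <- setdiff(catalog, unique(labels))
  if (length(missing)) {
    warning("reference set lacks subfamilies: ", paste(missing, collapse = ", "))
  }
  qset <- if (methods::is(queries, "AAStringSet")) queries
          else Biostrings::AAStringSet(vapply(queries, as.character, ""))
  rset <- if (methods::is(references, "AAStringSet")) references
          else Biostrings::AAStringSet(vapply(references, as.character, ""))
  out <- vector("list", length(qset))
  for (qi in seq_along(qset)) {
    aln <- Biostrings::pairwiseAlignment(
      rset, qset[[qi]], substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global")
    dist <- 1 - Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    ord <- order(dist, labels)  # label order as deterministic final tie-break
    kk <- min(k, length(dist))
    top <- ord[seq_len(kk)]
    votes <- table(labels[top])
    best <- max(votes)
    winners <- names(votes)[votes == best]
    ambiguous <- FALSE
    if (length(winners) > 1) {
      mins <- vapply(winners, function(l) min(dist[top][labels[top] == l]),
                     numeric(1))
      closest <- winners[mins == min(mins)]
      ambiguous <- length(closest) > 1
      winners <- closest[1]
    }
    out[[qi]] <- data.frame(
      gene_id = names(qset)[qi], subfamily = winners[1],
      family = unname(SUBFAMILY_GROUP[winners[1]]),
      support = best / kk, ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Exon/intron statistics per gene model
#'
#' @param gene_models List of gene models (as produced by
#'   [generate_genome()] / [read_bundle()]): each a list with `gene_id`,
#'   `exons` (matrix of 0-based half-open genomic intervals, sorted).
#' @return Data frame with `gene_id`, `n_exons`, `n_introns_in_cds`,
#'   `cds_span` (bp, genomic extent), `has_utr_annotation`, `intronless`.
#' @export
gene_structure_stats <- function(gene_models) {
  out <- lapply(gene_models, function(gm) {
    ex <- gm$exons
    if (is.null(dim(ex))) ex <- matrix(ex, ncol = 2)
    ord <- order(ex[, 1])
    ex <- ex[ord, , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("overlapping CDS segments in gene ", gm$gene_id)
    }
    data.frame(gene_id = gm$gene_id,
               n_exons = nrow(ex),
               n_introns_in_cds = nrow(ex) - 1L,
               cds_span = max(ex[, 2]) - min(ex[, 1]),
               has_utr_annotation = isTRUE(gm$has_utr),
               intronless = nrow(ex) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
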