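# Duplication-mode analysis: all-vs-all homolog pairs, tandem arrays by
# gene-order adjacency, WGD/segmental blocks by monotonic anchor chaining,
# and per-gene mode classification.

#' All-vs-all homologous pairs within a protein set
#'
#' Pairs are retained iff alignment identity >= `min_identity` and score >=
#' `min_score`; the relation is symmetric and self-free, and each pair is
#' stored once with the lexicographically smaller id first.
#'
#' @param proteins Named character vector or `AAStringSet` (>= 2).
#' @param min_identity Identity cutoff, default 0.4.
#' @param min_score Alignment score cutoff, default 0 bits.
#' @param idm Optional precomputed result of [protein_identity_matrix()]
#'   (avoids re-aligning in pipelines).
#' @return Data frame with `gene_a`, `gene_b`, `identity`, `score`.
#' @export
find_homolog_pairs <- function(proteins, min_identity = 0.4, min_score = 0,
                               idm = NULL) {
  if (is.null(idm)) {
    if (length(proteins) < 2) stop("need >= 2 proteins")
    idm <- protein_identity_matrix(proteins)
  }
  ids <- rownames(idm$identity)
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (idm$identity[i, j] >= min_identity && idm$score[i, j] >= min_score) {
        a <- ids[i]; b <- ids[j]
        if (b < a) { tmp <- a; a <- b; b <- tmp }
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = a, gene_b = b, identity = idm$identity[i, j],
          score = idm$score[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# gene_order: data.frame(gene_id, chromosome, rank, is_family) covering all
# annotated genes; rank is the 1-based gene index along its chromosome.
check_gene_order <- function(gene_order, genes) {
  missing <- setdiff(genes, gene_order$gene_id)
  if (length(missing)) {
    stop("gene(s) missing from gene order: ", paste(missing, collapse = ", "))
  }
}

intervening_nonfamily <- function(gene_order, chrom, r1, r2) {
  lo <- min(r1, r2); hi <- max(r1, r2)
  sum(gene_order$chromosome == chrom & gene_order$rank > lo &
        gene_order$rank < hi & !gene_order$is_family)
}

#' Detect tandem arrays by gene-order adjacency
#'
#' Builds a graph with an edge between homologous family genes on the same
#' chromosome separated by at most `max_gap` intervening non-family genes;
#' arrays are the connected components of size >= 2, ordered along the
#' chromosome.
#'
#' @param pairs Homolog pairs from [find_homolog_pairs()].
#' @param gene_order Data frame with `gene_id`, `chromosome`, `rank`,
#'   `is_family` covering every annotated gene.
#' @param max_gap Maximum intervening non-family genes (default 1).
#' @return Data frame with `array_id`, `chromosome`, `gene_id`, `rank`,
#'   `is_representative` (lowest rank in the array), `max_gap_used`.
#' @export
detect_tandem <- function(pairs, gene_order, max_gap = 1) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  check_gene_order(gene_order, unique(c(pairs$gene_a, pairs$gene_b)))
  ord <- gene_order
  rank_of <- stats::setNames(ord$rank, ord$gene_id)
  chrom_of <- stats::setNames(ord$chromosome, ord$gene_id)
  keep <- which(chrom_of[pairs$gene_a] == chrom_of[pairs$gene_b])
  edges <- list()
  for (k in keep) {
    a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
    gap <- intervening_nonfamily(ord, chrom_of[[a]], rank_of[[a]], rank_of[[b]])
    if (gap <= max_gap) edges[[length(edges) + 1]] <- c(a, b)
  }
  empty <- data.frame(array_id = character(), chromosome = character(),
                      gene_id = character(), rank = integer(),
                      is_representative = logical(), max_gap_used = integer(),
                      stringsAsFactors = FALSE)
  if (!length(edges)) return(empty)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- Filter(function(m) length(m) >= 2, members)
  if (!length(members)) return(empty)
  # deterministic array ids ordered by (chromosome, first rank)
  keyed <- lapply(members, function(m) {
    m <- m[order(rank_of[m])]
    list(chrom = chrom_of[[m[1]]], first = rank_of[[m[1]]], genes = m)
  })
  keyed <- keyed[order(vapply(keyed, `[[`, "", "chrom"),
                       vapply(keyed, `[[`, 0, "first"))]
  rows <- lapply(seq_along(keyed), function(i) {
    k <- keyed[[i]]
    data.frame(array_id = sprintf("TA%02d", i), chromosome = k$chrom,
               gene_id = k$genes, rank = unname(rank_of[k$genes]),
               is_representative = seq_along(k$genes) == 1,
               max_gap_used = max_gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Longest monotonic chain of anchors (ra strictly increasing; rb strictly
# increasing or decreasing) with consecutive rank gaps <= max_rank_gap on
# both sides. O(n^2) dynamic program; deterministic backtracking.
best_chain <- function(ra, rb, max_rank_gap) {
  n <- length(ra)
  best <- NULL
  for (dir in c(1, -1)) {
    ord <- order(ra, dir * rb)
    a <- ra[ord]; b <- rb[ord]
    len <- rep(1L, n); prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok <- a[j] < a[i] && (a[i] - a[j]) <= max_rank_gap &&
          ((dir == 1 && b[j] < b[i] && (b[i] - b[j]) <= max_rank_gap) ||
           (dir == -1 && b[j] > b[i] && (b[j] - b[i]) <= max_rank_gap))
        if (ok && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    end <- which.max(len)
    chain <- integer(0)
    k <- end
    while (k != 0L) { chain <- c(k, chain); k <- prev[k] }
    chain_idx <- ord[chain]
    cand <- list(idx = chain_idx, length = len[end],
                 orientation = if (dir == 1) "same" else "inverted",
                 first_rank = ra[chain_idx[1]])
    better <- is.null(best) || cand$length > best$length ||
      (cand$length == best$length && best$orientation == "inverted" &&
         cand$orientation == "same") ||
      (cand$length == best$length && cand$orientation == best$orientation &&
         cand$first_rank < best$first_rank)
    if (better) best <- cand
  }
  best
}

#' Detect WGD/segmental duplications by collinearity anchor chaining
#'
#' For every chromosome pair (including a chromosome with itself), anchors
#' are chained by a dynamic program maximising anchor count under strict
#' rank monotonicity on both chromosomes and a maximum consecutive rank
#' gap; disjoint chains with at least `min_anchors` anchors are emitted
#' greedily by descending length, removing used anchors before re-searching.
#'
#' Following MCScanX practice, anchors must be recent duplicates
#' (`anchor_min_identity`), and genes listed in `exclude_genes` (typically
#' non-representative tandem-array members) are not allowed to anchor
#' blocks; tandem-proximal pairs (same chromosome within `tandem_max_gap`
#' intervening non-family genes) are likewise excluded.
#'
#' @param pairs Homolog pairs from [find_homolog_pairs()].
#' @param gene_order As in [detect_tandem()].
#' @param min_anchors Minimum anchors per block (default 3 at desk scale;
#'   the conventional genome-scale value is 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @param anchor_min_identity Identity floor for anchor pairs (default 0.7).
#' @param exclude_genes Genes barred from anchoring (default none).
#' @param tandem_max_gap Gap used to discard tandem-proximal same-chromosome
#'   pairs (default 1).
#' @return List with `blocks` (data frame: `block_id`, `chromosome_a`,
#'   `chromosome_b`, `orientation`, `n_anchors`) and `anchors` (data frame:
#'   `block_id`, `gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
detect_collinear_blocks <- function(pairs, gene_order, min_anchors = 3,
                                    max_rank_gap = 25,
                                    anchor_min_identity = 0.7,
                                    exclude_genes = character(),
                                    tandem_max_gap = 1) {
  if (min_anchors < 2) stop("min_anchors must be >= 2")
  check_gene_order(gene_order, unique(c(pairs$gene_a, pairs$gene_b)))
  rank_of <- stats::setNames(gene_order$rank, gene_order$gene_id)
  chrom_of <- stats::setNames(gene_order$chromosome, gene_order$gene_id)
  p <- pairs[pairs$identity >= anchor_min_identity &
               !(pairs$gene_a %in% exclude_genes) &
               !(pairs$gene_b %in% exclude_genes), , drop = FALSE]
  if (nrow(p)) {
    ca <- chrom_of[p$gene_a]; cb <- chrom_of[p$gene_b]
    # orient each anchor so chromosome_a <= chromosome_b (rank as tiebreak)
    swap <- ca > cb | (ca == cb & rank_of[p$gene_a] > rank_of[p$gene_b])
    tmp <- p$gene_a[swap]; p$gene_a[swap] <- p$gene_b[swap]; p$gene_b[swap] <- tmp
    p$chrom_a <- unname(chrom_of[p$gene_a])
    p$chrom_b <- unname(chrom_of[p$gene_b])
    p$rank_a <- unname(rank_of[p$gene_a])
    p$rank_b <- unname(rank_of[p$gene_b])
    # drop tandem-proximal same-chromosome pairs
    same <- p$chrom_a == p$chrom_b
    if (any(same)) {
      gaps <- vapply(which(same), function(k) {
        intervening_nonfamily(gene_order, p$chrom_a[k], p$rank_a[k], p$rank_b[k])
      }, numeric(1))
      p <- p[!same | replace(rep(Inf, nrow(p)), which(same), gaps) > tandem_max_gap, ,
             drop = FALSE]
    }
  }
  blocks <- list(); anchors <- list()
  if (nrow(p)) {
    chrom_pairs <- unique(p[, c("chrom_a", "chrom_b")])
    chrom_pairs <- chrom_pairs[order(chrom_pairs$chrom_a, chrom_pairs$chrom_b), ,
                               drop = FALSE]
    for (cp in seq_len(nrow(chrom_pairs))) {
      sub <- p[p$chrom_a == chrom_pairs$chrom_a[cp] &
                 p$chrom_b == chrom_pairs$chrom_b[cp], , drop = FALSE]
      repeat {
        if (nrow(sub) < min_anchors) break
        ch <- best_chain(sub$rank_a, sub$rank_b, max_rank_gap)
        if (ch$length < min_anchors) break
        bid <- sprintf("CB%02d", length(blocks) + 1)
        blocks[[length(blocks) + 1]] <- data.frame(
          block_id = bid,
          chromosome_a = chrom_pairs$chrom_a[cp],
          chromosome_b = chrom_pairs$chrom_b[cp],
          orientation = ch$orientation, n_anchors = ch$length,
          stringsAsFactors = FALSE)
        anchors[[length(anchors) + 1]] <- data.frame(
          block_id = bid, gene_a = sub$gene_a[ch$idx],
          gene_b = sub$gene_b[ch$idx], rank_a = sub$rank_a[ch$idx],
          rank_b = sub$rank_b[ch$idx], stringsAsFactors = FALSE)
        sub <- sub[-ch$idx, , drop = FALSE]
      }
    }
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks) else
         data.frame(block_id = character(), chromosome_a = character(),
                    chromosome_b = character(), orientation = character(),
                    n_anchors = integer(), stringsAsFactors = FALSE),
       anchors = if (length(anchors)) do.call(rbind, anchors) else
         data.frame(block_id = character(), gene_a = character(),
                    gene_b = character(), rank_a = integer(),
                    rank_b = integer(), stringsAsFactors = FALSE))
}

#' Classify duplication mode per family gene
#'
#' @param arrays Output of [detect_tandem()].
#' @param blocks Output of [detect_collinear_blocks()].
#' @param family_genes Character vector of family gene ids.
#' @return Data frame with `gene_id`, `mode`
#'   (`tandem`/`wgd_segmental`/`both`/`none`), `array_id`, `block_ids`
#'   (comma-separated); summary counts in `attr(, "summary")`.
#' @export
classify_modes <- function(arrays, blocks, family_genes) {
  in_array <- stats::setNames(rep(NA_character_, length(family_genes)), family_genes)
  if (nrow(arrays)) {
    hit <- arrays$gene_id %in% family_genes
    in_array[arrays$gene_id[hit]] <- arrays$array_id[hit]
  }
  block_ids <- stats::setNames(vector("list", length(family_genes)), family_genes)
  if (nrow(blocks$anchors)) {
    for (k in seq_len(nrow(blocks$anchors))) {
      for (g in c(blocks$anchors$gene_a[k], blocks$anchors$gene_b[k])) {
        if (g %in% family_genes) {
          block_ids[[g]] <- union(block_ids[[g]], blocks$anchors$block_id[k])
        }
      }
    }
  }
  mode <- vapply(family_genes, function(g) {
    t <- !is.na(in_array[[g]]); w <- length(block_ids[[g]]) > 0
    if (t && w) "both" else if (t) "tandem" else if (w) "wgd_segmental" else "none"
  }, "")
  out <- data.frame(gene_id = family_genes, mode = unname(mode),
                    array_id = unname(in_array[family_genes]),
                    block_ids = vapply(family_genes, function(g)
                      paste(block_ids[[g]], collapse = ","), ""),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    tandem = sum(out$mode == "tandem"),
    wgd_segmental = sum(out$mode == "wgd_segmental"),
    both = sum(out$mode == "both"),
    none = sum(out$mode == "none"),
    tandem_total = sum(out$mode %in% c("tandem", "both")),
    wgd_total = sum(out$mode %in% c("wgd_segmental", "both")))
  out
}
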