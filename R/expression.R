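# RPKM normalisation and expression-pattern classification, including the
# three divergence types of duplicated pairs.

#' RPKM expression matrix from raw counts
#'
#' RPKM = count / (mRNA length / 1000) / (library size / 1e6), per gene and
#' tissue.
#'
#' @param counts Integer matrix, genes x tissues (row/col names required).
#' @param mrna_lengths Named numeric vector of mRNA lengths (bp) covering
#'   all rows.
#' @param library_sizes Named numeric vector of mapped-read totals covering
#'   all columns.
#' @return Numeric matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(counts, mrna_lengths, library_sizes) {
  if (any(counts < 0)) stop("negative count encountered")
  if (any(mrna_lengths[rownames(counts)] <= 0)) stop("mRNA lengths must be > 0")
  if (any(library_sizes[colnames(counts)] <= 0)) stop("library sizes must be > 0")
  len <- mrna_lengths[rownames(counts)]
  lib <- library_sizes[colnames(counts)]
  sweep(counts / (len / 1000), 2, lib / 1e6, "/")
}

#' Classify the regulation status of one expression profile
#'
#' Silent if every tissue is below the detection threshold; otherwise the
#' fold range is max / max(min, threshold): uniform (not developmentally
#' regulated) below `fold_cutoff`, regulated at or above it. Preferred
#' tissues are those whose value is at least `preference_ratio` times the
#' second-highest value.
#'
#' @param profile Named numeric vector of per-tissue RPKM (>= 2 tissues).
#' @param detection_threshold RPKM detection floor, default 1.
#' @param fold_cutoff Fold-range cutoff for "uniform", default 2.
#' @param preference_ratio Dominance ratio for preferred tissues, default 2.
#' @return List with `status` (`silent`/`uniform`/`regulated`),
#'   `fold_range`, `preferred_tissues`.
#' @export
classify_regulation <- function(profile, detection_threshold = 1,
                                fold_cutoff = 2, preference_ratio = 2) {
  if (length(profile) < 2) stop("need >= 2 tissues")
  if (all(profile < detection_threshold)) {
    return(list(status = "silent", fold_range = NA_real_,
                preferred_tissues = character()))
  }
  fold_range <- max(profile) / max(min(profile), detection_threshold)
  status <- if (fold_range < fold_cutoff) "uniform" else "regulated"
  sorted <- sort(profile, decreasing = TRUE)
  second <- if (length(sorted) > 1) sorted[2] else sorted[1]
  preferred <- names(profile)[profile >= preference_ratio * second &
                                profile >= detection_threshold]
  list(status = status, fold_range = fold_range,
       preferred_tissues = preferred)
}

#' Classify the expression divergence type of a duplicated pair
#'
#' Pearson correlation is computed on log2(RPKM + pseudocount). Type I
#' (same pattern): r >= `r_cutoff` and |median log2 ratio| < `shift_cutoff`.
#' Type II (magnitude shift): r >= `r_cutoff`, one member higher in every
#' tissue, and |median log2 ratio| >= `shift_cutoff`. Type III (divergent):
#' everything else. A zero-variance profile leaves r undefined; the
#' magnitude rules then decide alone. Pairs with a silent member are
#' flagged rather than typed.
#'
#' @param profile_a,profile_b Per-tissue RPKM vectors in the same tissue
#'   order.
#' @param r_cutoff Correlation cutoff, default 0.8.
#' @param shift_cutoff Median |log2 ratio| cutoff, default 1 (twofold).
#' @param pseudocount Added before logs, default 0.1.
#' @param detection_threshold RPKM detection floor, default 1.
#' @return List with `type` (`"I"`, `"II"`, `"III"`, or `NA` when a member
#'   is silent), `correlation`, `magnitude_ratio` (median log2 ratio),
#'   `higher_member` (for type II), `silent_member` flag.
#' @export
classify_pair_divergence <- function(profile_a, profile_b, r_cutoff = 0.8,
                                     shift_cutoff = 1, pseudocount = 0.1,
                                     detection_threshold = 1) {
  if (length(profile_a) != length(profile_b)) {
    stop("profiles differ in tissue count")
  }
  silent_a <- all(profile_a < detection_threshold)
  silent_b <- all(profile_b < detection_threshold)
  la <- log2(profile_a + pseudocount)
  lb <- log2(profile_b + pseudocount)
  ratio <- la - lb
  med <- stats::median(ratio)
  r <- if (stats::sd(la) == 0 || stats::sd(lb) == 0) NA_real_
       else stats::cor(la, lb)
  if (silent_a || silent_b) {
    return(list(type = NA_character_, correlation = r,
                magnitude_ratio = med, higher_member = NA_character_,
                silent_member = TRUE))
  }
  correlated <- if (is.na(r)) TRUE else r >= r_cutoff  # fall-through rule
  one_higher <- all(ratio > 0) || all(ratio < 0)
  type <- if (correlated && abs(med) < shift_cutoff) {
    "I"
  } else if (correlated && one_higher && abs(med) >= shift_cutoff) {
    "II"
  } else {
    "III"
  }
  higher <- if (type == "II") { if (med > 0) "a" else "b" } else NA_character_
  list(type = type, correlation = r, magnitude_ratio = med,
       higher_member = higher, silent_member = FALSE)
}

#' Family-level expression summary tables
#'
#' @param expr RPKM matrix (genes x tissues).
#' @param subfamilies Named character vector mapping gene_id to subfamily
#'   (genes absent from `expr` raise an error naming them).
#' @param pair_table Optional data frame with `gene_a`, `gene_b` naming
#'   duplicated pairs to type.
#' @param detection_threshold,fold_cutoff,preference_ratio Passed to
#'   [classify_regulation()].
#' @param ... Passed to [classify_pair_divergence()].
#' @return List with `classes` (per-gene regulation calls),
#'   `status_counts`, `subfamily_tissue_means`, and (when pairs are given)
#'   `pair_types` and `pair_type_counts`.
#' @export
summarize_family_expression <- function(expr, subfamilies, pair_table = NULL,
                                        detection_threshold = 1,
                                        fold_cutoff = 2,
                                        preference_ratio = 2, ...) {
  offenders <- setdiff(names(subfamilies), rownames(expr))
  if (length(offenders)) {
    stop("genes missing from expression matrix: ",
         paste(offenders, collapse = ", "))
  }
  genes <- names(subfamilies)
  classes <- do.call(rbind, lapply(genes, function(g) {
    cl <- classify_regulation(expr[g, ], detection_threshold, fold_cutoff,
                              preference_ratio)
    data.frame(gene_id = g, subfamily = subfamilies[[g]], status = cl$status,
               fold_range = cl$fold_range,
               preferred_tissues = paste(cl$preferred_tissues, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  status_counts <- table(factor(classes$status,
                                levels = c("silent", "uniform", "regulated")))
  sub_means <- do.call(rbind, lapply(split(genes, subfamilies[genes]),
                                     function(g) colMeans(expr[g, , drop = FALSE])))
  out <- list(classes = classes, status_counts = status_counts,
              subfamily_tissue_means = sub_means)
  if (!is.null(pair_table) && nrow(pair_table)) {
    missing_pair <- setdiff(c(pair_table$gene_a, pair_table$gene_b),
                            rownames(expr))
    if (length(missing_pair)) {
      stop("pair genes missing from expression matrix: ",
           paste(missing_pair, collapse = ", "))
    }
    pt <- do.call(rbind, lapply(seq_len(nrow(pair_table)), function(k) {
      res <- classify_pair_divergence(expr[pair_table$gene_a[k], ],
                                      expr[pair_table$gene_b[k], ],
                                      detection_threshold = detection_threshold,
                                      ...)
      data.frame(gene_a = pair_table$gene_a[k], gene_b = pair_table$gene_b[k],
                 type = res$type, correlation = res$correlation,
                 magnitude_ratio = res$magnitude_ratio,
                 silent_member = res$silent_member, stringsAsFactors = FALSE)
    }))
    out$pair_types <- pt
    out$pair_type_counts <- table(factor(pt$type, levels = c("I", "II", "III")))
  }
  out
}

#' Write a subfamily-ordered expression heatmap
#'
#' @param expr RPKM matrix.
#' @param subfamilies Named subfamily vector for row ordering.
#' @param file Output PNG path.
#' @param pseudocount Added before log2 display transform.
#' @return Invisibly, the file path (or `NA` if pheatmap is unavailable).
#' @export
write_expression_heatmap <- function(expr, subfamilies, file,
                                     pseudocount = 0.1) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    warning("pheatmap not installed; heatmap skipped")
    return(invisible(NA_character_))
  }
  genes <- names(sort(subfamilies))
  genes <- genes[genes %in% rownames(expr)]
  mat <- log2(expr[genes, , drop = FALSE] + pseudocount)
  ann <- data.frame(subfamily = subfamilies[genes], row.names = genes)
  grDevices::png(file, width = 900, height = 1400)
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_row = ann, show_rownames = FALSE)
  grDevices::dev.off()
  invisible(file)
}
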