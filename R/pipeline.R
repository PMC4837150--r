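# End-to-end survey pipeline: identification -> features -> duplication ->
# Ka/Ks dating -> classification -> expression, with persisted stage
# tables and a JSON summary. The pipeline never consults the generator's
# truth table; recovery scoring against truth is the caller's business.

#' Pipeline configuration with all stage defaults pinned
#'
#' @param min_coverage Domain completeness cutoff (default 0.5).
#' @param null_n,null_q,null_margin,calibration_seed Null calibration of the
#'   profile score threshold (see [calibrate_threshold()]).
#' @param min_identity,min_score Homolog-pair retention cutoffs.
#' @param tandem_max_gap Intervening non-family genes allowed within a
#'   tandem array (default 1).
#' @param min_anchors,max_rank_gap,anchor_min_identity Collinearity
#'   chaining parameters.
#' @param lambda_rate Synonymous clock rate (default 6.1e-9 /site/year).
#' @param recent_cutoff_my Recent-WGD boundary (default 25 My).
#' @param k_neighbors Reference votes for subfamily assignment (default 3).
#' @param detection_threshold,fold_cutoff,preference_ratio Expression
#'   regulation-stage cutoffs.
#' @param r_cutoff,shift_cutoff,pseudocount Pair-divergence typing cutoffs.
#' @param bootstrap_n NJ bootstrap replicates (default 0).
#' @param include_motifs Scan the packaged motif catalog (default FALSE;
#'   the scan is the slowest descriptor at family scale).
#' @param heatmap Write the expression heatmap PNG (default FALSE).
#' @param seed Seed for stochastic stages.
#' @return Classed list `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 0.5, null_n = 1000, null_q = 0.99,
                            null_margin = 20, calibration_seed = 101,
                            min_identity = 0.4, min_score = 0,
                            tandem_max_gap = 1, min_anchors = 3,
                            max_rank_gap = 25, anchor_min_identity = 0.7,
                            lambda_rate = 6.1e-9, recent_cutoff_my = 25,
                            k_neighbors = 3, detection_threshold = 1,
                            fold_cutoff = 2, preference_ratio = 2,
                            r_cutoff = 0.8, shift_cutoff = 1,
                            pseudocount = 0.1, bootstrap_n = 0,
                            include_motifs = FALSE, heatmap = FALSE,
                            seed = 17) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[famsurvey] %-14s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full gene-family survey on a bundle
#'
#' Stages: domain identification (profile calibration, scan, completeness
#' filter), subfamily assignment and systematic naming, protein
#' descriptors, duplication-mode classification (tandem + collinear),
#' Ka/Ks dating of detected anchor pairs, NJ tree, and expression typing.
#' With identical config and inputs the summary is identical.
#'
#' @param bundle A `synthetic_bundle`, a bundle list from [read_bundle()],
#'   or a bundle directory path.
#' @param outdir Optional output directory for stage TSVs, `tree.nwk` and
#'   `summary.json`.
#' @param config A [pipeline_config()].
#' @return List with all stage results and `summary`.
#' @export
run_pipeline <- function(bundle, outdir = NULL, config = pipeline_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  proteins <- bundle$proteins
  if (is.null(bundle$counts) && !is.null(outdir)) {
    stop("stage expression: counts matrix missing from bundle")
  }

  # --- identification -------------------------------------------------------
  profiles <- lapply(names(bundle$domain_profiles), function(pid)
    build_profile(bundle$domain_profiles[[pid]], profile_id = pid))
  thresholds <- vapply(profiles, function(p)
    calibrate_threshold(p, n = config$null_n, q = config$null_q,
                        margin = config$null_margin,
                        seed = config$calibration_seed)$threshold, 0)
  hits_by_gene <- lapply(stats::setNames(names(proteins), names(proteins)),
                         function(g) scan_domains(as.character(proteins[[g]]),
                                                  profiles, thresholds,
                                                  gene_id = g))
  assignments <- filter_candidates(hits_by_gene, config$min_coverage)
  candidates <- assignments$gene_id[assignments$rejection_reason != "no_hit" |
                                      assignments$accepted]
  accepted <- assignments$gene_id[assignments$accepted]
  stage_msg("identify", t0)

  # --- subfamily assignment and naming -------------------------------------
  if (is.null(bundle$references)) stop("stage classify: reference set missing")
  subcalls <- assign_subfamily(proteins[accepted], bundle$references$seqs,
                               bundle$references$subfamily,
                               k = config$k_neighbors)
  coords <- do.call(rbind, lapply(bundle$gene_models[accepted], function(gm)
    data.frame(gene_id = gm$gene_id, chromosome = gm$chromosome,
               start = min(gm$exons), stringsAsFactors = FALSE)))
  named <- assign_names(merge(subcalls, coords, by = "gene_id"))
  stage_msg("classify", t0)

  # --- protein descriptors --------------------------------------------------
  stats_df <- compute_stats(proteins[accepted])
  tm_counts <- vapply(accepted, function(g)
    nrow(predict_tm_regions(as.character(proteins[[g]]))), 0L)
  stats_df$tm_count <- tm_counts[stats_df$gene_id]
  motif_hits <- NULL
  if (config$include_motifs) {
    cat20 <- motif_catalog()
    motif_hits <- do.call(rbind, lapply(accepted, function(g)
      scan_motifs(as.character(proteins[[g]]), cat20, gene_id = g)))
  }
  structures <- gene_structure_stats(bundle$gene_models[accepted])
  stage_msg("features", t0)

  # --- duplication ----------------------------------------------------------
  gene_order <- do.call(rbind, lapply(bundle$gene_models, function(gm)
    data.frame(gene_id = gm$gene_id, chromosome = gm$chromosome,
               start = min(gm$exons), stringsAsFactors = FALSE)))
  gene_order <- gene_order[order(gene_order$chromosome, gene_order$start), ]
  gene_order$rank <- stats::ave(seq_len(nrow(gene_order)),
                                gene_order$chromosome, FUN = seq_along)
  gene_order$is_family <- gene_order$gene_id %in% accepted
  idm <- protein_identity_matrix(proteins[accepted])
  pairs <- find_homolog_pairs(NULL, config$min_identity, config$min_score,
                              idm = idm)
  arrays <- detect_tandem(pairs, gene_order, config$tandem_max_gap)
  non_rep <- arrays$gene_id[!arrays$is_representative]
  blocks <- detect_collinear_blocks(pairs, gene_order, config$min_anchors,
                                    config$max_rank_gap,
                                    config$anchor_min_identity,
                                    exclude_genes = non_rep,
                                    tandem_max_gap = config$tandem_max_gap)
  modes <- classify_modes(arrays, blocks, accepted)
  stage_msg("duplication", t0)

  # --- Ka/Ks dating of detected anchor pairs --------------------------------
  kaks <- NULL
  if (nrow(blocks$anchors)) {
    kaks <- do.call(rbind, lapply(seq_len(nrow(blocks$anchors)), function(k) {
      a <- blocks$anchors$gene_a[k]; b <- blocks$anchors$gene_b[k]
      row <- kaks_pair(as.character(bundle$cds[[a]]),
                       as.character(bundle$cds[[b]]),
                       lambda_rate = config$lambda_rate,
                       recent_cutoff_my = config$recent_cutoff_my)
      cbind(data.frame(block_id = blocks$anchors$block_id[k], gene_a = a,
                       gene_b = b, stringsAsFactors = FALSE), row)
    }))
  }
  stage_msg("kaks", t0)

  # --- tree -----------------------------------------------------------------
  tree <- nj_tree(distance_matrix(idm$identity), bootstrap_n = config$bootstrap_n,
                  seed = config$seed)
  stage_msg("tree", t0)

  # --- expression -----------------------------------------------------------
  expression <- NULL
  if (!is.null(bundle$counts) && ncol(bundle$counts) > 0) {
    mrna_lengths <- vapply(bundle$gene_models, function(g) nchar(g$cds), 0)
    expr <- rpkm(bundle$counts[accepted, , drop = FALSE], mrna_lengths,
                 bundle$library_sizes)
    pair_table <- if (!is.null(kaks))
      kaks[, c("gene_a", "gene_b"), drop = FALSE] else NULL
    expression <- summarize_family_expression(
      expr, stats::setNames(named$subfamily, named$gene_id), pair_table,
      detection_threshold = config$detection_threshold,
      fold_cutoff = config$fold_cutoff,
      preference_ratio = config$preference_ratio,
      r_cutoff = config$r_cutoff, shift_cutoff = config$shift_cutoff,
      pseudocount = config$pseudocount)
    expression$rpkm <- expr
  }
  stage_msg("expression", t0)

  # --- summary --------------------------------------------------------------
  mode_summary <- attr(modes, "summary")
  summary <- list(
    n_scanned = length(proteins),
    n_candidates = length(candidates),
    n_accepted = length(accepted),
    n_rejected_incomplete = sum(assignments$rejection_reason ==
                                  "short_or_incomplete_domain"),
    subfamily_counts = as.list(table(named$subfamily)),
    duplication_modes = as.list(mode_summary),
    n_blocks = nrow(blocks$blocks),
    n_anchor_pairs = nrow(blocks$anchors),
    n_tandem_arrays = length(unique(arrays$array_id)),
    selection_tally = if (!is.null(kaks)) as.list(table(kaks$selection)) else NULL,
    wgd_round_tally = if (!is.null(kaks)) as.list(table(kaks$wgd_round)) else NULL,
    expression_status = if (!is.null(expression))
      as.list(expression$status_counts) else NULL,
    pair_type_counts = if (!is.null(expression) &&
                             !is.null(expression$pair_type_counts))
      as.list(expression$pair_type_counts) else NULL,
    config = unclass(config))

  result <- list(assignments = assignments, names = named, stats = stats_df,
                 structures = structures, motif_hits = motif_hits,
                 gene_order = gene_order, pairs = pairs, arrays = arrays,
                 blocks = blocks, modes = modes, kaks = kaks, tree = tree,
                 expression = expression, thresholds = thresholds,
                 summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(assignments, "assignments.tsv")
    wt(named, "subfamilies.tsv")
    wt(stats_df, "stats.tsv")
    wt(structures, "structures.tsv")
    wt(modes, "duplications.tsv")
    wt(blocks$anchors, "blocks.tsv")
    if (!is.null(kaks)) wt(kaks, "kaks.tsv")
    if (!is.null(expression)) {
      wt(expression$classes, "expression_classes.tsv")
      if (!is.null(expression$pair_types)) wt(expression$pair_types,
                                              "pair_types.tsv")
      utils::write.table(expression$rpkm, file.path(outdir, "rpkm.tsv"),
                         sep = "\t", quote = FALSE)
      if (config$heatmap) {
        write_expression_heatmap(
          expression$rpkm, stats::setNames(named$subfamily, named$gene_id),
          file.path(outdir, "heatmap.png"))
      }
    }
    ape::write.tree(tree, file.path(outdir, "tree.nwk"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' Regression check of the packaged divergence table
#'
#' Recomputes Ka/Ks ratios and clock dates from the 23 printed (Ka, Ks)
#' pairs and prints them next to the printed columns, listing deviations
#' beyond the tolerance (which arise only from rounding of the printed
#' inputs).
#'
#' @inheritParams table1_regression
#' @param quiet Suppress printing.
#' @return Invisibly, the [table1_regression()] result with a `pass` flag
#'   attached.
#' @export
table1_check <- function(lambda_rate = 6.1e-9, recent_cutoff_my = 25,
                         tol = 0.01, quiet = FALSE) {
  reg <- table1_regression(lambda_rate, recent_cutoff_my, tol)
  reg$pass <- nrow(reg$deviations) == 0
  if (!quiet) {
    print(reg$table[, c("pair", "ka", "ks", "ratio", "ratio_printed",
                        "time_my", "date_printed")], digits = 4)
    cat(sprintf("\n%d/%d pairs within %.1f%% of the printed ratio and date\n",
                nrow(reg$table) - nrow(reg$deviations), nrow(reg$table),
                100 * tol))
    s <- reg$summary
    cat(sprintf("ratios < 0.6: %d | dates <= %g My: %d | range %.2f-%.2f My\n",
                s[["n_ratio_below_0.6"]], recent_cutoff_my,
                s[["n_recent_wgd"]], s[["min_date_my"]], s[["max_date_my"]]))
  }
  invisible(reg)
}
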