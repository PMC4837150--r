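# Homolog pairs, tandem arrays, collinearity chaining, mode classification.

make_gene_order <- function(chrom_sizes, family_ranks) {
  rows <- list()
  for (chrom in names(chrom_sizes)) {
    n <- chrom_sizes[[chrom]]
    fam <- family_ranks[[chrom]]
    rows[[chrom]] <- data.frame(
      gene_id = sprintf("%s_g%02d", chrom, 1:n), chromosome = chrom,
      rank = 1:n, is_family = 1:n %in% fam, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

pairs_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = pmin(m[, 1], m[, 2]), gene_b = pmax(m[, 1], m[, 2]),
             identity = 0.9, score = 100, stringsAsFactors = FALSE)
}

test_that("homolog pairs respect identity cutoffs and the pair bound", {
  withr::with_seed(19, {
    base <- random_protein_seq(120)
    mut <- famsurvey:::mutate_protein(base, 0.1)
    unrelated <- random_protein_seq(120)
    prot <- c(a = base, b = mut, c = unrelated)
    pairs <- find_homolog_pairs(prot, min_identity = 0.4)
    expect_lte(nrow(pairs), 3)  # n(n-1)/2 bound
    expect_true(any(pairs$gene_a == "a" & pairs$gene_b == "b"))
    expect_false(any(pairs$gene_b == "c" | pairs$gene_a == "c"))
    ident <- find_homolog_pairs(c(x = base, y = base))
    expect_equal(ident$identity, 1)
    expect_true(all(pairs$gene_a < pairs$gene_b))
  })
})

test_that("tandem arrays follow the gene-order adjacency rule", {
  go <- make_gene_order(c(chr1 = 10, chr2 = 10),
                        list(chr1 = c(3, 4, 5, 8), chr2 = c(2)))
  # three consecutive homologous family genes -> one array of 3
  p <- pairs_df("chr1_g03", "chr1_g04", "chr1_g04", "chr1_g05",
                "chr1_g03", "chr1_g05")
  arr <- detect_tandem(p, go, max_gap = 1)
  expect_equal(nrow(arr), 3)
  expect_equal(length(unique(arr$array_id)), 1)
  expect_equal(arr$gene_id[arr$is_representative], "chr1_g03")
  # homologs on different chromosomes never form an array
  expect_equal(nrow(detect_tandem(pairs_df("chr1_g03", "chr2_g02"), go, 1)), 0)
  # gap boundary: two background genes between the pair
  p2 <- pairs_df("chr1_g05", "chr1_g08")  # ranks 6,7 are non-family
  expect_equal(nrow(detect_tandem(p2, go, max_gap = 1)), 0)
  expect_equal(nrow(detect_tandem(p2, go, max_gap = 2)), 3 - 1)
  expect_error(detect_tandem(pairs_df("chr1_g03", "nope"), go, 1), "missing")
})

test_that("planted collinear blocks are chained exactly", {
  go <- make_gene_order(c(chrA = 30, chrB = 30),
                        list(chrA = c(2, 5, 8, 11, 14), chrB = c(3, 6, 9, 12, 15)))
  anchors <- pairs_df(
    "chrA_g02", "chrB_g03", "chrA_g05", "chrB_g06", "chrA_g08", "chrB_g09",
    "chrA_g11", "chrB_g12", "chrA_g14", "chrB_g15")
  res <- detect_collinear_blocks(anchors, go, min_anchors = 3)
  expect_equal(nrow(res$blocks), 1)
  expect_equal(res$blocks$n_anchors, 5)
  expect_equal(res$blocks$orientation, "same")
  expect_setequal(res$anchors$gene_a, unique(anchors$gene_a))
  # two anchors are below the min_anchors threshold
  res2 <- detect_collinear_blocks(anchors[1:2, ], go, min_anchors = 3)
  expect_equal(nrow(res2$blocks), 0)
  # inverted orientation is detected
  inv <- pairs_df("chrA_g02", "chrB_g15", "chrA_g05", "chrB_g12",
                  "chrA_g08", "chrB_g09", "chrA_g11", "chrB_g06")
  res3 <- detect_collinear_blocks(inv, go, min_anchors = 3)
  expect_equal(res3$blocks$orientation, "inverted")
  expect_equal(res3$blocks$n_anchors, 4)
})

test_that("chaining equals exhaustive monotonic-subset search on small instances", {
  withr::with_seed(23, {
    for (instance in 1:15) {
      n <- sample(4:8, 1)
      ra <- sample(1:20, n)
      rb <- sample(1:20, n)
      go <- make_gene_order(c(cA = 20, cB = 20),
                            list(cA = sort(unique(ra)), cB = sort(unique(rb))))
      anchors <- data.frame(
        gene_a = sprintf("cA_g%02d", ra), gene_b = sprintf("cB_g%02d", rb),
        identity = 0.9, score = 100, stringsAsFactors = FALSE)
      gap <- sample(c(5, 10, 20), 1)
      res <- detect_collinear_blocks(anchors, go, min_anchors = 2,
                                     max_rank_gap = gap)
      got <- if (nrow(res$blocks)) max(res$blocks$n_anchors) else 0
      want <- brute_force_chain_size(ra, rb, gap)
      if (want < 2) want <- 0
      expect_equal(got, want, info = paste("instance", instance))
    }
  })
})

test_that("anchors never include invented pairs and arrays partition genes", {
  b <- tiny_bundle()
  res <- suppressWarnings(suppressMessages(run_pipeline(b)))
  key <- function(df) paste(df$gene_a, df$gene_b)
  expect_true(all(key(res$blocks$anchors) %in% key(res$pairs)))
  expect_false(any(duplicated(res$arrays$gene_id)))
  # mode bookkeeping identity
  s <- attr(res$modes, "summary")
  n_array_members <- nrow(res$arrays[res$arrays$gene_id %in% res$modes$gene_id, ])
  expect_equal(unname(s["tandem"] + s["both"]), n_array_members)
})

test_that("duplication modes combine array and block membership", {
  arrays <- data.frame(array_id = "TA01", chromosome = "chr1",
                       gene_id = c("g1", "g2"), rank = 1:2,
                       is_representative = c(TRUE, FALSE), max_gap_used = 1)
  blocks <- list(blocks = data.frame(block_id = "CB01", chromosome_a = "chr1",
                                     chromosome_b = "chr2",
                                     orientation = "same", n_anchors = 3),
                 anchors = data.frame(block_id = "CB01",
                                      gene_a = c("g1", "g3", "g4"),
                                      gene_b = c("h1", "h3", "h4"),
                                      rank_a = 1:3, rank_b = 1:3))
  modes <- classify_modes(arrays, blocks, c("g1", "g2", "g3", "g5"))
  got <- stats::setNames(modes$mode, modes$gene_id)
  expect_equal(unname(got[c("g1", "g2", "g3", "g5")]),
               c("both", "tandem", "wgd_segmental", "none"))
})
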