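# Synthetic genome generator: determinism, planted structure, CDS
# invariants, divergence control, expression archetypes, round-trip I/O.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_generator_config(seed = 31)
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  expect_identical(as.character(b1$chromosomes), as.character(b2$chromosomes))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$counts, b2$counts)
  expect_identical(as.character(b1$proteins), as.character(b2$proteins))
})

test_that("bundle invariants hold: translation, frame, exon geometry, truth coverage", {
  b <- tiny_bundle()
  chroms <- as.character(b$chromosomes)
  for (gm in b$gene_models) {
    expect_equal(nchar(gm$cds) %% 3, 0)
    ex <- gm$exons
    expect_true(all(diff(ex[, 1]) > 0))
    expect_true(all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    expect_true(min(ex) >= 0)
    expect_true(max(ex) <= nchar(chroms[[gm$chromosome]]))
    expect_equal(sum(ex[, 2] - ex[, 1]), nchar(gm$cds))
  }
  # every non-decoy CDS translates cleanly (decoys here do too, but only
  # the intact genes are guaranteed by contract)
  intact <- b$truth$gene_id[b$truth$role != "decoy"]
  for (g in intact) {
    expect_silent(famsurvey:::translate_cds(b$gene_models[[g]]$cds))
  }
  expect_identical(sort(b$truth$gene_id), sort(names(b$gene_models)))
  expect_false(anyDuplicated(b$truth$gene_id) > 0)
})

test_that("CDS in the bundle equals the strand-aware exon assembly of the genome", {
  b <- tiny_bundle()
  chroms <- as.character(b$chromosomes)
  minus_seen <- FALSE
  for (gm in b$gene_models) {
    segs <- apply(gm$exons, 1, function(e)
      substr(chroms[[gm$chromosome]], e[1] + 1, e[2]))
    s <- paste(segs, collapse = "")
    if (gm$strand == "-") {
      minus_seen <- TRUE
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_identical(s, gm$cds)
  }
  expect_true(minus_seen)
})

test_that("planted tandem arrays occupy consecutive family gene ranks", {
  b <- tiny_bundle()
  tr <- b$truth
  arr <- tr[!is.na(tr$array) & tr$array == 1, ]
  expect_equal(nrow(arr), 3)
  expect_equal(length(unique(arr$chromosome)), 1)
  # consecutive ranks (gap 0: no intervening genes at all)
  expect_equal(sort(diff(sort(arr$rank))), c(1, 1))
})

test_that("evolve_cds honours its targets and degenerate cases", {
  withr::with_seed(13, {
    cds <- random_sense_cds(320)
    expect_identical(evolve_cds(cds, 0, 0, seed = 1), cds)
    # synonymous-only edits leave the protein unchanged
    syn <- evolve_cds(cds, 0.3, 0, seed = 2)
    expect_identical(famsurvey:::translate_cds(syn),
                     famsurvey:::translate_cds(cds))
    expect_false(identical(syn, cds))
    expect_error(evolve_cds(cds, -0.1, 0), ">= 0")
  })
})

test_that("planted Ks is recovered by the NG86 round trip", {
  withr::with_seed(29, {
    cds <- random_sense_cds(320)
    est <- vapply(1:6, function(s) {
      m <- evolve_cds(cds, 0.2, 0, seed = 1000 + s)
      aln <- list(codons_a = oracle_split_codons(cds),
                  codons_b = oracle_split_codons(m))
      ng86_kaks(aln)$ks
    }, 0)
    expect_true(all(abs(est - 0.2) <= 0.05))
  })
})

test_that("planted and estimated Ks correlate strongly across a divergence ladder", {
  withr::with_seed(37, {
    cds <- random_sense_cds(300)
    targets <- seq(0.05, 0.9, length.out = 30)
    est <- vapply(seq_along(targets), function(i) {
      m <- evolve_cds(cds, targets[i], 0, seed = 2000 + i)
      ng86_kaks(list(codons_a = oracle_split_codons(cds),
                     codons_b = oracle_split_codons(m)))$ks
    }, 0)
    expect_gt(stats::cor(targets, est), 0.95)
  })
})

test_that("expression archetypes are planted as declared", {
  b <- tiny_bundle()
  tr <- b$truth
  expr <- rpkm(b$counts, vapply(b$gene_models, function(g) nchar(g$cds), 0),
               b$library_sizes)
  silent <- tr$gene_id[tr$archetype == "silent"]
  expect_gt(length(silent), 0)
  expect_true(all(expr[silent, ] < 1))
  # type II pairs: noise-free means differ by the configured ratio everywhere
  t2 <- tr[!is.na(tr$pair_type) & tr$pair_type == "II", ]
  if (nrow(t2)) {
    for (pid in unique(t2$pair_id)) {
      g <- t2[t2$pair_id == pid, ]
      hi <- b$expression_means[g$gene_id[g$side == "source"], ]
      lo <- b$expression_means[g$gene_id[g$side == "target"], ]
      expect_equal(unname(hi / lo), rep(4, ncol(b$counts)))
    }
  }
  # same seed, same matrix
  e1 <- generate_expression(b, seed = 99)
  e2 <- generate_expression(b, seed = 99)
  expect_identical(e1$counts, e2$counts)
})

test_that("an over-specified chromosome length raises a sizing error", {
  cfg <- tiny_generator_config()
  cfg$chromosome_length <- 1000  # far below content
  expect_error(generate_genome(cfg), "do not fit")
})

test_that("write_bundle/read_bundle round-trips every documented field", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  r <- read_bundle(dir)
  expect_identical(as.character(r$chromosomes), as.character(b$chromosomes))
  expect_identical(as.character(r$proteins), as.character(b$proteins))
  expect_identical(as.character(r$cds), as.character(b$cds))
  expect_identical(r$counts, b$counts)
  expect_equal(r$library_sizes, b$library_sizes)
  expect_identical(r$truth$gene_id, b$truth$gene_id)
  expect_identical(r$truth$archetype, b$truth$archetype)
  expect_identical(names(r$gene_models), names(b$gene_models))
  for (g in names(b$gene_models)) {
    expect_identical(r$gene_models[[g]]$exons, unname(b$gene_models[[g]]$exons))
    expect_identical(r$gene_models[[g]]$strand, b$gene_models[[g]]$strand)
    expect_identical(r$gene_models[[g]]$chromosome,
                     b$gene_models[[g]]$chromosome)
  }
  expect_identical(r$references$subfamily, b$references$subfamily)
  expect_identical(names(r$domain_profiles), sort(names(b$domain_profiles)))
})

test_that("an empty tissue list writes a header-only count table", {
  cfg <- tiny_generator_config()
  cfg$tissues <- character(0)
  b <- generate_genome(cfg)
  expect_equal(ncol(b$counts), 0)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_identical(readLines(file.path(dir, "counts.tsv")), "gene_id")
})
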