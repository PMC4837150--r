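# Alignment scores, distance matrices, NJ trees, subfamily votes,
# gene-structure statistics.

test_that("global alignment scores identical and small sequences correctly", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- global_align("MKWVTF", "MKWVTF")
  expect_equal(aln$identity, 1)
  expect_equal(aln$score,
               sum(diag(BLOSUM62[strsplit("MKWVTF", "")[[1]],
                                 strsplit("MKWVTF", "")[[1]]])))
  expect_error(global_align("A", ""), "empty")
  expect_error(global_align("AB", "AC"), "non-amino-acid")
})

test_that("alignment scores equal exhaustive enumeration on tiny pairs", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      a <- random_protein_seq(sample(3:8, 1))
      b <- random_protein_seq(sample(3:8, 1))
      got <- global_align(a, b)$score
      want <- brute_force_align_score(a, b)
      expect_equal(got, want, tolerance = 1e-9,
                   info = paste(a, b))
    }
  })
})

test_that("p-distance matrices are symmetric with zero diagonal", {
  withr::with_seed(41, {
    prot <- stats::setNames(
      c(random_protein_seq(50), random_protein_seq(50), random_protein_seq(50)),
      c("a", "b", "c"))
    prot["b"] <- prot["a"]
    d <- distance_matrix(prot)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_equal(d["a", "b"], 0)
    expect_error(distance_matrix(prot[1:2]), ">= 3")
  })
})

test_that("three leaves give the closed-form star decomposition", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  # closed form: la = (dab + dac - dbc)/2, etc.
  bl <- stats::setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers additive four-taxon topologies (four-point condition)", {
  withr::with_seed(47, {
    for (rep in 1:20) {
      d <- random_additive_quartet()
      phy <- nj_tree(d)
      expect_equal(four_point_split(d), "AB_CD")
      expect_true(tree_has_cherry(phy, c("A", "B")))
      expect_true(all(phy$edge.length >= 0))
    }
  })
})

test_that("bootstrap supports appear only when replicates are requested", {
  withr::with_seed(53, {
    msa <- t(replicate(5, sample(c("A", "C", "D", "E"), 40, TRUE)))
    rownames(msa) <- paste0("t", 1:5)
    d <- famsurvey:::pdistance_from_characters(msa)
    plain <- nj_tree(d, bootstrap_n = 0)
    expect_null(plain$node.label)
    boot <- nj_tree(d, bootstrap_n = 25, alignment = msa, seed = 3)
    expect_equal(length(boot$node.label), boot$Nnode)
    expect_true(all(boot$node.label >= 0 & boot$node.label <= 100))
    # determinism under the seed
    boot2 <- nj_tree(d, bootstrap_n = 25, alignment = msa, seed = 3)
    expect_identical(boot$node.label, boot2$node.label)
  })
})

test_that("subfamily votes follow k nearest references with tie handling", {
  withr::with_seed(59, {
    aap <- random_protein_seq(80)
    cat_ <- random_protein_seq(80)
    refs <- c(r1 = aap, r2 = famsurvey:::mutate_protein(aap, 0.05),
              r3 = cat_, r4 = famsurvey:::mutate_protein(cat_, 0.05))
    labels <- c("AAP", "AAP", "CAT", "CAT")
    res <- suppressWarnings(
      assign_subfamily(c(q = aap), refs, labels, k = 3))
    expect_equal(res$subfamily, "AAP")
    expect_equal(res$support, 2 / 3)
    expect_equal(res$family, "AAAP")
    # invariant under duplicating a reference sequence
    res2 <- suppressWarnings(
      assign_subfamily(c(q = aap), c(refs, r5 = aap), c(labels, "AAP"), k = 3))
    expect_equal(res2$subfamily, "AAP")
    # k = 1 with two equidistant labels flags ambiguity
    resT <- suppressWarnings(
      assign_subfamily(c(q = aap), c(x = aap, y = aap), c("AAP", "CAT"), k = 2))
    expect_true(resT$ambiguous)
    expect_warning(assign_subfamily(c(q = aap), refs, labels), "lacks")
  })
})

test_that("gene-structure statistics count CDS segments", {
  gm <- function(id, exons) list(gene_id = id, exons = exons)
  res <- gene_structure_stats(list(
    gm("single", matrix(c(0L, 300L), 1)),
    gm("triple", matrix(c(0L, 100L, 200L, 350L, 500L, 650L), 3, byrow = TRUE))))
  expect_equal(res$n_introns_in_cds, c(0L, 2L))
  expect_true(res$intronless[1])
  expect_equal(res$cds_span[2], 650)
  expect_error(gene_structure_stats(list(
    gm("bad", matrix(c(0L, 100L, 50L, 150L), 2, byrow = TRUE)))), "overlapping")
})

test_that("intron counts on the default bundle stay inside the reported family range", {
  res <- default_pipeline_result()
  expect_true(all(res$structures$n_introns_in_cds >= 0 &
                    res$structures$n_introns_in_cds <= 16))
  expect_gt(sum(res$structures$intronless), 0)
})
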