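# Domain-profile construction, scanning, completeness filter, naming.

make_seed_alignment <- function(consensus, n = 4) {
  Biostrings::AAStringSet(stats::setNames(rep(consensus, n),
                                          paste0("s", seq_len(n))))
}

test_that("a profile from identical sequences has that sequence as consensus", {
  withr::with_seed(3, {
    cons <- random_protein_seq(40)
    prof <- build_profile(make_seed_alignment(cons), "p")
    expect_equal(prof$profile_length, 40)
    expect_identical(profile_consensus(prof), cons)
  })
})

test_that("majority-gap columns are dropped and pseudocounts keep scores finite", {
  core <- "ACDEFGHIKLMNPQ"
  aln <- Biostrings::AAStringSet(c(a = paste0("AC-", core),
                                   b = paste0("AC-", core),
                                   c = paste0("ACW", core)))
  prof <- build_profile(aln, "p")
  expect_equal(prof$profile_length, 16)  # the 2/3-gap column is dropped
  prof0 <- build_profile(make_seed_alignment("ACDEFGHIKLMNPQRS", 2), "p",
                         pseudocount = 0)
  expect_true(all(is.finite(prof0$pwm)))
  expect_error(build_profile(Biostrings::AAStringSet(c("ACDEFGHIKL",
                                                       "ACDEFGHIKLM"))),
               "differ in length")
})

test_that("scanning finds verbatim and end-truncated placements", {
  withr::with_seed(8, {
    cons <- random_protein_seq(60)
    prof <- build_profile(make_seed_alignment(cons), "p")
    flank1 <- random_protein_seq(50)
    flank2 <- random_protein_seq(30)
    hits <- scan_domains(paste0(flank1, cons, flank2), prof, 10)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$coverage, 1)
    expect_equal(hits$start, 50)
    expect_equal(hits$end, 110)
    # local placement: score invariant under different flanks
    hits2 <- scan_domains(paste0(random_protein_seq(12), cons,
                                 random_protein_seq(90)), prof, 10)
    expect_equal(hits2$score, hits$score)
    # truncated: only the first 40% of the consensus, at the sequence end
    part <- substr(cons, 1, 24)
    hits3 <- scan_domains(paste0(flank1, part), prof, 10)
    expect_equal(nrow(hits3), 1)
    expect_equal(hits3$coverage, 0.4)
    expect_error(scan_domains("ACDB*", prof, 0), "B|\\*")
  })
})

test_that("random sequences rarely reach the calibrated threshold", {
  withr::with_seed(14, {
    cons <- random_protein_seq(80)
    prof <- build_profile(make_seed_alignment(cons), "p")
    cal <- calibrate_threshold(prof, n = 400, seed = 51)
    hits <- vapply(1:400, function(i) {
      nrow(scan_domains(random_protein_seq(300), prof, cal$threshold)) > 0
    }, TRUE)
    expect_lte(mean(hits), 0.01)
  })
})

test_that("the completeness filter partitions candidates with reasons", {
  hits <- list(
    full = data.frame(gene_id = "full", profile_id = "p", start = 0, end = 50,
                      score = 100, coverage = 1),
    partial = data.frame(gene_id = "partial", profile_id = "p", start = 0,
                         end = 20, score = 40, coverage = 0.4),
    boundary = data.frame(gene_id = "boundary", profile_id = "p", start = 0,
                          end = 49, score = 95, coverage = 0.99),
    none = data.frame(gene_id = character(), profile_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      coverage = numeric()))
  res <- filter_candidates(hits, min_coverage = 0.5)
  expect_equal(nrow(res), 4)  # partition: accepted + rejected = input
  expect_true(res$accepted[res$gene_id == "full"])
  expect_equal(res$rejection_reason[res$gene_id == "partial"],
               "short_or_incomplete_domain")
  expect_equal(res$rejection_reason[res$gene_id == "none"], "no_hit")
  # boundary: min_coverage 1.0 rejects a 0.99-coverage hit
  strict <- filter_candidates(hits["boundary"], min_coverage = 1.0)
  expect_false(strict$accepted)
  expect_error(filter_candidates(hits, min_coverage = 0), "in \\(0, 1\\]")
})

test_that("systematic names rank subfamily members by position", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    subfamily = c("AAP", "AAP", "TTP", "AAP"),
    chromosome = c("chr01", "chr01", "chr02", "chr02"),
    start = c(500, 100, 10, 50), stringsAsFactors = FALSE)
  named <- assign_names(genes)
  expect_equal(named$assigned_name[named$gene_id == "g2"], "AAP1")
  expect_equal(named$assigned_name[named$gene_id == "g1"], "AAP2")
  expect_equal(named$assigned_name[named$gene_id == "g4"], "AAP3")
  expect_equal(named$assigned_name[named$gene_id == "g3"], "TTP1")
  expect_error(assign_names(genes[c(1, 1), ]), "duplicate")
  genes$subfamily[2] <- NA
  expect_error(assign_names(genes), "missing a subfamily")
})
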