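# Nei-Gojobori estimation, clock dating, and the packaged divergence table.

test_that("identical and single-class codon pairs give the expected corner values", {
  cds <- "ATGGCTAAAGGTCTTCCAACTGAAGATTGGTTCAGAATG"  # 13 codons
  cods <- famsurvey:::split_codons(cds)
  aln <- list(codons_a = cods, codons_b = cods)
  est <- ng86_kaks(aln)
  expect_identical(c(est$ka, est$ks), c(0, 0))

  # third-position synonymous change only: GGT -> GGC
  b <- cods; b[4] <- "GGC"
  est <- ng86_kaks(list(codons_a = cods, codons_b = b))
  expect_equal(est$ka, 0)
  expect_gt(est$ks, 0)

  # first-position nonsynonymous change only: CTT -> ATT is Leu -> Ile
  b <- cods; b[5] <- "ATT"
  est <- ng86_kaks(list(codons_a = cods, codons_b = b))
  expect_equal(est$ks, 0)
  expect_gt(est$ka, 0)
})

test_that("ng86_kaks is symmetric and conserves 3 sites per codon", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      a <- random_sense_cds(30)
      b <- mutate_cds_random(a, 8)
      ca <- oracle_split_codons(a); cb <- oracle_split_codons(b)
      e1 <- ng86_kaks(list(codons_a = ca, codons_b = cb))
      e2 <- ng86_kaks(list(codons_a = cb, codons_b = ca))
      expect_identical(e1[c("ka", "ks", "sd", "nd")],
                       e2[c("ka", "ks", "sd", "nd")])
      expect_equal(e1$s_sites + e1$n_sites, 3 * 30, tolerance = 1e-12)
      # per-codon conservation within each sequence
      tab <- famsurvey:::codon_tables()
      expect_true(all(abs(tab$syn_sites[ca] + (3 - tab$syn_sites[ca]) - 3) < 1e-9))
    }
  })
})

test_that("ng86_kaks matches the pathway-enumeration oracle on seeded pairs", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(10:50, 1)
      a <- random_sense_cds(n)
      b <- mutate_cds_random(a, sample(1:12, 1))
      ca <- oracle_split_codons(a); cb <- oracle_split_codons(b)
      est <- ng86_kaks(list(codons_a = ca, codons_b = cb))
      ora <- oracle_ng86(ca, cb)
      expect_equal(est$sd, ora$sd, tolerance = 1e-9)
      expect_equal(est$nd, ora$nd, tolerance = 1e-9)
      expect_equal(est$ks, ora$ks, tolerance = 1e-9)
      expect_equal(est$ka, ora$ka, tolerance = 1e-9)
    }
  })
})

test_that("codon_align threads codons through the protein alignment", {
  a <- "ATGGCTGAA"          # M A E
  b <- "ATGGAA"             # M E
  aln <- global_align("MAE", "ME")
  cal <- codon_align(a, b, aln)
  expect_equal(cal$n_codons, 2)
  expect_identical(cal$codons_a, c("ATG", "GAA"))
  expect_identical(cal$codons_b, c("ATG", "GAA"))
  expect_error(codon_align(substr(a, 1, 7), b, aln), "divisible")
  expect_error(codon_align(a, b, list(aligned_a = "MAE", aligned_b = "MEX")),
               "length|match")
})

test_that("the molecular clock maps Ks to the published dates", {
  # anchors from the packaged divergence table
  expect_equal(date_duplication(0.348), 28.53, tolerance = 0.01)
  expect_equal(date_duplication(0.243), 19.92, tolerance = 0.01)
  expect_equal(date_duplication(0), 0)
  expect_true(is.na(date_duplication(NA_real_)))
  # strictly increasing in ks, decreasing in lambda
  expect_gt(date_duplication(0.4), date_duplication(0.39))
  expect_gt(date_duplication(0.4, 6.1e-9), date_duplication(0.4, 1.22e-8))
  expect_error(date_duplication(-0.1), ">= 0")
})

test_that("selection regime and WGD round follow the published rules", {
  expect_equal(classify_evolution(0.011, 0.103, 8.43)$selection, "purifying")
  expect_equal(classify_evolution(0.269, 0.177, 14.50)$selection, "positive")
  expect_equal(classify_evolution(0.2, 0.2, 16)$selection, "neutral")
  expect_equal(classify_evolution(0.1, 0, NA)$selection, "undefined")
  expect_equal(classify_evolution(0.061, 0.348, 28.53)$wgd_round, "ancient")
  expect_equal(classify_evolution(0.009, 0.083, 6.78)$wgd_round, "recent")
  expect_equal(classify_evolution(0.163, 0.933, 76.51)$wgd_round, "pre_wgd")
  expect_equal(classify_evolution(0.1, NA, NA)$wgd_round, "not_assigned")
})

test_that("the packaged pair table reproduces the printed summaries", {
  reg <- table1_regression()
  expect_equal(nrow(reg$table), 23)
  s <- reg$summary
  expect_equal(unname(s["n_ratio_below_0.6"]), 21)
  expect_equal(unname(s["n_recent_wgd"]), 20)
  expect_equal(unname(s["min_date_my"]), 6.78, tolerance = 0.01)
  expect_equal(unname(s["max_date_my"]), 76.51, tolerance = 0.01)
  # all dates within 1% of print; ratio deviations are 3-decimal rounding
  expect_true(all(reg$table$date_rel_dev <= 0.01))
  expect_true(all(abs(reg$table$ratio - reg$table$ratio_printed) < 0.005))
})

test_that("kaks_pair runs the whole estimation chain on one CDS pair", {
  withr::with_seed(5, {
    a <- random_sense_cds(120)
    b <- evolve_cds(a, 0.3, 0.05, seed = 9)
    row <- kaks_pair(a, b)
    expect_equal(row$ks, 0.3, tolerance = 0.12)
    expect_equal(row$selection, "purifying")
    expect_equal(row$time_my, row$ks / (2 * 6.1e-9) / 1e6)
  })
})
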