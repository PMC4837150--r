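# Shared fixtures built in code. The tiny bundle keeps unit tests fast;
# the full default bundle and its pipeline run are generated once and
# cached for the acceptance suite.

.fixture_env <- new.env(parent = emptyenv())

tiny_generator_config <- function(seed = 7) {
  generator_config(
    n_chromosomes = 4,
    n_background_genes = 70,
    subfamily_plan = c(AAP = 7, CAT = 6, LHT = 5, GAT = 4),
    tandem_arrays = data.frame(
      array = 1, size = 3, gap = 0, subfamily = "AAP", chromosome = "chr03",
      attach_block = NA, attach_anchor = NA, stringsAsFactors = FALSE),
    collinear_blocks = list(
      list(source = "chr01", target = "chr02", target_ks = 0.2,
           subfamilies = c("AAP", "CAT", "LHT"))),
    decoy_truncated = 3,
    expression_plan = list(n_constitutive = 4, n_silent = 2,
                           pair_type_split = c(I = 1, II = 1, III = 1),
                           type_ii_ratio = 4),
    seed = seed)
}

tiny_bundle <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_genome(tiny_generator_config())
  }
  .fixture_env$tiny
}

default_bundle <- function() {
  if (is.null(.fixture_env$full)) {
    .fixture_env$full <- generate_genome(generator_config())
  }
  .fixture_env$full
}

default_pipeline_result <- function() {
  if (is.null(.fixture_env$full_res)) {
    .fixture_env$full_res <- suppressMessages(run_pipeline(default_bundle()))
  }
  .fixture_env$full_res
}

truth_duplication_mode <- function(truth) {
  mode <- ifelse(!is.na(truth$array) & !is.na(truth$block), "both",
                 ifelse(!is.na(truth$array), "tandem",
                        ifelse(!is.na(truth$block), "wgd_segmental", "none")))
  stats::setNames(mode, truth$gene_id)
}
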