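# Nei-Gojobori (1986) Ka/Ks estimation, molecular-clock dating, and
# selection / WGD-round classification for paralog pairs.

# Average synonymous/nonsynonymous difference counts for one codon pair,
# averaged over all minimal substitution pathways. Pathways crossing a stop
# codon are excluded; if every pathway crosses a stop, all pathways are used.
# Results are memoised (pair order does not matter for the totals).
codon_pair_differences <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(syn = 0, nonsyn = 0))
  key <- if (codon_a < codon_b) paste(codon_a, codon_b) else paste(codon_b, codon_a)
  cache <- .famsurvey_cache
  if (is.null(cache$pair_diffs)) cache$pair_diffs <- new.env(parent = emptyenv())
  hit <- cache$pair_diffs[[key]]
  if (!is.null(hit)) return(hit)

  gc_map <- Biostrings::GENETIC_CODE
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  perms <- list()
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  orders <- permute(diff_pos)
  walk <- function(order) {
    cur <- a
    syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (gc_map[[cod_nxt]] == "*" || gc_map[[cod_cur]] == "*") {
        return(NULL)  # stop-crossing pathway
      }
      if (gc_map[[cod_cur]] == gc_map[[cod_nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  counts <- Filter(Negate(is.null), lapply(orders, walk))
  if (!length(counts)) {
    # all pathways blocked by stops: fall back to counting through them
    walk_any <- function(order) {
      cur <- a; syn <- 0; nonsyn <- 0
      for (pos in order) {
        nxt <- cur
        nxt[pos] <- b[pos]
        same <- identical(gc_map[[paste(cur, collapse = "")]],
                          gc_map[[paste(nxt, collapse = "")]])
        if (same) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    counts <- lapply(orders, walk_any)
  }
  res <- colMeans(do.call(rbind, counts))
  cache$pair_diffs[[key]] <- res
  res
}

#' Thread two coding sequences through a protein alignment
#'
#' Back-translates a pairwise protein alignment into a gap-free codon
#' alignment: each aligned residue column is replaced by the underlying
#' codons; columns with a gap in either sequence, an ambiguous nucleotide,
#' or a stop codon are dropped.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`), lengths
#'   divisible by 3, no terminal stop codon.
#' @param alignment A pairwise protein alignment as returned by
#'   [global_align()] (list with `aligned_a`, `aligned_b`).
#' @return An object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (character vectors of equal length) and `n_codons`.
#' @export
codon_align <- function(cds_a, cds_b, alignment) {
  tab <- codon_tables()
  cods_a <- split_codons(cds_a)
  cods_b <- split_codons(cds_b)
  ga <- strsplit(alignment$aligned_a, "")[[1]]
  gb <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(ga) != length(gb)) stop("aligned sequences differ in length")
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  if (gsub("-", "", alignment$aligned_a) != prot_a ||
      gsub("-", "", alignment$aligned_b) != prot_b) {
    stop("protein alignment does not match the translated CDS")
  }
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  keep <- which(ga != "-" & gb != "-")
  ca <- cods_a[ia[keep]]
  cb <- cods_b[ib[keep]]
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% tab$stops) & !(cb %in% tab$stops)
  structure(list(codons_a = ca[clean], codons_b = cb[clean],
                 n_codons = sum(clean)),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka and Ks for a codon alignment
#'
#' Synonymous site fractions are computed per codon by enumerating the three
#' single-nucleotide neighbours of each position (changes to stop codons
#' count as nonsynonymous), averaged over the two sequences. Observed
#' differences are averaged over all minimal substitution pathways,
#' excluding pathways that cross a stop codon. Proportions are corrected
#' with Jukes-Cantor, d = -(3/4) log(1 - (4/3) p); p >= 3/4 is flagged
#' saturated rather than raising an error.
#'
#' @param alignment A `codon_alignment` from [codon_align()], or a list with
#'   `codons_a` / `codons_b`.
#' @param min_codons Minimum number of codon columns required (default 10).
#' @return List with `ka`, `ks`, `ratio`, the raw proportions `pn`, `ps`,
#'   site counts `n_sites`, `s_sites`, difference counts `nd`, `sd`, and
#'   logical flags `ka_saturated`, `ks_saturated`.
#' @export
ng86_kaks <- function(alignment, min_codons = 10) {
  tab <- codon_tables()
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  if (length(ca) != length(cb)) stop("codon vectors differ in length")
  if (length(ca) < min_codons) {
    stop("codon alignment has ", length(ca), " codons; need >= ", min_codons)
  }
  if (any(!ca %in% tab$codons) || any(!cb %in% tab$codons)) {
    stop("alignment contains stop or ambiguous codons")
  }
  s1 <- sum(tab$syn_sites[ca])
  s2 <- sum(tab$syn_sites[cb])
  s_sites <- (s1 + s2) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd_tot <- 0
  nd_tot <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) {
      d <- codon_pair_differences(ca[i], cb[i])
      sd_tot <- sd_tot + d[["syn"]]
      nd_tot <- nd_tot + d[["nonsyn"]]
    }
  }
  ps <- if (s_sites > 0) sd_tot / s_sites else 0
  pn <- if (n_sites > 0) nd_tot / n_sites else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  list(ka = ka, ks = ks,
       ratio = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
       pn = pn, ps = ps, n_sites = n_sites, s_sites = s_sites,
       nd = nd_tot, sd = sd_tot,
       ka_saturated = is.na(ka), ks_saturated = is.na(ks))
}

#' Date a duplication event from Ks under a strict molecular clock
#'
#' T = Ks / (2 * lambda) / 1e6 million years, with the synonymous
#' substitution rate lambda defaulting to 6.1e-9 substitutions per
#' synonymous site per year (the legume rate used throughout the package).
#'
#' @param ks Synonymous substitutions per synonymous site (may be a vector).
#' @param lambda_rate Substitutions/site/year; default `6.1e-9`.
#' @return Divergence time(s) in million years; `NA` where `ks` is `NA`
#'   (saturated estimates stay undated).
#' @export
date_duplication <- function(ks, lambda_rate = 6.1e-9) {
  if (any(!is.na(ks) & ks < 0)) stop("ks must be >= 0")
  if (lambda_rate <= 0) stop("lambda_rate must be > 0")
  ks / (2 * lambda_rate) / 1e6
}

#' Classify selection regime and WGD round for a dated pair
#'
#' Selection: purifying if Ka/Ks < 1, positive if > 1, neutral if equal
#' within `1e-9`, undefined if Ks = 0 or either estimate is saturated.
#' WGD round: `recent` if the date is at or below `recent_cutoff_my`
#' (default 25 My, bracketing the ~13 Mya Glycine-specific event),
#' `ancient` up to 65 My (bracketing the ~59 Mya papilionoid event),
#' `pre_wgd` beyond that, `not_assigned` when undated.
#'
#' @param ka,ks NG86 estimates (NA = saturated).
#' @param time_my Divergence time in million years (NA = undated).
#' @param recent_cutoff_my Boundary for the recent WGD round, default 25.
#' @param ancient_cutoff_my Boundary between ancient WGD and older events,
#'   default 65.
#' @return List with `selection` and `wgd_round`.
#' @export
classify_evolution <- function(ka, ks, time_my,
                               recent_cutoff_my = 25, ancient_cutoff_my = 65) {
  selection <- if (is.na(ka) || is.na(ks) || ks == 0) {
    "undefined"
  } else {
    ratio <- ka / ks
    if (abs(ratio - 1) < 1e-9) "neutral"
    else if (ratio < 1) "purifying"
    else "positive"
  }
  wgd_round <- if (is.na(time_my)) {
    "not_assigned"
  } else if (time_my <= recent_cutoff_my) {
    "recent"
  } else if (time_my <= ancient_cutoff_my) {
    "ancient"
  } else {
    "pre_wgd"
  }
  list(selection = selection, wgd_round = wgd_round)
}

#' Full Ka/Ks, dating and classification for one CDS pair
#'
#' Convenience wrapper: aligns the translated proteins globally, threads the
#' codon alignment, runs NG86, dates the duplication and classifies it.
#'
#' @inheritParams codon_align
#' @inheritParams date_duplication
#' @inheritParams classify_evolution
#' @param ... Passed to [global_align()].
#' @return One-row data frame with ka, ks, ratio, time_my, selection,
#'   wgd_round and saturation flags.
#' @export
kaks_pair <- function(cds_a, cds_b, lambda_rate = 6.1e-9,
                      recent_cutoff_my = 25, ...) {
  aln <- global_align(translate_cds(cds_a), translate_cds(cds_b), ...)
  cal <- codon_align(cds_a, cds_b, aln)
  est <- ng86_kaks(cal)
  time_my <- if (is.na(est$ks)) NA_real_ else date_duplication(est$ks, lambda_rate)
  cls <- classify_evolution(est$ka, est$ks, time_my, recent_cutoff_my)
  data.frame(ka = est$ka, ks = est$ks, ratio = est$ratio, time_my = time_my,
             selection = cls$selection, wgd_round = cls$wgd_round,
             ka_saturated = est$ka_saturated, ks_saturated = est$ks_saturated,
             n_codons = cal$n_codons, stringsAsFactors = FALSE)
}

#' Load the packaged divergence table of the 23 segmental duplicate pairs
#'
#' Transcribes the printed per-pair Ka and Ks values (with the printed
#' ratio and date columns retained for regression checking) for the 23
#' WGD/segmentally duplicated pairs of the surveyed soybean family.
#'
#' @return Data frame with columns `pair`, `ka`, `ks`, `ratio_printed`,
#'   `date_printed`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.tsv", package = "famsurvey")
  if (!nzchar(path)) stop("packaged table1.tsv fixture not found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pair", "ka", "ks", "ratio_printed", "date_printed")
  if (!all(needed %in% names(df)) || nrow(df) != 23) {
    stop("table1.tsv fixture is malformed")
  }
  df
}

#' Recompute ratio and duplication date for the packaged pair table
#'
#' For each of the 23 printed (Ka, Ks) pairs, recomputes Ka/Ks and the
#' clock date and compares them with the printed columns. Deviations beyond
#' `tol` relative tolerance are listed (they arise when the printed columns
#' were derived from unrounded inputs). Also emits the summary counts used
#' in the survey: pairs with ratio < 0.6, pairs dating to the recent WGD,
#' and the date extremes.
#'
#' @param lambda_rate Clock rate, default `6.1e-9`.
#' @param recent_cutoff_my Recent-WGD cutoff, default 25 My.
#' @param tol Relative tolerance for the printed-value comparison (default
#'   0.01).
#' @return List with `table` (per-pair recomputation), `summary` (named
#'   numeric vector) and `deviations` (rows exceeding `tol`).
#' @export
table1_regression <- function(lambda_rate = 6.1e-9, recent_cutoff_my = 25,
                              tol = 0.01) {
  df <- table1_fixture()
  df$ratio <- df$ka / df$ks
  df$time_my <- date_duplication(df$ks, lambda_rate)
  df$ratio_rel_dev <- abs(df$ratio - df$ratio_printed) / df$ratio_printed
  df$date_rel_dev <- abs(df$time_my - df$date_printed) / df$date_printed
  df$selection <- ifelse(df$ratio < 1, "purifying",
                         ifelse(df$ratio > 1, "positive", "neutral"))
  summary <- c(
    n_pairs = nrow(df),
    n_ratio_below_0.6 = sum(df$ratio < 0.6),
    n_recent_wgd = sum(df$time_my <= recent_cutoff_my),
    min_date_my = min(df$time_my),
    max_date_my = max(df$time_my),
    max_ratio_rel_dev = max(df$ratio_rel_dev),
    max_date_rel_dev = max(df$date_rel_dev))
  list(table = df,
       summary = summary,
       deviations = df[df$ratio_rel_dev > tol | df$date_rel_dev > tol, ,
                       drop = FALSE])
}
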