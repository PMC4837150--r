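# Per-protein descriptors: length, molecular weight, isoelectric point,
# Kyte-Doolittle transmembrane spans, and conserved-motif occurrences.

protein_mw <- function(chars) {
  (sum(RESIDUE_MASS[chars]) + WATER_MASS) / 1000  # kilodaltons
}

net_charge_at_ph <- function(chars, ph) {
  charge <- 1 / (1 + 10^(ph - PKA_SET$nterm))
  for (res in names(PKA_SET$positive)) {
    n <- sum(chars == res)
    if (n) charge <- charge + n / (1 + 10^(ph - PKA_SET$positive[[res]]))
  }
  charge <- charge - 1 / (1 + 10^(PKA_SET$cterm - ph))
  for (res in names(PKA_SET$negative)) {
    n <- sum(chars == res)
    if (n) charge <- charge - n / (1 + 10^(PKA_SET$negative[[res]] - ph))
  }
  charge
}

protein_pi <- function(chars, tol = 1e-4) {
  lo <- 0; hi <- 14
  # termini guarantee charge(0) > 0 > charge(14), so bisection converges
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    q <- net_charge_at_ph(chars, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Length, molecular weight and isoelectric point of proteins
#'
#' Molecular weight is the sum of average residue masses plus one water
#' (reported in kD). The isoelectric point is solved by bisection on the
#' Henderson-Hasselbalch net charge (termini plus D, E, C, Y, H, K, R side
#' chains, Lehninger pKa set) to |charge| < 1e-4.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @return Data frame with `gene_id`, `length`, `mw` (kD), `pi`.
#' @export
compute_stats <- function(proteins) {
  seqs <- vapply(proteins, as.character, "")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    chars <- check_protein(seqs[i])
    data.frame(gene_id = ids[i], length = length(chars),
               mw = protein_mw(chars), pi = protein_pi(chars),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict transmembrane spans by sliding-window hydropathy
#'
#' A windowed-mean Kyte-Doolittle scan: maximal runs of positions whose
#' centred window mean is at or above the threshold are reported, runs
#' separated by gaps of at most `merge_gap` residues are merged, and runs
#' shorter than `min_length` residues are discarded. This is a transparent
#' surrogate for HMM-based TM predictors and preserves their downstream
#' contract (a per-protein span count, possibly zero).
#'
#' @param protein Protein sequence.
#' @param window Odd window size >= 7 (default 19).
#' @param threshold Mean hydropathy cutoff (default 1.6).
#' @param merge_gap Maximum gap merged between runs (default 5).
#' @param min_length Minimum span length kept (default 15).
#' @return Matrix of 0-based half-open intervals (`start`, `end`); zero
#'   rows when the sequence is shorter than the window or no span passes.
#' @export
predict_tm_regions <- function(protein, window = 19, threshold = 1.6,
                               merge_gap = 5, min_length = 15) {
  if (window %% 2 == 0 || window < 7) stop("window must be odd and >= 7")
  chars <- check_protein(protein)
  L <- length(chars)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (L < window) return(empty)
  h <- KD_HYDROPATHY[chars]
  cs <- c(0, cumsum(h))
  half <- (window - 1) / 2
  centers <- (half + 1):(L - half)
  means <- (cs[centers + half + 1] - cs[centers - half]) / window
  above <- centers[means >= threshold]
  if (!length(above)) return(empty)
  # maximal runs
  runs <- split(above, cumsum(c(1, diff(above) > 1)))
  iv <- t(vapply(runs, function(r) c(min(r), max(r)), numeric(2)))
  # merge runs separated by <= merge_gap residues
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv[i, 1] - merged[last, 2] - 1 <= merge_gap) {
        merged[last, 2] <- iv[i, 2]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1) >= min_length
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  out <- cbind(start = merged[, 1] - 1L, end = merged[, 2])  # 0-based half-open
  rownames(out) <- NULL
  out
}

#' Load the packaged conserved-motif catalog
#'
#' Twenty consensus motifs (width 20-164 aa) transcribed from the published
#' survey of the family. Each entry's stored width is checked against its
#' sequence length at load; a mismatch is flagged with a warning rather
#' than silently corrected.
#'
#' @return Data frame with `motif_id`, `width`, `sequence`.
#' @export
motif_catalog <- function() {
  path <- system.file("extdata", "motif_catalog.tsv", package = "famsurvey")
  if (!nzchar(path)) stop("packaged motif catalog not found")
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- which(nchar(cat$sequence) != cat$width)
  if (length(bad)) {
    warning("motif width/sequence mismatch for motif_id ",
            paste(cat$motif_id[bad], collapse = ", "))
  }
  cat
}

#' Scan a protein for catalog motif occurrences
#'
#' Exact-width Hamming scan (no gaps): every placement of each motif with
#' at most `max_mismatch` mismatches is a candidate; overlapping placements
#' of the same motif are deduplicated to the best (fewest mismatches,
#' leftmost on ties). Motifs longer than the protein simply yield no
#' occurrence.
#'
#' @param protein Protein sequence.
#' @param catalog Data frame from [motif_catalog()].
#' @param max_mismatch Maximum Hamming mismatches; default 10% of each
#'   motif's width, rounded down.
#' @param gene_id Optional identifier copied into the result.
#' @return Data frame with `gene_id`, `motif_id`, `start` (0-based),
#'   `mismatches`.
#' @export
scan_motifs <- function(protein, catalog = motif_catalog(),
                        max_mismatch = NULL, gene_id = NA) {
  chars <- check_protein(protein)
  L <- length(chars)
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    motif <- strsplit(catalog$sequence[i], "")[[1]]
    W <- length(motif)
    mm_cap <- if (is.null(max_mismatch)) floor(0.1 * W) else max_mismatch
    if (W > L) next
    starts <- 1:(L - W + 1)
    mism <- vapply(starts, function(s) sum(chars[s:(s + W - 1)] != motif),
                   integer(1))
    cand <- which(mism <= mm_cap)
    if (!length(cand)) next
    # deduplicate overlapping placements to the best
    taken <- logical(L)
    ord <- cand[order(mism[cand], cand)]
    for (s in ord) {
      span <- s:(s + W - 1)
      if (!any(taken[span])) {
        taken[span] <- TRUE
        out[[length(out) + 1]] <- data.frame(
          gene_id = gene_id, motif_id = catalog$motif_id[i],
          start = s - 1L, mismatches = mism[s], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), motif_id = integer(),
                      start = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$motif_id, res$start), , drop = FALSE]
}
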