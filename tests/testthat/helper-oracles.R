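# Independent oracles used to check the package implementations on small
# instances. These are written naively on purpose and share nothing with
# the implementation paths they verify except the standard genetic code.

GC_MAP <- Biostrings::GENETIC_CODE

oracle_split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# --- NG86 oracle ------------------------------------------------------------
# Site fractions by neighbour enumeration; differences by recursive
# enumeration of substitution orders (stop-crossing paths skipped, with
# all-paths fallback); Jukes-Cantor correction.

oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- nt
      if (GC_MAP[[paste(mut, collapse = "")]] == GC_MAP[[codon]]) {
        total <- total + 1 / 3
      }
    }
  }
  total
}

oracle_pair_paths <- function(ca, cb, allow_stops = FALSE) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diff <- which(a != b)
  if (!length(diff)) return(matrix(c(0, 0), 1))
  recurse <- function(cur, remaining) {
    if (!length(remaining)) return(matrix(c(0, 0), 1))
    out <- NULL
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- b[pos]
      cod_c <- paste(cur, collapse = ""); cod_n <- paste(nxt, collapse = "")
      if (!allow_stops && (GC_MAP[[cod_n]] == "*")) next
      step <- if (GC_MAP[[cod_c]] == GC_MAP[[cod_n]]) c(1, 0) else c(0, 1)
      tails <- recurse(nxt, setdiff(remaining, pos))
      if (!is.null(tails)) {
        out <- rbind(out, sweep(tails, 2, step, "+"))
      }
    }
    out
  }
  paths <- recurse(a, diff)
  if (is.null(paths)) paths <- oracle_pair_paths(ca, cb, allow_stops = TRUE)
  paths
}

oracle_ng86 <- function(codons_a, codons_b) {
  L <- length(codons_a)
  s_sites <- (sum(vapply(codons_a, oracle_syn_sites, 0)) +
                sum(vapply(codons_b, oracle_syn_sites, 0))) / 2
  n_sites <- 3 * L - s_sites
  sd_tot <- 0; nd_tot <- 0
  for (i in seq_len(L)) {
    paths <- oracle_pair_paths(codons_a[i], codons_b[i])
    sd_tot <- sd_tot + mean(paths[, 1])
    nd_tot <- nd_tot + mean(paths[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(ka = jc(nd_tot / n_sites), ks = jc(sd_tot / s_sites),
       sd = sd_tot, nd = nd_tot, s_sites = s_sites, n_sites = n_sites)
}

random_sense_cds <- function(n_codons) {
  sense <- setdiff(names(GC_MAP), names(GC_MAP)[GC_MAP == "*"])
  paste(sample(sense, n_codons, TRUE), collapse = "")
}

# a random mutated copy (may hit stops -> resample the codon)
mutate_cds_random <- function(cds, n_subs) {
  cods <- oracle_split_codons(cds)
  for (k in seq_len(n_subs)) {
    repeat {
      i <- sample.int(length(cods), 1)
      chars <- strsplit(cods[i], "")[[1]]
      pos <- sample.int(3, 1)
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
      mut <- paste(chars, collapse = "")
      if (GC_MAP[[mut]] != "*") { cods[i] <- mut; break }
    }
  }
  paste(cods, collapse = "")
}

# --- global alignment oracle ------------------------------------------------
# Exhaustive enumeration of all global alignments with affine gap cost
# (a gap of length L costs gap_open + gap_extend * L), matching the
# Biostrings convention used by global_align().

brute_force_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      recurse(i + 1, j + 1, score + sub[A[i], B[j]], "m")
    }
    if (i <= length(A)) {  # gap in b
      pen <- gap_extend + if (state == "ga") 0 else gap_open
      recurse(i + 1, j, score - pen, "ga")
    }
    if (j <= length(B)) {  # gap in a
      pen <- gap_extend + if (state == "gb") 0 else gap_open
      recurse(i, j + 1, score - pen, "gb")
    }
  }
  recurse(1, 1, 0, "m")
  best
}

# --- collinearity oracle ----------------------------------------------------
# Exhaustive search over all subsets of anchors for the largest valid
# monotone chain (either orientation) under the rank-gap constraint.

brute_force_chain_size <- function(ra, rb, max_rank_gap) {
  n <- length(ra)
  best <- 0
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ord <- idx[order(ra[idx])]
    a <- ra[ord]; b <- rb[ord]
    if (any(duplicated(a)) || any(duplicated(b))) next
    ok_gap_a <- all(diff(a) > 0) && all(diff(a) <= max_rank_gap)
    up <- all(diff(b) > 0) && all(diff(b) <= max_rank_gap)
    down <- all(diff(b) < 0) && all(-diff(b) <= max_rank_gap)
    if (ok_gap_a && (up || down)) best <- length(idx)
  }
  best
}

# --- additive tree / four-point oracle --------------------------------------

# distance matrix of a random additive 4-taxon tree with topology ((A,B),(C,D))
random_additive_quartet <- function() {
  e <- stats::runif(5, 0.05, 1)  # a, b, c, d, internal
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- e[1] + e[2]
  d["C", "D"] <- d["D", "C"] <- e[3] + e[4]
  d["A", "C"] <- d["C", "A"] <- e[1] + e[5] + e[3]
  d["A", "D"] <- d["D", "A"] <- e[1] + e[5] + e[4]
  d["B", "C"] <- d["C", "B"] <- e[2] + e[5] + e[3]
  d["B", "D"] <- d["D", "B"] <- e[2] + e[5] + e[4]
  d
}

# which pairing the four-point condition supports: the split with the
# SMALLEST sum is the cherry pairing of the true topology
four_point_split <- function(d) {
  sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
            AC_BD = d["A", "C"] + d["B", "D"],
            AD_BC = d["A", "D"] + d["B", "C"])
  names(which.min(sums))
}

tree_has_cherry <- function(phy, pair) {
  pairs <- ape::prop.part(phy)
  any(vapply(ape::prop.part(phy), function(p) {
    tips <- attr(pairs, "labels")[p]
    setequal(tips, pair) || setequal(tips, setdiff(phy$tip.label, pair))
  }, TRUE))
}

random_protein_seq <- function(n) {
  paste(sample(famsurvey:::AMINO_ACIDS, n, TRUE), collapse = "")
}
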