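# Synthetic genome generator: plants a fully specified gene-family
# structure (subfamilies, tandem arrays, collinear blocks with controlled
# synonymous divergence, truncated-domain decoys, background genes, and an
# 11-tissue count matrix) so that every downstream stage can be validated
# against ground truth.

NTS <- c("A", "C", "G", "T")

random_protein <- function(n) paste(sample(AMINO_ACIDS, n, TRUE), collapse = "")

mutate_protein <- function(protein, rate) {
  chars <- strsplit(protein, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- vapply(which(hit), function(i)
    sample(setdiff(AMINO_ACIDS, chars[i]), 1), "")
  paste(chars, collapse = "")
}

back_translate <- function(protein) {
  tab <- codon_tables()
  by_aa <- split(tab$codons, tab$aa)
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Core mutation engine (RNG state of the caller is used; the exported
# evolve_cds() wraps it with an explicit seed).
evolve_cds_impl <- function(cds, target_ks, target_ka) {
  tab <- codon_tables()
  gc_map <- Biostrings::GENETIC_CODE
  cods <- split_codons(cds)
  if (any(cods %in% tab$stops)) stop("input CDS contains a stop codon")
  s_sites <- sum(tab$syn_sites[cods])
  n_sites <- 3 * length(cods) - s_sites
  n_syn <- round(target_ks * s_sites)
  n_non <- round(target_ka * n_sites)
  events <- sample(c(rep("s", n_syn), rep("n", n_non)))
  max_attempts <- 50 * (n_syn + n_non) + 1000
  attempts <- 0L
  for (ev in events) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("mutation target unreachable without stop codons after ",
             max_attempts, " attempts")
      }
      i <- sample.int(length(cods), 1)
      pos <- sample.int(3, 1)
      chars <- strsplit(cods[i], "")[[1]]
      nt <- sample(setdiff(NTS, chars[pos]), 1)
      chars[pos] <- nt
      mut <- paste(chars, collapse = "")
      if (gc_map[[mut]] == "*") next
      is_syn <- gc_map[[mut]] == gc_map[[cods[i]]]
      if ((ev == "s") == is_syn) {
        cods[i] <- mut
        break
      }
    }
  }
  paste(cods, collapse = "")
}

#' Mutate a coding sequence to planted synonymous/nonsynonymous targets
#'
#' Substitution events are drawn one at a time: a codon and position are
#' picked uniformly and the change is accepted only if it matches the
#' requested site class (synonymous = amino acid preserved) and introduces
#' no stop codon; the search is bounded at 50x the event count. Event
#' counts are `round(target * NG86 site count)`, so multiple hits accrue
#' naturally and the Jukes-Cantor-corrected NG86 estimate recovers the
#' targets in expectation.
#'
#' @param cds Coding sequence (length divisible by 3, no stop codons).
#' @param target_ks,target_ka Planted substitutions per synonymous /
#'   nonsynonymous site (>= 0).
#' @param seed RNG seed.
#' @return The mutated CDS (same length).
#' @export
evolve_cds <- function(cds, target_ks, target_ka, seed = 17) {
  if (target_ks < 0 || target_ka < 0) stop("targets must be >= 0")
  withr::with_seed(seed, evolve_cds_impl(as.character(cds), target_ks, target_ka))
}

default_tandem_arrays <- function() {
  data.frame(
    array = 1:8,
    size = c(2, 2, 2, 2, 5, 6, 6, 11),
    gap = 0,
    subfamily = c("AAP", "AUX", "CAT", "ATLb", "LHT", "GAT", "ATLb", "AAP"),
    chromosome = c(NA, NA, NA, NA, NA, NA, "chr19", "chr20"),
    attach_block = c(1, 2, 3, 6, 4, 5, NA, NA),
    attach_anchor = c(1, 1, 1, 1, 2, 4, NA, NA),
    stringsAsFactors = FALSE)
}

default_collinear_blocks <- function() {
  list(
    list(source = "chr02", target = "chr11", target_ks = 0.10,
         subfamilies = c("AAP", "LHT", "ProT", "GAT")),
    list(source = "chr04", target = "chr09", target_ks = 0.15,
         subfamilies = c("AUX", "ANT", "ATLa", "ATLb")),
    list(source = "chr05", target = "chr13", target_ks = 0.25,
         subfamilies = c("CAT", "ACT", "PHS", "AAP")),
    list(source = "chr10", target = "chr18", target_ks = 0.35,
         subfamilies = c("AUX", "LHT", "CAT", "ANT")),
    list(source = "chr01", target = "chr06", target_ks = 0.45,
         subfamilies = c("ProT", "ATLa", "PHS", "GAT")),
    list(source = "chr03", target = "chr12", target_ks = 0.90,
         subfamilies = c("ATLb", "ACT", "AAP")))
}

#' Generator configuration
#'
#' Defaults emulate the surveyed soybean family at full planted scale: 189
#' intact members across the 12 subfamilies, 17 truncated-domain decoys,
#' eight tandem groups of sizes 2/2/2/2/5/6/6/11 (36 genes), six collinear
#' blocks totalling 23 anchor pairs (46 WGD genes, six of which are also
#' tandem-array representatives and hence dual-mode), 20 chromosomes, and
#' the 11 reference tissues.
#'
#' @param n_chromosomes Number of chromosomes (default 20).
#' @param chromosome_length Optional fixed chromosome length (bp); laid-out
#'   content exceeding it raises a sizing error; `NULL` (default) sizes
#'   each chromosome to its content.
#' @param n_background_genes Non-family genes used as spacers (default 450).
#' @param subfamily_plan Named member counts per subfamily (default sums to
#'   189).
#' @param tandem_arrays Data frame of planted arrays (see
#'   `default_tandem_arrays()`): size, intervening-gene gap, subfamily,
#'   chromosome (or attachment to a block anchor, which makes the
#'   representative dual-mode).
#' @param collinear_blocks List of planted blocks: source/target
#'   chromosome, anchor subfamilies, planted Ks.
#' @param decoy_truncated Number of truncated-domain decoys (default 17).
#' @param tissues Ordered tissue labels (default the 11 reference tissues).
#' @param expression_plan List with `n_constitutive`, `n_silent`,
#'   `pair_type_split` (named I/II/III counts over the planted block
#'   pairs), `type_ii_ratio`.
#' @param noise_sigma Log-normal count noise sigma (default 0.08).
#' @param member_ka,member_ks Divergence of ordinary members from their
#'   subfamily founder (default 0.35 / 0.6: old paralogs, ~50% protein
#'   identity between members).
#' @param tandem_ka,tandem_ks Divergence of extra tandem copies from the
#'   array representative (default 0.03 / 0.08: recent duplicates).
#' @param block_ka_fraction Ka as a fraction of each block's planted Ks
#'   (default 0.1: purifying selection).
#' @param decoy_ka,decoy_ks Divergence of decoys from their subfamily
#'   founder (default 0.1 / 0.2: recent truncation events).
#' @param domain_length Diagnostic domain length in residues (default 80).
#' @param seed Master seed (default 17).
#' @return A classed list (`generator_config`).
#' @export
generator_config <- function(n_chromosomes = 20,
                             chromosome_length = NULL,
                             n_background_genes = 500,
                             subfamily_plan = c(
                               AAP = 35, LHT = 22, ProT = 6, GAT = 19,
                               AUX = 16, ANT = 9, ATLa = 16, ATLb = 30,
                               TTP = 1, CAT = 19, ACT = 7, PHS = 9),
                             tandem_arrays = default_tandem_arrays(),
                             collinear_blocks = default_collinear_blocks(),
                             decoy_truncated = 17,
                             tissues = DEFAULT_TISSUES,
                             expression_plan = list(
                               n_constitutive = 35, n_silent = 18,
                               pair_type_split = c(I = 8, II = 8, III = 7),
                               type_ii_ratio = 4),
                             noise_sigma = 0.08,
                             member_ka = 0.15, member_ks = 0.5,
                             tandem_ka = 0.03, tandem_ks = 0.08,
                             block_ka_fraction = 0.1,
                             decoy_ka = 0.1, decoy_ks = 0.2,
                             domain_length = 100,
                             seed = 17) {
  cfg <- list(n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              n_background_genes = n_background_genes,
              subfamily_plan = subfamily_plan,
              tandem_arrays = tandem_arrays,
              collinear_blocks = collinear_blocks,
              decoy_truncated = decoy_truncated,
              tissues = tissues,
              expression_plan = expression_plan,
              noise_sigma = noise_sigma,
              member_ka = member_ka, member_ks = member_ks,
              tandem_ka = tandem_ka, tandem_ks = tandem_ks,
              block_ka_fraction = block_ka_fraction,
              decoy_ka = decoy_ka, decoy_ks = decoy_ks,
              domain_length = domain_length,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$n_background_genes >= 0,
            cfg$decoy_truncated >= 0, all(cfg$subfamily_plan >= 0))
  if (anyDuplicated(cfg$tissues)) stop("tissue labels must be unique")
  if (!all(names(cfg$subfamily_plan) %in% SUBFAMILY_CATALOG)) {
    stop("unknown subfamily in plan")
  }
  for (b in cfg$collinear_blocks) {
    if (b$target_ks < 0 || b$target_ks > 1.5) {
      stop("block target_ks must lie in [0, 1.5]")
    }
  }
  ta <- cfg$tandem_arrays
  if (nrow(ta) && any(ta$size < 2)) stop("tandem arrays need >= 2 members")
  # member budget per subfamily must cover planted structure
  need <- stats::setNames(rep(0, length(cfg$subfamily_plan)),
                          names(cfg$subfamily_plan))
  for (b in cfg$collinear_blocks) {
    for (s in b$subfamilies) need[s] <- need[s] + 2
  }
  if (nrow(ta)) {
    extra <- ifelse(is.na(ta$attach_block), ta$size, ta$size - 1)
    for (i in seq_len(nrow(ta))) need[ta$subfamily[i]] <-
        need[ta$subfamily[i]] + extra[i]
  }
  short <- need > cfg$subfamily_plan[names(need)]
  if (any(short)) {
    stop("subfamily plan too small for planted structure: ",
         paste(names(need)[short], collapse = ", "))
  }
  invisible(cfg)
}

# ---- internal generation ---------------------------------------------------

make_founders <- function(cfg) {
  # one diagnostic domain consensus per group; founders carry a mildly
  # diverged copy of their group's domain at the C-terminal end (short tail)
  domains <- list(aa_trans = random_protein(cfg$domain_length),
                  aa_permease = random_protein(cfg$domain_length))
  founders <- list()
  for (sf in names(cfg$subfamily_plan)) {
    group <- SUBFAMILY_GROUP[[sf]]
    dom_id <- if (group == "AAAP") "aa_trans" else "aa_permease"
    prefix_len <- sample(120:300, 1)
    prot <- paste0(random_protein(prefix_len),
                   mutate_protein(domains[[dom_id]], 0.1),
                   random_protein(8))
    founders[[sf]] <- list(protein = prot, cds = back_translate(prot),
                           prefix_len = prefix_len, domain_id = dom_id)
  }
  list(domains = domains, founders = founders)
}

make_gene_roster <- function(cfg, founders) {
  # Returns a list of gene descriptors with planted roles; CDS filled in.
  plan <- cfg$subfamily_plan
  used <- stats::setNames(rep(0, length(plan)), names(plan))
  genes <- list()
  gid <- 0
  new_gene <- function(role, subfamily, cds, ...) {
    gid <<- gid + 1
    c(list(gene_id = sprintf("g%04d", gid), role = role,
           subfamily = subfamily, cds = cds), list(...))
  }
  member_cds <- function(sf) {
    evolve_cds_impl(founders$founders[[sf]]$cds, cfg$member_ks, cfg$member_ka)
  }
  # block anchors
  for (bi in seq_along(cfg$collinear_blocks)) {
    b <- cfg$collinear_blocks[[bi]]
    for (ai in seq_along(b$subfamilies)) {
      sf <- b$subfamilies[ai]
      src <- member_cds(sf)
      tgt <- evolve_cds_impl(src, b$target_ks,
                             cfg$block_ka_fraction * b$target_ks)
      used[sf] <- used[sf] + 2
      genes[[length(genes) + 1]] <- new_gene(
        "family", sf, src, block = bi, anchor = ai, side = "source",
        chromosome = b$source, target_ks = b$target_ks)
      genes[[length(genes) + 1]] <- new_gene(
        "family", sf, tgt, block = bi, anchor = ai, side = "target",
        chromosome = b$target, target_ks = b$target_ks)
    }
  }
  # tandem arrays (attached arrays grow from a block source anchor)
  ta <- cfg$tandem_arrays
  for (i in seq_len(nrow(ta))) {
    sf <- ta$subfamily[i]
    if (!is.na(ta$attach_block[i])) {
      rep_idx <- which(vapply(genes, function(g)
        isTRUE(g$block == ta$attach_block[i]) &&
          isTRUE(g$anchor == ta$attach_anchor[i]) &&
          identical(g$side, "source"), logical(1)))
      if (length(rep_idx) != 1) stop("array attachment does not match a block anchor")
      if (genes[[rep_idx]]$subfamily != sf) {
        stop("attached array subfamily must match its anchor")
      }
      genes[[rep_idx]]$array <- ta$array[i]
      rep_cds <- genes[[rep_idx]]$cds
      chrom <- genes[[rep_idx]]$chromosome
      n_extra <- ta$size[i] - 1
    } else {
      rep_cds <- member_cds(sf)
      used[sf] <- used[sf] + 1
      chrom <- ta$chromosome[i]
      genes[[length(genes) + 1]] <- new_gene(
        "family", sf, rep_cds, array = ta$array[i], chromosome = chrom)
      n_extra <- ta$size[i] - 1
    }
    for (k in seq_len(n_extra)) {
      used[sf] <- used[sf] + 1
      genes[[length(genes) + 1]] <- new_gene(
        "family", sf, evolve_cds_impl(rep_cds, cfg$tandem_ks, cfg$tandem_ka),
        array = ta$array[i], chromosome = chrom)
    }
  }
  # ordinary members fill the plan
  for (sf in names(plan)) {
    for (k in seq_len(plan[[sf]] - used[[sf]])) {
      genes[[length(genes) + 1]] <- new_gene("family", sf, member_cds(sf))
    }
  }
  # decoys: recent member-like genes truncated partway into the domain
  for (k in seq_len(cfg$decoy_truncated)) {
    sf <- sample(names(plan)[plan > 0], 1)
    full <- evolve_cds_impl(founders$founders[[sf]]$cds, cfg$decoy_ks,
                            cfg$decoy_ka)
    prefix_len <- founders$founders[[sf]]$prefix_len
    keep_codons <- prefix_len + floor(0.4 * cfg$domain_length)
    genes[[length(genes) + 1]] <- new_gene(
      "decoy", sf, substr(full, 1, 3 * keep_codons))
  }
  # background genes: random proteins, no domain
  for (k in seq_len(cfg$n_background_genes)) {
    genes[[length(genes) + 1]] <- new_gene(
      "background", NA_character_, back_translate(random_protein(sample(150:450, 1))))
  }
  genes
}

assign_chromosomes <- function(cfg, genes) {
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  # chromosomes carrying a block anchored in subfamily s are off-limits for
  # that subfamily's unplanted members; cap two members per subfamily per
  # chromosome to keep chance collinear chains impossible
  excluded <- list()
  for (b in cfg$collinear_blocks) {
    for (s in b$subfamilies) {
      excluded[[s]] <- union(excluded[[s]], c(b$source, b$target))
    }
  }
  count <- matrix(0, nrow = length(cfg$subfamily_plan), ncol = length(chroms),
                  dimnames = list(names(cfg$subfamily_plan), chroms))
  # balance total family items per chromosome so background spacers suffice
  load <- stats::setNames(rep(0, length(chroms)), chroms)
  for (g in genes) {
    if (!is.null(g$chromosome) && !is.na(g$chromosome)) {
      load[g$chromosome] <- load[g$chromosome] + 1
    }
  }
  bg_i <- 0
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (!is.null(g$chromosome) && !is.na(g$chromosome)) next
    if (g$role == "background") {
      bg_i <- bg_i + 1
      genes[[i]]$chromosome <- chroms[(bg_i - 1) %% length(chroms) + 1]
    } else if (g$role == "decoy") {
      pick <- names(which.min(load))
      genes[[i]]$chromosome <- pick
      load[pick] <- load[pick] + 1
    } else {
      allowed <- setdiff(chroms, excluded[[g$subfamily]])
      allowed <- allowed[count[g$subfamily, allowed] < 2]
      if (!length(allowed)) stop("no chromosome available for ", g$subfamily)
      pick <- allowed[which.min(load[allowed])]
      genes[[i]]$chromosome <- pick
      count[g$subfamily, pick] <- count[g$subfamily, pick] + 1
      load[pick] <- load[pick] + 1
    }
  }
  genes
}

# Order genes along each chromosome. Planted structure is kept intact:
# each block side is laid out as a contiguous run of its anchors in anchor
# order, each array as a contiguous run (representative first); everything
# else is shuffled. Family-ish items are separated by at least
# (tandem max gap + 1) background genes so no unplanned adjacency arises.
layout_chromosomes <- function(cfg, genes) {
  by_chrom <- split(seq_along(genes),
                    vapply(genes, `[[`, "", "chromosome"))
  bg_pool <- which(vapply(genes, function(g) g$role == "background", TRUE))
  bg_by_chrom <- split(bg_pool, vapply(genes[bg_pool], `[[`, "", "chromosome"))
  order_out <- list()
  for (chrom in names(by_chrom)) {
    idx <- by_chrom[[chrom]]
    is_bg <- vapply(genes[idx], function(g) g$role == "background", TRUE)
    bg <- idx[is_bg]
    fam <- idx[!is_bg]
    arr_of <- vapply(genes[fam], function(g) g$array %||% NA_real_, 0)
    blk_of <- vapply(genes[fam], function(g) g$block %||% NA_real_, 0)
    anch_of <- vapply(genes[fam], function(g) g$anchor %||% NA_real_, 0)
    # attached arrays (containing a block anchor) are emitted with the block
    attached <- unique(arr_of[!is.na(arr_of) & !is.na(blk_of)])
    items <- list()
    used <- logical(length(fam))
    for (a in sort(unique(arr_of[!is.na(arr_of)]))) {
      sel <- !is.na(arr_of) & arr_of == a
      used[sel] <- TRUE
      if (a %in% attached) next  # rides with the block segment
      items[[length(items) + 1]] <- list(kind = "array",
                                         genes = order_array(genes, fam[sel]))
    }
    anchors_here <- fam[!is.na(blk_of)]
    if (length(anchors_here)) {
      anchors_here <- anchors_here[order(anch_of[!is.na(blk_of)])]
      items[[length(items) + 1]] <- list(kind = "block", genes = anchors_here)
      used[fam %in% anchors_here] <- TRUE
    }
    for (g in fam[!used]) {
      items[[length(items) + 1]] <- list(kind = "single", genes = g)
    }
    if (length(items) > 1) items <- items[sample.int(length(items))]
    # lay out with background spacers (>= 2 between family items)
    seq_genes <- integer(0)
    bgq <- bg
    take_bg <- function(n) {
      n <- min(n, length(bgq))
      out <- bgq[seq_len(n)]
      bgq <<- bgq[-seq_len(n)]
      out
    }
    for (it in items) {
      if (length(seq_genes)) seq_genes <- c(seq_genes, take_bg(2))
      if (it$kind == "block") {
        for (k in seq_along(it$genes)) {
          if (k > 1) seq_genes <- c(seq_genes, take_bg(2))
          g <- it$genes[k]
          garr <- genes[[g]]$array
          if (!is.null(garr)) {
            sel <- !is.na(arr_of) & arr_of == garr
            seq_genes <- c(seq_genes, order_array(genes, fam[sel]))
          } else {
            seq_genes <- c(seq_genes, g)
          }
        }
      } else {
        seq_genes <- c(seq_genes, it$genes)
      }
    }
    seq_genes <- c(seq_genes, bgq)  # leftover background at the end
    order_out[[chrom]] <- seq_genes
  }
  order_out
}

order_array <- function(genes, members) {
  # representative (the member that is a block anchor, else the first) first
  is_anchor <- vapply(genes[members], function(g) !is.null(g$block), TRUE)
  c(members[is_anchor], members[!is_anchor])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_exons <- function(cds_len, n_exons) {
  if (n_exons == 1) return(cds_len)
  for (try in 1:100) {
    cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
    lens <- diff(c(0, cuts, cds_len))
    if (all(lens >= 9)) return(lens)
  }
  lens <- rep(cds_len %/% n_exons, n_exons)
  lens[n_exons] <- lens[n_exons] + cds_len %% n_exons
  lens
}

build_gene_model <- function(gene_id, chrom, cds, offset) {
  L <- nchar(cds)
  n_exons <- sample.int(min(17, max(1, L %/% 60)), 1)
  exon_lens <- split_exons(L, n_exons)
  strand <- sample(c("+", "-"), 1)
  intron_lens <- if (n_exons > 1) sample(60:200, n_exons - 1, TRUE) else integer(0)
  rel <- matrix(0L, nrow = n_exons, ncol = 2)  # transcript-orientation coords
  pos <- 0L
  for (k in seq_len(n_exons)) {
    rel[k, ] <- c(pos, pos + exon_lens[k])
    pos <- pos + exon_lens[k]
    if (k < n_exons) pos <- pos + intron_lens[k]
  }
  R <- pos
  if (strand == "-") {
    rel <- cbind(R - rel[, 2], R - rel[, 1])
    rel <- rel[order(rel[, 1]), , drop = FALSE]
  }
  exons <- rel + offset  # absolute 0-based half-open
  storage.mode(exons) <- "integer"
  list(gene_id = gene_id, chromosome = chrom, strand = strand,
       exons = exons, cds = cds, has_utr = FALSE)
}

assign_expression_archetypes <- function(cfg, truth) {
  truth$archetype <- NA_character_
  truth$pref_tissue <- NA_character_
  truth$pair_id <- NA_character_
  truth$pair_type <- NA_character_
  # planted block pairs get the three divergence types
  split3 <- cfg$expression_plan$pair_type_split
  anchors <- truth[!is.na(truth$block), ]
  anchors <- anchors[order(anchors$block, anchors$anchor, anchors$side), ]
  pair_keys <- unique(paste(anchors$block, anchors$anchor))
  types <- rep(names(split3), times = split3)
  if (length(types) < length(pair_keys)) {
    types <- c(types, rep("I", length(pair_keys) - length(types)))
  }
  for (pi in seq_along(pair_keys)) {
    sel <- paste(truth$block, truth$anchor) == pair_keys[pi] & !is.na(truth$block)
    truth$pair_id[sel] <- sprintf("pair%02d", pi)
    truth$pair_type[sel] <- types[pi]
    truth$archetype[sel] <- paste0("pair_", types[pi])
  }
  # remaining family genes: constitutive / silent / preferential
  rest <- which(truth$role == "family" & is.na(truth$archetype))
  rest <- rest[sample.int(length(rest))]
  n_con <- min(cfg$expression_plan$n_constitutive, length(rest))
  n_sil <- min(cfg$expression_plan$n_silent, length(rest) - n_con)
  truth$archetype[rest[seq_len(n_con)]] <- "constitutive"
  truth$archetype[rest[n_con + seq_len(n_sil)]] <- "silent"
  pref <- if (n_con + n_sil < length(rest)) rest[-(seq_len(n_con + n_sil))]
          else integer(0)
  truth$archetype[pref] <- "preferential"
  truth$pref_tissue[pref] <- if (length(cfg$tissues))
    sample(cfg$tissues, length(pref), TRUE) else NA_character_
  # decoys and background are constitutive
  truth$archetype[is.na(truth$archetype)] <- "constitutive"
  truth
}

expression_means <- function(cfg, truth, mrna_lengths) {
  tissues <- cfg$tissues
  nt <- length(tissues)
  means <- matrix(0, nrow = nrow(truth), ncol = nt,
                  dimnames = list(truth$gene_id, tissues))
  loguni <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  pair_profiles <- list()
  for (i in seq_len(nrow(truth))) {
    a <- truth$archetype[i]
    if (a == "constitutive") {
      means[i, ] <- loguni(1, 5, 50)
    } else if (a == "silent") {
      means[i, ] <- 0.05
    } else if (a == "preferential") {
      base <- stats::runif(nt, 2, 4)
      base[tissues == truth$pref_tissue[i]] <- 40
      means[i, ] <- base
    } else if (startsWith(a, "pair_")) {
      pid <- truth$pair_id[i]
      type <- truth$pair_type[i]
      if (is.null(pair_profiles[[pid]])) {
        pair_profiles[[pid]] <- loguni(nt, 2, 50)
      }
      base <- pair_profiles[[pid]]
      second <- truth$side[i] == "target"
      means[i, ] <- if (type == "I") {
        base
      } else if (type == "II") {
        if (second) base / cfg$expression_plan$type_ii_ratio else base
      } else {
        if (second) loguni(nt, 2, 50) else base
      }
    } else {
      stop("unknown expression archetype: ", a)
    }
  }
  means
}

#' Generate counts and library sizes for a synthetic bundle
#'
#' Counts are drawn around the archetype RPKM means with multiplicative
#' log-normal noise (sigma per config) and rounded to integers; silent
#' genes stay below RPKM 1 in every tissue by construction.
#'
#' @param bundle A `synthetic_bundle` from [generate_genome()].
#' @param seed RNG seed (defaults to the bundle config seed + 1).
#' @return List with `counts` (integer matrix), `library_sizes`, and the
#'   noise-free `means` (RPKM scale).
#' @export
generate_expression <- function(bundle, seed = NULL) {
  cfg <- bundle$config
  if (is.null(seed)) seed <- cfg$seed + 1
  withr::with_seed(seed, {
    tissues <- cfg$tissues
    mrna_lengths <- vapply(bundle$gene_models, function(g) nchar(g$cds), 0)
    lib <- stats::setNames(round(stats::runif(length(tissues), 18e6, 22e6)),
                           tissues)
    if (length(tissues) == 0) {
      counts <- matrix(0L, nrow = nrow(bundle$truth), ncol = 0,
                       dimnames = list(bundle$truth$gene_id, NULL))
      means <- counts
      return(list(counts = counts, library_sizes = lib, means = means))
    }
    means <- expression_means(cfg, bundle$truth, mrna_lengths)
    lens <- mrna_lengths[rownames(means)]
    expected <- means * (lens / 1000) %o% (lib / 1e6)
    noise <- matrix(exp(stats::rnorm(length(expected), 0, cfg$noise_sigma)),
                    nrow = nrow(expected))
    counts <- round(expected * noise)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- dimnames(means)
    list(counts = counts, library_sizes = lib, means = means)
  })
}

#' Generate a complete synthetic genome bundle
#'
#' Builds chromosome sequences, gene models, planted truth labels,
#' subfamily reference proteins, domain-profile seed alignments, and the
#' tissue count matrix, all deterministically from the config seed.
#'
#' @param config A [generator_config()].
#' @return A classed list (`synthetic_bundle`) with `chromosomes`
#'   (`DNAStringSet`), `gene_models`, `truth` (per-gene roles), `proteins`,
#'   `cds`, `references` (list: `seqs`, `subfamily`), `domain_profiles`
#'   (seed alignments), `counts`, `library_sizes`, `expression_means`,
#'   `config`.
#' @export
generate_genome <- function(config = generator_config()) {
  validate_generator_config(config)
  bundle <- withr::with_seed(config$seed, {
    founders <- make_founders(config)
    genes <- make_gene_roster(config, founders)
    genes <- assign_chromosomes(config, genes)
    chrom_orders <- layout_chromosomes(config, genes)
    # build chromosome sequences and models
    models <- list()
    chrom_seqs <- character(0)
    truth_rows <- list()
    for (chrom in sort(names(chrom_orders))) {
      pieces <- character(0)
      offset <- 0L
      rank <- 0L
      for (gi in chrom_orders[[chrom]]) {
        g <- genes[[gi]]
        spacer <- paste(sample(NTS, sample(100:200, 1), TRUE), collapse = "")
        pieces <- c(pieces, spacer)
        offset <- offset + nchar(spacer)
        gm <- build_gene_model(g$gene_id, chrom, g$cds, offset)
        region <- gene_region_sequence(gm)
        pieces <- c(pieces, region)
        offset <- offset + nchar(region)
        models[[g$gene_id]] <- gm
        rank <- rank + 1L
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          gene_id = g$gene_id, chromosome = chrom, rank = rank,
          start = min(gm$exons), end = max(gm$exons), strand = gm$strand,
          role = g$role, subfamily = g$subfamily %||% NA_character_,
          array = g$array %||% NA_integer_,
          block = g$block %||% NA_integer_,
          anchor = g$anchor %||% NA_integer_,
          side = g$side %||% NA_character_,
          target_ks = g$target_ks %||% NA_real_,
          stringsAsFactors = FALSE)
      }
      tail_spacer <- paste(sample(NTS, sample(100:200, 1), TRUE), collapse = "")
      pieces <- c(pieces, tail_spacer)
      seq <- paste(pieces, collapse = "")
      if (!is.null(config$chromosome_length)) {
        if (nchar(seq) > config$chromosome_length) {
          stop("genes do not fit chromosome length: ", chrom, " needs ",
               nchar(seq), " bp but chromosome_length is ",
               config$chromosome_length)
        }
        pad <- config$chromosome_length - nchar(seq)
        if (pad > 0) seq <- paste0(seq, paste(sample(NTS, pad, TRUE), collapse = ""))
      }
      chrom_seqs[chrom] <- seq
    }
    truth <- do.call(rbind, truth_rows)
    truth <- assign_expression_archetypes(config, truth)
    # reference proteins: founder + two mildly diverged copies per subfamily
    ref_seqs <- character(0)
    ref_sub <- character(0)
    for (sf in names(config$subfamily_plan)) {
      fo <- founders$founders[[sf]]
      for (k in 1:3) {
        cds <- if (k == 1) fo$cds else evolve_cds_impl(fo$cds, 0.25, 0.1)
        nm <- sprintf("Ref%s_%d", sf, k)
        ref_seqs[nm] <- translate_cds(cds)
        ref_sub[nm] <- sf
      }
    }
    # domain seed alignments: 8 diverged copies of each consensus (gapless)
    profiles <- lapply(founders$domains, function(dom) {
      Biostrings::AAStringSet(stats::setNames(
        vapply(1:8, function(i) mutate_protein(dom, 0.1), ""),
        paste0("seed", 1:8)))
    })
    proteins <- vapply(models, function(m) translate_cds(m$cds), "")
    cds_all <- vapply(models, function(m) m$cds, "")
    list(chromosomes = Biostrings::DNAStringSet(chrom_seqs),
         gene_models = models,
         truth = truth,
         proteins = Biostrings::AAStringSet(proteins),
         cds = Biostrings::DNAStringSet(cds_all),
         references = list(seqs = Biostrings::AAStringSet(ref_seqs),
                           subfamily = ref_sub),
         domain_profiles = profiles,
         config = config)
  })
  expr <- generate_expression(bundle)
  bundle$counts <- expr$counts
  bundle$library_sizes <- expr$library_sizes
  bundle$expression_means <- expr$means
  class(bundle) <- "synthetic_bundle"
  bundle
}

# build the genomic sequence of a gene region from its model (introns are
# drawn fresh from the surrounding RNG stream)
gene_region_sequence <- function(gm) {
  n <- nrow(gm$exons)
  lens <- gm$exons[, 2] - gm$exons[, 1]
  if (gm$strand == "+") {
    starts <- cumsum(c(1, lens[-n]))
    exon_seqs <- substring(gm$cds, starts, starts + lens - 1)
  } else {
    # exons stored in genomic order; transcription runs right to left
    tx_lens <- rev(lens)
    starts <- cumsum(c(1, tx_lens[-n]))
    tx_seqs <- substring(gm$cds, starts, starts + tx_lens - 1)
    exon_seqs <- rev(vapply(tx_seqs, rev_comp, ""))
  }
  pieces <- character(0)
  for (k in seq_len(n)) {
    if (k > 1) {
      gap <- gm$exons[k, 1] - gm$exons[k - 1, 2]
      pieces <- c(pieces, paste(sample(NTS, gap, TRUE), collapse = ""))
    }
    pieces <- c(pieces, exon_seqs[k])
  }
  paste(pieces, collapse = "")
}
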