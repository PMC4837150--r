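# Shared lookup tables: amino-acid alphabet, residue masses, pKa values,
# Kyte-Doolittle hydropathy, genetic-code derived codon tables.

AMINO_ACIDS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

# Average residue masses (Da), monoisotopic not used; peptide Mw = sum + water.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Side-chain and terminal pKa values (Lehninger-style set; pinned for
# reproducibility -- any standard set is acceptable but must stay fixed).
PKA_SET <- list(
  nterm = 9.69, cterm = 2.34,
  positive = c(H = 6.00, K = 10.53, R = 12.48),
  negative = c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07))

# Kyte & Doolittle (1982) hydropathy index.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# The 11 tissues profiled in the soybean RNA-seq resource the survey targets.
DEFAULT_TISSUES <- c("RT", "hypocotyl", "cotyledon", "callus",
                     "SAM6d", "SAM17d", "SAM38d", "AM", "IBM", "IAM", "OF")

# Subfamily catalog: 12 clades; AAAP group vs APC group.
SUBFAMILY_CATALOG <- c("AAP", "LHT", "ProT", "GAT", "AUX", "ANT",
                       "ATLa", "ATLb", "TTP", "CAT", "ACT", "PHS")
SUBFAMILY_GROUP <- c(
  AAP = "AAAP", LHT = "AAAP", ProT = "AAAP", GAT = "AAAP", AUX = "AAAP",
  ANT = "AAAP", ATLa = "AAAP", ATLb = "AAAP", TTP = "AAAP",
  CAT = "APC", ACT = "APC", PHS = "APC")

# Cache environment for codon tables and other lazily built objects.
.famsurvey_cache <- new.env(parent = emptyenv())

#' Standard-code codon tables used by the NG86 machinery
#'
#' Built once per session from [Biostrings::GENETIC_CODE]: the 61 sense
#' codons, their encoded amino acids, the set of stop codons, and per-codon
#' synonymous site fractions obtained by enumerating the three
#' single-nucleotide neighbours of every position (changes to stop codons
#' count as nonsynonymous, so synonymous + nonsynonymous sites are exactly 3
#' per codon).
#'
#' @return A list with elements `codons`, `aa` (named by codon), `stops`,
#'   and `syn_sites` (named numeric, synonymous site count per codon).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.famsurvey_cache$codon_tables)) {
    return(.famsurvey_cache$codon_tables)
  }
  gc_map <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_map)
  stops <- all_codons[gc_map == "*"]
  sense <- setdiff(all_codons, stops)
  aa <- gc_map[sense]
  nts <- c("A", "C", "G", "T")
  syn_sites <- vapply(sense, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    total <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, chars[pos])) {
        mut <- chars
        mut[pos] <- nt
        mut_cod <- paste(mut, collapse = "")
        if (gc_map[[mut_cod]] == gc_map[[cod]]) total <- total + 1 / 3
      }
    }
    total
  }, numeric(1))
  out <- list(codons = sense, aa = aa, stops = stops, syn_sites = syn_sites)
  .famsurvey_cache$codon_tables <- out
  out
}

split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

translate_cds <- function(cds, allow_stop = FALSE) {
  tab <- codon_tables()
  cods <- split_codons(cds)
  if (!allow_stop && any(cods %in% tab$stops)) {
    stop("CDS contains a stop codon")
  }
  aa <- Biostrings::GENETIC_CODE[cods]
  if (anyNA(aa)) stop("CDS contains ambiguous codons: ",
                      paste(unique(cods[is.na(aa)]), collapse = ", "))
  paste(aa[aa != "*"], collapse = "")
}

check_protein <- function(protein) {
  protein <- toupper(as.character(protein))
  if (!nzchar(protein)) stop("empty protein sequence")
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(chars), AMINO_ACIDS)
  if (length(bad)) {
    stop("non-amino-acid symbol(s) in sequence: ", paste(bad, collapse = ", "))
  }
  chars
}
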