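# Pairwise global protein alignment and p-distance matrices.
# Alignment is delegated to Biostrings::pairwiseAlignment (Needleman-Wunsch
# with affine gaps); a gap of length L costs gap_open + gap_extend * L.

#' Global pairwise protein alignment (BLOSUM62, affine gaps)
#'
#' @param a,b Protein sequences (character or `AAString`), non-empty.
#' @param substitution_matrix Name of a packaged scoring matrix or a numeric
#'   matrix; default `"BLOSUM62"`.
#' @param gap_open,gap_extend Affine gap parameters (default 10 and 0.5; a
#'   gap of length L costs `gap_open + gap_extend * L`).
#' @return List of class `alignment_result` with `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, and `identity`
#'   (matches / aligned columns).
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  check_protein(a); check_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  ncols <- nchar(aligned_a)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = Biostrings::score(aln),
                 identity = Biostrings::nmatch(aln) / ncols,
                 n_columns = ncols),
            class = "alignment_result")
}

#' All-vs-all identity and score matrices for a protein set
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param ... Passed to [Biostrings::pairwiseAlignment] scoring scheme
#'   (`substitution_matrix`, `gap_open`, `gap_extend` as in
#'   [global_align()]).
#' @return List with symmetric matrices `identity` and `score`
#'   (diagonal: identity 1, score `NA`).
#' @export
protein_identity_matrix <- function(proteins, substitution_matrix = "BLOSUM62",
                                    gap_open = 10, gap_extend = 0.5) {
  set <- if (methods::is(proteins, "AAStringSet")) proteins
         else Biostrings::AAStringSet(vapply(proteins, as.character, ""))
  n <- length(set)
  ids <- names(set)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteins must be uniquely named")
  identity <- matrix(0, n, n, dimnames = list(ids, ids))
  score <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(identity) <- 1
  if (n < 2) return(list(identity = identity, score = score))
  for (i in seq_len(n - 1)) {
    aln <- Biostrings::pairwiseAlignment(
      set[(i + 1):n], set[[i]],
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
    idv <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    identity[i, (i + 1):n] <- idv
    identity[(i + 1):n, i] <- idv
    sv <- Biostrings::score(aln)
    score[i, (i + 1):n] <- sv
    score[(i + 1):n, i] <- sv
  }
  list(identity = identity, score = score)
}

#' Pairwise p-distance matrix (1 - fractional identity)
#'
#' p-distances are not metric; triangle-inequality violations are permitted
#' by contract.
#'
#' @param proteins Named character vector or `AAStringSet` of >= 3
#'   sequences, or a precomputed identity matrix.
#' @param ... Passed to [protein_identity_matrix()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(proteins, ...) {
  idm <- if (is.matrix(proteins)) proteins
         else {
           if (length(proteins) < 3) stop("need >= 3 proteins")
           protein_identity_matrix(proteins, ...)$identity
         }
  d <- 1 - idm
  diag(d) <- 0
  d
}
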