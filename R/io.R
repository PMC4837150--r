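# Bundle serialisation: FASTA (60-column wrap), GFF3 (1-based inclusive,
# gene -> mRNA -> exon/CDS with Parent attributes), and TSV tables.
# Internal coordinates are 0-based half-open; the conversion to GFF3
# happens here and only here.

#' Write a synthetic bundle to a directory
#'
#' Emits `chromosomes.fasta`, `genes.gff3`, `cds.fasta`, `proteins.fasta`,
#' `references.fasta` (subfamily in the description), `profile_<id>.fasta`
#' seed alignments, `counts.tsv`, `library_sizes.tsv` and `truth.tsv`.
#' A subsequent [read_bundle()] reproduces the bundle.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  fp <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$chromosomes, fp("chromosomes.fasta"),
                              width = 60)
  Biostrings::writeXStringSet(bundle$cds, fp("cds.fasta"), width = 60)
  Biostrings::writeXStringSet(bundle$proteins, fp("proteins.fasta"),
                              width = 60)
  refs <- bundle$references$seqs
  names(refs) <- paste0(names(refs), " subfamily=",
                        bundle$references$subfamily[names(refs)])
  Biostrings::writeXStringSet(refs, fp("references.fasta"), width = 60)
  for (pid in names(bundle$domain_profiles)) {
    Biostrings::writeXStringSet(bundle$domain_profiles[[pid]],
                                fp(paste0("profile_", pid, ".fasta")),
                                width = 60)
  }
  export_gff3(bundle$gene_models, fp("genes.gff3"))
  write_counts_tsv(bundle$counts, fp("counts.tsv"))
  utils::write.table(
    data.frame(tissue = names(bundle$library_sizes),
               library_size = as.numeric(bundle$library_sizes)),
    fp("library_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

write_counts_tsv <- function(counts, path) {
  if (ncol(counts) == 0) {
    writeLines("gene_id", path)
    return(invisible(path))
  }
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

export_gff3 <- function(gene_models, path) {
  rows <- list()
  for (gm in gene_models) {
    ex <- gm$exons
    gstart <- min(ex[, 1]) + 1L  # to 1-based inclusive
    gend <- max(ex[, 2])
    gid <- gm$gene_id
    mid <- paste0(gid, ".mRNA")
    rows[[length(rows) + 1]] <- data.frame(
      chrom = gm$chromosome, start = gstart, end = gend, strand = gm$strand,
      type = c("gene", "mRNA"), ID = c(gid, mid),
      Parent = c(NA_character_, gid), phase = NA_integer_,
      stringsAsFactors = FALSE)
    # CDS phases follow transcription order
    ord <- if (gm$strand == "+") order(ex[, 1]) else order(-ex[, 1])
    lens <- ex[ord, 2] - ex[ord, 1]
    phase_tx <- (3 - cumsum(c(0, lens[-length(lens)])) %% 3) %% 3
    phase <- integer(nrow(ex))
    phase[ord] <- phase_tx
    for (k in seq_len(nrow(ex))) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = gm$chromosome, start = ex[k, 1] + 1L, end = ex[k, 2],
        strand = gm$strand, type = c("exon", "CDS"),
        ID = c(sprintf("%s.exon%d", gid, k), sprintf("%s.cds%d", gid, k)),
        Parent = mid, phase = c(NA_integer_, phase[k]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with the same core fields as a `synthetic_bundle`:
#'   `chromosomes`, `gene_models` (exons as 0-based half-open intervals),
#'   `proteins`, `cds`, `references`, `domain_profiles`, `counts`,
#'   `library_sizes`, `truth`, `tissues`.
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  for (f in c("chromosomes.fasta", "genes.gff3", "cds.fasta",
              "proteins.fasta", "counts.tsv", "truth.tsv")) {
    if (!file.exists(fp(f))) stop("bundle file missing: ", f)
  }
  chroms <- Biostrings::readDNAStringSet(fp("chromosomes.fasta"))
  cds <- Biostrings::readDNAStringSet(fp("cds.fasta"))
  proteins <- Biostrings::readAAStringSet(fp("proteins.fasta"))
  gff <- rtracklayer::import(fp("genes.gff3"))
  cds_rows <- gff[S4Vectors::mcols(gff)$type == "CDS"]
  parent <- as.character(S4Vectors::mcols(cds_rows)$Parent)
  gene_of <- sub("\\.mRNA$", "", parent)
  models <- list()
  for (gid in unique(gene_of)) {
    sel <- cds_rows[gene_of == gid]
    ex <- cbind(GenomicRanges::start(sel) - 1L, GenomicRanges::end(sel))
    ord <- order(ex[, 1])
    ex <- ex[ord, , drop = FALSE]
    colnames(ex) <- NULL
    models[[gid]] <- list(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(sel))[1],
      strand = as.character(GenomicRanges::strand(sel))[1],
      exons = ex,
      cds = as.character(cds[[gid]]),
      has_utr = FALSE)
  }
  truth <- utils::read.delim(fp("truth.tsv"), stringsAsFactors = FALSE)
  models <- models[truth$gene_id]
  counts_raw <- utils::read.delim(fp("counts.tsv"), check.names = FALSE,
                                  stringsAsFactors = FALSE)
  if (ncol(counts_raw) > 1) {
    counts <- as.matrix(counts_raw[, -1, drop = FALSE])
    rownames(counts) <- counts_raw$gene_id
    storage.mode(counts) <- "integer"
  } else {
    ids <- if (nrow(counts_raw)) counts_raw$gene_id else truth$gene_id
    counts <- matrix(0L, nrow = length(ids), ncol = 0,
                     dimnames = list(ids, NULL))
  }
  lib <- numeric(0)
  if (file.exists(fp("library_sizes.tsv"))) {
    ldf <- utils::read.delim(fp("library_sizes.tsv"), stringsAsFactors = FALSE)
    lib <- stats::setNames(ldf$library_size, ldf$tissue)
  }
  refs <- NULL
  if (file.exists(fp("references.fasta"))) {
    rf <- Biostrings::readAAStringSet(fp("references.fasta"))
    hdr <- names(rf)
    ids <- sub(" .*", "", hdr)
    sub_lab <- sub(".*subfamily=([^ ]+).*", "\\1", hdr)
    names(rf) <- ids
    refs <- list(seqs = rf, subfamily = stats::setNames(sub_lab, ids))
  }
  prof_files <- list.files(dir, pattern = "^profile_.*\\.fasta$")
  profiles <- stats::setNames(
    lapply(prof_files, function(f) Biostrings::readAAStringSet(fp(f))),
    sub("^profile_(.*)\\.fasta$", "\\1", prof_files))
  list(chromosomes = chroms, gene_models = models, proteins = proteins,
       cds = cds, references = refs, domain_profiles = profiles,
       counts = counts, library_sizes = lib, truth = truth,
       tissues = colnames(counts))
}
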