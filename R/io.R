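#' Read and write FASTA
#'
#' Thin wrappers over Biostrings that work in named character vectors, the
#' sequence currency of this package. `read_protein_fasta()` also accepts
#' `genomeID|proteinID` headers and returns a protein-record tibble.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector. `read_protein_fasta()`:
#'   tibble `genome_id`, `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) abort(paste0("malformed FASTA ", path, ": ",
                                                 conditionMessage(e))))
  setNames(as.character(x), names(x))
}

#' @param seqs Named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_protein_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  if (all(grepl("|", ids, fixed = TRUE))) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    tibble(genome_id = vapply(parts, `[`, character(1), 1),
           protein_id = vapply(parts, `[`, character(1), 2),
           sequence = unname(seqs))
  } else {
    stem <- sub("\\.[^.]*$", "", basename(path))
    tibble(genome_id = stem, protein_id = ids, sequence = unname(seqs))
  }
}

#' Read and write paired FASTQ (Phred+33)
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files.
#' @param sample Sample label attached to every pair.
#' @return Tibble `sample`, `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_paired_fastq <- function(r1, r2, sample = "sample1") {
  rd <- function(p) {
    x <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
        p, quality.scoring = "phred")),
      error = function(e) abort(paste0("malformed FASTQ ", p, ": ",
                                       conditionMessage(e))))
    list(id = names(x), seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$seq) != length(b$seq)) abort("R1/R2 record counts differ")
  tibble(sample = sample, id = unname(a$id),
         seq1 = unname(a$seq), qual1 = unname(a$qual),
         seq2 = unname(b$seq), qual2 = unname(b$qual))
}

#' @param reads Tibble as returned by [simulate_reads()].
#' @param dir Output directory; one `<sample>_R1.fastq` / `_R2.fastq` pair
#'   per sample.
#' @rdname read_paired_fastq
#' @export
write_paired_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(reads$sample)) {
    rs <- reads[reads$sample == s, ]
    for (side in 1:2) {
      sq <- Biostrings::DNAStringSet(rs[[paste0("seq", side)]])
      names(sq) <- rs$id
      q <- Biostrings::PhredQuality(rs[[paste0("qual", side)]])
      suppressWarnings({
        x <- Biostrings::QualityScaledDNAStringSet(sq, q)
        Biostrings::writeQualityScaledXStringSet(
          x, file.path(dir, sprintf("%s_R%d.fastq", s, side)))
      })
    }
  }
  invisible(dir)
}

#' Read and write labeled square distance matrices as TSV
#'
#' @param d Labeled symmetric matrix.
#' @param path TSV path (row labels in the first column).
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(label = rownames(d), as.data.frame(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write Newick trees
#'
#' @param tree `ape::phylo`.
#' @param path Newick file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read and write sample tables (TSV, sample label first)
#'
#' @param x Data frame with a `sample` column.
#' @param path TSV path.
#' @export
write_sample_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_tsv
#' @export
read_sample_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}
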