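# Small fixture builders shared across test files.

toy_proteins <- function() {
  tibble::tribble(
    ~genome_id, ~protein_id, ~sequence,
    "g1", "p1", strrep("ACDEFGHIKL", 10),
    "g1", "p2", strrep("MNPQRSTVWY", 8),
    "g2", "p3", strrep("ACDEFGHIKL", 10),
    "g2", "p4", strrep("WYACDQRSTV", 9)
  )
}

# an OTU tibble from a plain count matrix
otu_tbl <- function(m, samples = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% paste0("otu", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample = samples),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mutate a protein at exactly k positions (deterministic given the RNG state)
mutate_protein <- function(seq, k) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
  paste(s, collapse = "")
}

random_protein_str <- function(len) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# error-free read pair covering an amplicon with the given read length
perfect_pair <- function(amp, read_len = 300, q = "G") {
  L <- nchar(amp)
  r1 <- substr(amp, 1, read_len)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, L - read_len + 1, L))))
  tibble::tibble(sample = "s1", id = "p1",
                 seq1 = r1, qual1 = strrep(q, nchar(r1)),
                 seq2 = r2, qual2 = strrep(q, nchar(r2)))
}
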