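#' Pairwise amino-acid identity from a global alignment
#'
#' Aligns two protein sequences globally (BLOSUM62, affine gap penalties:
#' open 10, extend 1) and returns the fraction of identical aligned residue
#' pairs over all alignment columns excluding terminal-gap columns. This is the
#' identity definition used everywhere in the package: protein clustering, the
#' amplicon OTU threshold, reference screens and clade assignment.
#'
#' @param a,b Protein sequence strings (standard amino acids plus `X`).
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAAAAAAAA", "AAAAAWWWWW") # 0.5
#' @export
pairwise_identity <- function(a, b) {
  pairwise_identity_many(b, a)[[1]]
}

#' Identities of many sequences against one subject
#'
#' Vectorised form of [pairwise_identity()]: one global alignment per query.
#'
#' @param queries Character vector of protein sequences.
#' @param subject Single protein sequence.
#' @return Numeric vector of identities, one per query.
#' @export
pairwise_identity_many <- function(queries, subject) {
  identity_detail(queries, subject)$identity
}

# identity plus the number of alignment columns it was computed over
identity_detail <- function(queries, subject) {
  check_protein_alphabet(c(queries, subject))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
  res <- vapply(seq_along(pa), function(i) {
    p <- pa[[i]]; s <- sa[[i]]
    both <- p != "-" & s != "-"
    # terminal-gap columns: outside the first/last column where both rows
    # carry a residue
    idx <- which(both)
    if (length(idx) == 0) return(c(0, 0))
    cols <- idx[1]:idx[length(idx)]
    c(sum(p[cols] == s[cols] & both[cols]) / length(cols), length(cols))
  }, numeric(2))
  list(identity = res[1, ], cols = res[2, ])
}

check_protein_alphabet <- function(seqs, ids = NULL) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seqs)
  if (any(bad)) {
    label <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
             else paste(which(bad), collapse = ", ")
    abort(paste0("invalid residue characters in sequence(s): ", label))
  }
  invisible(TRUE)
}

#' Maximum pairwise identity in a sequence panel
#'
#' Scans all pairs and reports the largest [pairwise_identity()]. Used to
#' check that a chosen OTU clustering threshold sits above the most similar
#' pair of reference amplicons.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @return A single fraction.
#' @export
max_pairwise_identity <- function(seqs) {
  if (length(seqs) < 2) abort("need at least 2 sequences")
  best <- 0
  for (i in seq_len(length(seqs) - 1L)) {
    ids <- pairwise_identity_many(seqs[(i + 1L):length(seqs)], seqs[[i]])
    best <- max(best, ids)
  }
  best
}

# Greedy centroid clustering shared by protein-family and OTU clustering.
#
# Candidates are visited in the supplied order; each joins the FIRST existing
# centroid whose identity is >= threshold, else founds a new cluster. A
# bounded-shift ungapped identity is used as a certificate on either side of
# the threshold; only identities inside `band` of the threshold fall back to
# the exact global alignment. `exact = TRUE` disables the fast path.
cluster_greedy_core <- function(seqs, threshold, band = 0.05, exact = FALSE) {
  n <- length(seqs)
  if (exact) {
    cluster <- integer(n)
    centroid_idx <- integer(0)
    for (i in seq_len(n)) {
      assigned <- 0L
      for (ci in seq_along(centroid_idx)) {
        if (pairwise_identity(seqs[[i]], seqs[[centroid_idx[ci]]]) >= threshold) {
          assigned <- ci; break
        }
      }
      if (assigned == 0L) {
        centroid_idx <- c(centroid_idx, i)
        cluster[i] <- length(centroid_idx)
      } else {
        cluster[i] <- assigned
      }
    }
    return(list(cluster = cluster, centroid_idx = centroid_idx))
  }
  res <- .greedy_cluster_cpp(unname(seqs), threshold, band)
  cluster <- res$cluster
  centroid_idx <- res$centroid_idx
  # founders whose closest earlier centroid fell just under the threshold on
  # the ungapped screen: re-examine with the exact alignment and merge the
  # whole cluster if the exact identity reaches the threshold
  pending <- which(res$band_centroid[centroid_idx] > 0)
  if (length(pending) > 0) {
    drop <- logical(length(centroid_idx))
    for (ci in pending) {
      target <- res$band_centroid[centroid_idx[ci]]
      if (drop[target]) next
      idy <- pairwise_identity(seqs[[centroid_idx[ci]]], seqs[[centroid_idx[target]]])
      if (idy >= threshold) {
        cluster[cluster == ci] <- target
        drop[ci] <- TRUE
      }
    }
    if (any(drop)) {
      keep <- which(!drop)
      remap <- integer(length(centroid_idx))
      remap[keep] <- seq_along(keep)
      cluster <- remap[cluster]
      centroid_idx <- centroid_idx[keep]
    }
  }
  list(cluster = cluster, centroid_idx = centroid_idx)
}
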