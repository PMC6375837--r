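#' Pairwise distance matrix from a protein alignment
#'
#' For each row pair, p = mismatches / shared ungapped columns (columns where
#' both rows carry a residue). With `correction = "poisson"` the distance is
#' `-ln(1 - p)`, the standard correction for multiple substitutions; saturated
#' pairs (p = 1) are set to `cap`.
#'
#' @param aln Named character vector of equal-length aligned amino-acid rows
#'   (gap character `-`), or an `Biostrings::AAStringSet`.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @param cap Distance used where the correction diverges (default 10).
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
marker_distance <- function(aln, correction = c("none", "poisson"), cap = 10) {
  correction <- match.arg(correction)
  if (methods::is(aln, "AAStringSet")) aln <- as.character(aln)
  labs <- names(aln)
  if (is.null(labs) || anyDuplicated(labs)) abort("alignment rows must have unique names")
  if (length(aln) < 2) abort("need at least 2 rows")
  if (length(unique(nchar(aln))) != 1) abort("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(aln, ""))
  res <- m != "-"
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- res[i, ] & res[j, ]
    ns <- sum(shared)
    if (ns == 0) {
      abort(paste0("rows share no ungapped columns: ", labs[i], ", ", labs[j]))
    }
    p <- sum(m[i, shared] != m[j, shared]) / ns
    dd <- if (correction == "none") p else if (p >= 1) cap else -log(1 - p)
    d[i, j] <- d[j, i] <- dd
  }
  attr(d, "correction") <- correction
  d
}

#' Mantel permutation test of distance-matrix congruence
#'
#' Pearson correlation of the upper triangles of two distance matrices over
#' the same labels, with a one-tailed permutation null built by jointly
#' permuting the rows and columns of the second matrix. The p-value uses the
#' +1 correction: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 Labeled symmetric distance matrices over identical label sets
#'   (order reconciled by label).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `mantel_result` object (fields `r`, `p`, `n_perm`, `seed`, `n`);
#'   see [tidy.mantel_result()].
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (!setequal(l1, l2)) {
    abort(paste0("label sets differ: only in d1 {",
                 paste(setdiff(l1, l2), collapse = ", "), "}; only in d2 {",
                 paste(setdiff(l2, l1), collapse = ", "), "}"))
  }
  n <- nrow(d1)
  if (n < 4) abort("need at least 4 labels")
  if (n_perm < 1) abort("n_perm must be >= 1")
  d2 <- d2[l1, l1]
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r_obs <- cor(v1, d2[ut])
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(v1, d2[p, p][ut]) >= r_obs - 1e-12) ge <- ge + 1L
  }
  structure(list(r = r_obs, p = (ge + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (n = %d): r = %.4f, p = %.4g (%d permutations)\n",
              x$n, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Locate and extract an amplicon region with IUPAC primers
#'
#' Finds the forward primer on the given strand and the reverse primer's
#' reverse complement downstream of it, each allowing up to `max_mismatches`
#' under IUPAC ambiguity matching, and returns the inter-primer insert
#' (primers excluded). Coordinates are 0-based half-open on the input
#' sequence. Sequences where a primer is absent or matches more than once get
#' status `"not found"` / `"ambiguous"` and an `NA` insert.
#'
#' @param nuc_seqs Named character vector of nucleotide sequences.
#' @param forward,reverse IUPAC primer patterns (reverse given as the primer
#'   itself, in its own 5'->3' orientation).
#' @param max_mismatches Allowed mismatches per primer site (default 0).
#' @return Tibble with `id`, `status` (`"ok"`, `"not found"`, `"ambiguous"`),
#'   `start`, `end` (0-based half-open insert coordinates) and `insert`.
#' @export
extract_amplicon_region <- function(nuc_seqs, forward, reverse, max_mismatches = 0) {
  if (nchar(forward) == 0 || nchar(reverse) == 0) abort("primers must be non-empty")
  if (grepl("[^ACGTRYSWKMBDHVN]", toupper(forward)) ||
      grepl("[^ACGTRYSWKMBDHVN]", toupper(reverse))) {
    abort("primers must use IUPAC nucleotide codes")
  }
  fwd <- Biostrings::DNAString(toupper(forward))
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse)))
  purrr::map_dfr(seq_along(nuc_seqs), function(i) {
    s <- Biostrings::DNAString(nuc_seqs[[i]])
    id <- names(nuc_seqs)[i] %||% as.character(i)
    fhits <- Biostrings::matchPattern(fwd, s, max.mismatch = max_mismatches,
                                      fixed = "subject")
    if (length(fhits) == 0) {
      return(tibble(id = id, status = "not found", start = NA_integer_,
                    end = NA_integer_, insert = NA_character_))
    }
    if (length(fhits) > 1) {
      return(tibble(id = id, status = "ambiguous", start = NA_integer_,
                    end = NA_integer_, insert = NA_character_))
    }
    rhits <- Biostrings::matchPattern(rev_rc, s, max.mismatch = max_mismatches,
                                      fixed = "subject")
    rhits <- rhits[BiocGenerics::start(rhits) > BiocGenerics::end(fhits)]
    if (length(rhits) == 0) {
      return(tibble(id = id, status = "not found", start = NA_integer_,
                    end = NA_integer_, insert = NA_character_))
    }
    if (length(rhits) > 1) {
      return(tibble(id = id, status = "ambiguous", start = NA_integer_,
                    end = NA_integer_, insert = NA_character_))
    }
    s0 <- BiocGenerics::end(fhits)          # 0-based start of insert
    e0 <- BiocGenerics::start(rhits) - 1L   # 0-based half-open end
    tibble(id = id, status = "ok", start = as.integer(s0), end = as.integer(e0),
           insert = as.character(Biostrings::subseq(s, s0 + 1L, e0)))
  })
}

#' Calibrate an amplicon clustering threshold against full-length distances
#'
#' For each identity level in `identity_grid`, amplicon sequences are greedily
#' clustered (the same rule as [cluster_proteins()]) and the spread of
#' full-length pairwise distances inside clusters is measured: the population
#' variance of within-cluster distance pairs, pooled across clusters weighted
#' by pair count. The recommended threshold is the smallest level whose
#' statistic falls at or below `tolerance`; if none does, the highest level is
#' returned with `tolerance_met = FALSE`.
#'
#' @param full_dist Labeled distance matrix of full-length sequences.
#' @param amplicon_seqs Named character vector of amplicon protein sequences;
#'   names must be a subset of `full_dist` labels.
#' @param identity_grid Strictly increasing identity levels
#'   (default 0.90 ... 0.99).
#' @param tolerance Acceptable pooled within-cluster variance (default 1e-3).
#' @return A `calibration_curve` object: tibble with `identity_level`,
#'   `within_cluster_variance`, `n_clusters`; attributes
#'   `recommended_threshold` and `tolerance_met`.
#' @export
threshold_calibration <- function(full_dist, amplicon_seqs,
                                  identity_grid = seq(0.90, 0.99, by = 0.01),
                                  tolerance = 1e-3) {
  if (length(identity_grid) == 0) abort("identity_grid must be non-empty")
  if (is.unsorted(identity_grid, strictly = TRUE)) {
    abort("identity_grid must be strictly increasing")
  }
  labs <- names(amplicon_seqs)
  fd <- as.matrix(full_dist)
  if (!all(labs %in% rownames(fd))) {
    abort("amplicon labels must be a subset of full_dist labels")
  }
  rows <- purrr::map_dfr(identity_grid, function(level) {
    ord <- order(-nchar(amplicon_seqs), labs)
    res <- cluster_greedy_core(amplicon_seqs[ord], level)
    cl <- split(labs[ord], res$cluster)
    wv <- 0; npairs <- 0
    for (members in cl) {
      if (length(members) < 2) next
      dv <- fd[members, members][upper.tri(matrix(0, length(members), length(members)))]
      np <- length(dv)
      v <- sum((dv - mean(dv))^2) / np  # population variance
      wv <- wv + np * v
      npairs <- npairs + np
    }
    tibble(identity_level = level,
           within_cluster_variance = if (npairs > 0) wv / npairs else 0,
           n_clusters = length(cl))
  })
  if (is.unsorted(rows$n_clusters)) {
    warn("n_clusters is not non-decreasing across the identity grid (greedy clustering is not formally nested)")
  }
  ok <- rows$identity_level[rows$within_cluster_variance <= tolerance]
  met <- length(ok) > 0
  structure(rows,
            class = c("calibration_curve", class(rows)),
            recommended_threshold = if (met) min(ok) else max(rows$identity_level),
            tolerance_met = met,
            tolerance = tolerance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
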