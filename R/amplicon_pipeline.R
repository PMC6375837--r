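#' Quality-trim reads from both ends
#'
#' Removes all terminal bases with Phred quality below `q_threshold` from both
#' ends of each read (interior low-quality bases are kept) and discards reads
#' whose remaining length is below `min_len`.
#'
#' @param reads Tibble with columns `sequence` and `quality` (Phred+33
#'   strings of equal length per read); other columns pass through.
#' @param q_threshold Minimum terminal base quality (default 30).
#' @param min_len Minimum retained length (default 36).
#' @return The kept rows with trimmed `sequence`/`quality`; attribute
#'   `n_discarded` counts dropped reads.
#' @export
quality_trim <- function(reads, q_threshold = 30, min_len = 36) {
  stopifnot(is.data.frame(reads), all(c("sequence", "quality") %in% names(reads)))
  res <- .trim_batch_cpp(reads$sequence, reads$quality, q_threshold, min_len)
  out <- reads[res$keep, , drop = FALSE]
  out$sequence <- res$sequence[res$keep]
  out$quality <- res$quality[res$keep]
  attr(out, "n_discarded") <- sum(!res$keep)
  out
}

#' Merge read pairs by their best ungapped overlap
#'
#' The reverse read is reverse-complemented and the best ungapped overlap of
#' at least `min_overlap` bases maximising matches is found; pairs whose best
#' overlap still mismatches at more than `max_mismatch_frac` of its positions
#' are discarded. In the overlap the higher-quality base wins and the
#' consensus quality is the maximum of the two.
#'
#' @param pairs Tibble with columns `seq1`, `qual1`, `seq2`, `qual2`
#'   (`seq2` in sequencing orientation); other columns pass through.
#' @param min_overlap Minimum overlap length (default 20).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return Tibble of merged pairs with `sequence`, `quality`, `overlap`;
#'   attribute `n_discarded`.
#' @export
merge_pairs <- function(pairs, min_overlap = 20, max_mismatch_frac = 0.1) {
  stopifnot(is.data.frame(pairs),
            all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  res <- .merge_batch_cpp(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                          as.integer(min_overlap), max_mismatch_frac)
  keep <- res$merged
  out <- pairs[keep, setdiff(names(pairs), c("seq1", "qual1", "seq2", "qual2")),
               drop = FALSE]
  out$sequence <- res$sequence[keep]
  out$quality <- res$quality[keep]
  out$overlap <- res$overlap[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Translate merged amplicons and keep the longest open reading frame
#'
#' Each nucleotide sequence is translated in all six frames; the frame holding
#' the longest stop-free run wins (ties go to the earlier frame: the three
#' forward frames, then the three reverse-complement frames) and that run is
#' emitted. Runs shorter than `min_aa` are discarded. Ambiguous codons
#' translate to `X`.
#'
#' @param nuc_seqs Character vector of nucleotide sequences over `ACGTN`.
#' @param min_aa Minimum protein length (default 140).
#' @return Character vector of proteins, `NA` where discarded.
#' @export
translate_filter <- function(nuc_seqs, min_aa = 140) {
  if (length(nuc_seqs) == 0) return(character(0))
  dna <- Biostrings::DNAStringSet(nuc_seqs)
  L <- Biostrings::width(dna)
  frame_of <- function(x, f, rc = FALSE) {
    if (rc) x <- Biostrings::reverseComplement(x)
    w <- pmax(((Biostrings::width(x) - f) %/% 3L) * 3L, 0L)
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(x, start = f + 1L, width = w), if.fuzzy.codon = "X")))
  }
  longest_run <- function(aa) {
    runs <- strsplit(aa, "*", fixed = TRUE)
    vapply(runs, function(r) {
      if (length(r) == 0) "" else r[[which.max(nchar(r))]]
    }, character(1))
  }
  # frame 1 first: a stop-free frame-1 translation attains the maximum
  # possible run length, so no other frame can beat it (ties prefer frame 1)
  f1 <- frame_of(dna, 0)
  best <- longest_run(f1)
  best_len <- nchar(best)
  undecided <- which(best_len < nchar(f1))
  if (length(undecided) > 0) {
    sub <- dna[undecided]
    for (fr in list(c(1, FALSE), c(2, FALSE), c(0, TRUE), c(1, TRUE), c(2, TRUE))) {
      cand <- longest_run(frame_of(sub, fr[1], rc = as.logical(fr[2])))
      better <- nchar(cand) > best_len[undecided]
      best[undecided[better]] <- cand[better]
      best_len[undecided] <- pmax(best_len[undecided], nchar(cand))
    }
  }
  best[best_len < min_aa] <- NA_character_
  best
}

#' Pool and dereplicate translated reads
#'
#' Groups identical protein strings across samples, keeping per-sample counts.
#' Output is sorted by total abundance (descending), ties broken
#' lexicographically by sequence — the order greedy OTU clustering consumes.
#'
#' @param proteins Tibble with columns `sample` and `sequence`.
#' @return A `unique_seqs` object: tibble with `sequence` and `total`,
#'   with the per-sample count matrix in attribute `counts` (rows parallel to
#'   the tibble, columns = samples).
#' @export
dereplicate <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("sample", "sequence") %in% names(proteins)))
  samples <- unique(proteins$sample)
  tab <- proteins |>
    dplyr::count(.data$sample, .data$sequence, name = "count")
  totals <- tab |>
    group_by(.data$sequence) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$total), .data$sequence)
  counts <- matrix(0L, nrow = nrow(totals), ncol = length(samples),
                   dimnames = list(NULL, samples))
  counts[cbind(match(tab$sequence, totals$sequence),
               match(tab$sample, samples))] <- as.integer(tab$count)
  out <- totals
  attr(out, "counts") <- counts
  class(out) <- c("unique_seqs", class(out))
  out
}

#' Greedy abundance-sorted OTU clustering
#'
#' Unique sequences are visited in decreasing abundance and each joins the
#' first existing centroid at or above `identity` ([pairwise_identity()]
#' definition), else founds a new OTU. Clusters with total abundance 1
#' (singletons) are removed.
#'
#' @param uniques A `unique_seqs` object from [dereplicate()].
#' @param identity Clustering threshold (default 0.97).
#' @return An `otu_set` object: tibble with `otu_id`, `centroid`, `size`,
#'   per-sample count matrix in attribute `counts`.
#' @export
greedy_otu_cluster <- function(uniques, identity = 0.97) {
  counts <- attr(uniques, "counts")
  ord <- order(-uniques$total, uniques$sequence)
  seqs <- uniques$sequence[ord]
  counts <- counts[ord, , drop = FALSE]
  res <- cluster_greedy_core(seqs, identity)
  k <- length(res$centroid_idx)
  ccounts <- rowsum(counts, group = res$cluster, reorder = TRUE)
  sizes <- rowSums(ccounts)
  keep <- which(sizes > 1)  # singleton clusters removed
  ord2 <- keep[order(-sizes[keep])]
  otus <- tibble(
    otu_id = sprintf("OTU%04d", seq_along(ord2)),
    centroid = seqs[res$centroid_idx[ord2]],
    size = as.integer(sizes[ord2])
  )
  cm <- ccounts[ord2, , drop = FALSE]
  rownames(cm) <- otus$otu_id
  attr(otus, "counts") <- cm
  attr(otus, "identity") <- identity
  attr(otus, "n_singletons_removed") <- k - length(keep)
  class(otus) <- c("otu_set", class(otus))
  otus
}

#' Flag likely chimeric (bimeric) OTUs
#'
#' An OTU is flagged when its centroid looks like a two-parent splice: some
#' left/right split matches two distinct more abundant centroids (each at
#' least twice the candidate's size) at per-segment identity >= 0.99, while no
#' single parent explains it (best whole-sequence parent identity <= 0.95).
#' Only equal-length parents are considered for the split scan.
#'
#' @param otus An `otu_set` from [greedy_otu_cluster()].
#' @param seg_identity Per-segment identity needed to call a parent
#'   (default 0.99).
#' @param max_single_identity Best single-parent identity above which a
#'   candidate is never flagged (default 0.95).
#' @return The `otu_set` with a logical `chimera_flag` column.
#' @export
chimera_flag <- function(otus, seg_identity = 0.99, max_single_identity = 0.95) {
  n <- nrow(otus)
  flag <- rep(FALSE, n)
  ord <- order(-otus$size)
  for (pos in seq_along(ord)) {
    k <- ord[pos]
    parents <- which(otus$size >= 2 * otus$size[k] & seq_len(n) != k)
    if (length(parents) < 2) next
    # ungapped screen first; exact alignment only near the decision boundary
    u <- vapply(otus$centroid[parents],
                function(p) .ungapped_identity_cpp(otus$centroid[k], p),
                numeric(1), USE.NAMES = FALSE)
    single <- max(u)
    if (single <= max_single_identity + 0.02 && single >= max_single_identity - 0.05) {
      single <- max(pairwise_identity_many(otus$centroid[parents], otus$centroid[k]))
    }
    if (single > max_single_identity) next
    cand <- otus$centroid[k]
    L <- nchar(cand)
    eq <- parents[nchar(otus$centroid[parents]) == L]
    if (length(eq) < 2) next
    mv <- lapply(otus$centroid[eq], function(p) .match_positions_cpp(cand, p))
    pre <- lapply(mv, cumsum)
    for (a in seq_along(eq)) for (b in seq_along(eq)) {
      if (a == b) next
      s <- seq_len(L - 1)
      left_id <- pre[[a]][s] / s
      right_id <- (pre[[b]][L] - pre[[b]][s]) / (L - s)
      if (any(left_id >= seg_identity & right_id >= seg_identity)) {
        flag[k] <- TRUE
      }
      if (flag[k]) break
    }
  }
  otus$chimera_flag <- flag
  otus
}

#' Size and reference screens for OTUs
#'
#' Keeps OTUs that (a) are not chimera-flagged, (b) have at least `min_size`
#' reads, and (c) resemble a supplied reference protein panel: best
#' global-alignment identity to any reference at or above
#' `min_screen_identity` over at least `min_screen_cols` aligned columns (a
#' local stand-in for a BLAST screen against known cyanophage sequences).
#'
#' @param otus An `otu_set` (with or without `chimera_flag`).
#' @param refs Named character vector of reference proteins.
#' @param min_size Minimum OTU read count (default 500).
#' @param min_screen_identity Minimum identity to any reference (default 0.5).
#' @param min_screen_cols Minimum aligned columns for the screen (default 100).
#' @return The retained `otu_set` rows with a `screen_pass` column; attribute
#'   `counts` subset accordingly.
#' @export
filter_otus <- function(otus, refs, min_size = 500,
                        min_screen_identity = 0.5, min_screen_cols = 100) {
  if (length(refs) == 0) abort("reference panel must be non-empty")
  pass <- vapply(otus$centroid, function(s) {
    # ungapped certificate: identity over min(length) columns; exact alignment
    # only when the screen decision is borderline
    u <- vapply(refs, function(r) .ungapped_identity_cpp(s, r), numeric(1))
    ulen <- pmin(nchar(s), nchar(refs))
    if (any(u >= min_screen_identity + 0.05 & ulen >= min_screen_cols)) return(TRUE)
    if (all(u < min_screen_identity - 0.05)) return(FALSE)
    det <- identity_detail(refs, s)
    any(det$identity >= min_screen_identity & det$cols >= min_screen_cols)
  }, logical(1), USE.NAMES = FALSE)
  otus$screen_pass <- pass
  chim <- if ("chimera_flag" %in% names(otus)) otus$chimera_flag else FALSE
  keep <- which(otus$size >= min_size & pass & !chim)
  out <- otus[keep, , drop = FALSE]
  attr(out, "counts") <- attr(otus, "counts")[keep, , drop = FALSE]
  attr(out, "identity") <- attr(otus, "identity")
  out
}

#' Assign OTUs to reference clades by nearest reference
#'
#' Each OTU receives the clade of its highest-identity reference amplicon
#' (ties broken by the lexicographically first reference label and logged via
#' a `tie` column); OTUs below `novelty_floor` identity to every reference are
#' labeled `"novel"`.
#'
#' @param otus An `otu_set`.
#' @param ref_amplicons Named character vector of reference amplicon proteins.
#' @param clade_map Data frame with columns `reference` and `clade` covering
#'   every reference label.
#' @param novelty_floor Identity below which an OTU is called novel
#'   (default 0.75).
#' @return The `otu_set` with `clade`, `best_reference`, `best_identity`,
#'   `tie` columns.
#' @export
assign_clades <- function(otus, ref_amplicons, clade_map, novelty_floor = 0.75) {
  stopifnot(is.data.frame(clade_map), all(c("reference", "clade") %in% names(clade_map)))
  missing <- setdiff(names(ref_amplicons), clade_map$reference)
  if (length(missing) > 0) {
    abort(paste0("reference(s) missing from clade map: ", paste(missing, collapse = ", ")))
  }
  rlab <- names(ref_amplicons)
  ord <- order(rlab)
  refs <- ref_amplicons[ord]; rlab <- rlab[ord]
  res <- purrr::map_dfr(otus$centroid, function(s) {
    # rank references by the ungapped screen, align only the contenders
    u <- vapply(refs, function(r) .ungapped_identity_cpp(s, r), numeric(1))
    cand <- which(u >= max(u) - 0.05)
    ids <- u
    ids[cand] <- pairwise_identity_many(refs[cand], s)
    best <- max(ids)
    hits <- which(ids >= best - 1e-12)
    tibble(best_reference = rlab[hits[1]], best_identity = best,
           tie = length(hits) > 1)
  })
  otus$best_reference <- res$best_reference
  otus$best_identity <- res$best_identity
  otus$tie <- res$tie
  otus$clade <- ifelse(
    res$best_identity < novelty_floor, "novel",
    clade_map$clade[match(res$best_reference, clade_map$reference)])
  if (any(res$tie)) {
    warn(paste0("clade ties broken lexicographically for: ",
                paste(otus$otu_id[res$tie], collapse = ", ")))
  }
  otus
}

#' Samples x OTUs count table
#'
#' Materialises the per-sample counts of a filtered `otu_set` as a tidy table
#' with one row per sample; column sums equal OTU sizes by construction.
#'
#' @param otus An `otu_set` whose `counts` attribute holds per-sample counts.
#' @param samples Optional sample ordering (default: columns of the count
#'   matrix). Duplicate labels are an error.
#' @return Tibble with a `sample` column and one integer column per OTU;
#'   per-OTU clade annotations (if present) in attribute `clades`.
#' @export
build_otu_table <- function(otus, samples = NULL) {
  cm <- attr(otus, "counts")
  if (is.null(samples)) samples <- colnames(cm)
  if (anyDuplicated(samples)) abort("duplicate sample labels")
  cm <- cm[, samples, drop = FALSE]
  out <- as_tibble(t(cm))
  out <- dplyr::bind_cols(tibble(sample = samples), out)
  if ("clade" %in% names(otus)) {
    attr(out, "clades") <- tibble(otu_id = otus$otu_id, clade = otus$clade)
  }
  out
}

#' Run the full amplicon-to-OTU-table pipeline
#'
#' Chains quality trimming, pair merging, translation with ORF selection,
#' pooled dereplication, greedy OTU clustering with singleton removal, the
#' chimera and reference screens, clade assignment and table construction. A
#' per-stage read ledger is kept: every input pair ends up in exactly one of
#' the discard bins or as a member of a dereplicated unique sequence.
#'
#' @param reads Tibble with columns `sample`, `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (one row per read pair), as produced by [simulate_reads()] or
#'   [read_paired_fastq()].
#' @param refs Named character vector of reference amplicon proteins (screen
#'   and clade assignment panel).
#' @param clade_map Data frame `reference` / `clade`; defaults to one clade
#'   per reference named after it.
#' @param identity OTU clustering threshold (default 0.97).
#' @param min_size Minimum OTU size (default 500).
#' @param q_threshold,min_len,min_overlap,max_mismatch_frac,min_aa,novelty_floor
#'   Stage parameters; see the individual stage functions.
#' @param min_screen_identity,min_screen_cols Reference screen parameters.
#' @return List with `otu_table`, `otus`, `stage_counts` (tibble of the read
#'   ledger) and `uniques`.
#' @export
run_amplicon_pipeline <- function(reads, refs, clade_map = NULL,
                                  identity = 0.97, min_size = 500,
                                  q_threshold = 30, min_len = 36,
                                  min_overlap = 20, max_mismatch_frac = 0.1,
                                  min_aa = 140, novelty_floor = 0.75,
                                  min_screen_identity = 0.5,
                                  min_screen_cols = 100) {
  stopifnot(is.data.frame(reads),
            all(c("sample", "seq1", "qual1", "seq2", "qual2") %in% names(reads)))
  n_in <- nrow(reads)
  t1 <- .trim_batch_cpp(reads$seq1, reads$qual1, q_threshold, min_len)
  t2 <- .trim_batch_cpp(reads$seq2, reads$qual2, q_threshold, min_len)
  keep <- t1$keep & t2$keep
  trimmed <- reads[keep, , drop = FALSE]
  trimmed$seq1 <- t1$sequence[keep]; trimmed$qual1 <- t1$quality[keep]
  trimmed$seq2 <- t2$sequence[keep]; trimmed$qual2 <- t2$quality[keep]
  n_trim_drop <- n_in - nrow(trimmed)

  merged <- merge_pairs(trimmed, min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  n_merge_drop <- attr(merged, "n_discarded")

  prot <- translate_filter(merged$sequence, min_aa = min_aa)
  ok <- !is.na(prot)
  n_translate_drop <- sum(!ok)
  proteins <- tibble(sample = merged$sample[ok], sequence = prot[ok])

  uniques <- dereplicate(proteins)
  stage_counts <- tibble(
    stage = c("input_pairs", "discarded_at_trim", "discarded_at_merge",
              "discarded_at_translate", "member_of_unique"),
    n = c(n_in, n_trim_drop, n_merge_drop, n_translate_drop, nrow(proteins))
  )

  otus <- greedy_otu_cluster(uniques, identity = identity)
  otus <- chimera_flag(otus)
  otus <- filter_otus(otus, refs, min_size = min_size,
                      min_screen_identity = min_screen_identity,
                      min_screen_cols = min_screen_cols)
  if (is.null(clade_map)) {
    clade_map <- tibble(reference = names(refs), clade = names(refs))
  }
  otus <- assign_clades(otus, refs, clade_map, novelty_floor = novelty_floor)
  list(otu_table = build_otu_table(otus),
       otus = otus, stage_counts = stage_counts, uniques = uniques)
}
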