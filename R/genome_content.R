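#' Cluster proteins into gene families by amino-acid identity
#'
#' Greedy centroid clustering of coding sequences across genomes, the first
#' step of gene-content phylogenetics. Candidates are sorted by length
#' (descending; ties broken by `protein_id`), and each sequence joins the first
#' centroid it matches at or above `identity_threshold` (identity defined by
#' [pairwise_identity()]), otherwise it founds a new cluster. The default 50%
#' threshold groups homologous gene families across related myovirus genomes.
#'
#' @param proteins Data frame with columns `genome_id`, `protein_id`,
#'   `sequence` (amino-acid strings, no gaps).
#' @param identity_threshold Fraction in (0, 1]; default 0.5.
#' @param exact Use the exact global alignment for every comparison instead of
#'   the ungapped fast path (slower; identical results away from the
#'   threshold boundary).
#' @return An object of class `protein_clusters`: list with `assignments`
#'   (tibble `genome_id`, `protein_id`, `cluster_id`), `centroids` (tibble
#'   `cluster_id`, `genome_id`, `protein_id`, `sequence`) and
#'   `identity_threshold`.
#' @export
cluster_proteins <- function(proteins, identity_threshold = 0.5, exact = FALSE) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) == 0) {
    return(structure(list(
      assignments = tibble(genome_id = character(), protein_id = character(),
                           cluster_id = character()),
      centroids = tibble(cluster_id = character(), genome_id = character(),
                         protein_id = character(), sequence = character()),
      identity_threshold = identity_threshold
    ), class = "protein_clusters"))
  }
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  key <- paste(proteins$genome_id, proteins$protein_id)
  if (anyDuplicated(key)) abort("(genome_id, protein_id) pairs must be unique")
  if (any(grepl("-", proteins$sequence, fixed = TRUE)) ||
      any(nchar(proteins$sequence) < 1)) {
    abort("sequences must be non-empty and gap-free")
  }
  check_protein_alphabet(proteins$sequence, key)
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  p <- proteins[ord, , drop = FALSE]
  res <- cluster_greedy_core(p$sequence, identity_threshold, exact = exact)
  cid <- sprintf("C%04d", res$cluster)
  centro <- p[res$centroid_idx, , drop = FALSE]
  structure(list(
    assignments = tibble(genome_id = p$genome_id, protein_id = p$protein_id,
                         cluster_id = cid),
    centroids = tibble(cluster_id = sprintf("C%04d", seq_along(res$centroid_idx)),
                       genome_id = centro$genome_id,
                       protein_id = centro$protein_id,
                       sequence = centro$sequence),
    identity_threshold = identity_threshold
  ), class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat("Protein clustering at", x$identity_threshold * 100, "% identity:",
      nrow(x$assignments), "proteins in", nrow(x$centroids), "clusters\n")
  invisible(x)
}

#' Gene-cluster presence/absence matrix
#'
#' Binary genomes x clusters table. A genome is marked present in a cluster if
#' it contributed at least one member; paralogs collapse to a single 1.
#'
#' @param clusters A `protein_clusters` object from [cluster_proteins()].
#' @param genome_ids Optional genome ordering; defaults to the genomes seen in
#'   the assignments. Every requested genome must have at least one protein.
#' @return Integer matrix (genomes x clusters) with dimnames.
#' @export
presence_absence <- function(clusters, genome_ids = NULL) {
  a <- clusters$assignments
  if (is.null(genome_ids)) genome_ids <- unique(a$genome_id)
  missing <- setdiff(genome_ids, unique(a$genome_id))
  if (length(missing) > 0) {
    abort(paste0("genome(s) with zero proteins: ", paste(missing, collapse = ", ")))
  }
  cl <- sort(unique(a$cluster_id))
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(cl),
              dimnames = list(genome_ids, cl))
  m[cbind(match(a$genome_id, genome_ids), match(a$cluster_id, cl))] <- 1L
  m
}

#' Gene-content phylogenetic distance
#'
#' For genomes i and j with Ni and Nj gene clusters of which Sij are shared,
#' the distance is `Dij = -ln(Sij / sqrt(Ni * Nj))`. Genomes with identical
#' cluster sets have distance 0; genomes sharing nothing would have infinite
#' distance, which is replaced by `cap` (recorded in the `"cap"` attribute) so
#' downstream tree building stays defined.
#'
#' @param pa Binary presence/absence matrix (genomes x clusters), as from
#'   [presence_absence()].
#' @param cap Distance assigned when Sij = 0 (default 10).
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
gene_content_distance <- function(pa, cap = 10) {
  pa <- as.matrix(pa)
  storage.mode(pa) <- "numeric"
  ni <- rowSums(pa)
  if (any(ni < 1)) abort("every genome must have at least one gene cluster")
  s <- pa %*% t(pa)
  d <- -log(s / sqrt(outer(ni, ni)))
  d[s == 0] <- cap
  diag(d) <- 0
  attr(d, "cap") <- cap
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising the Q criterion
#' is joined (ties broken on the lexicographically lowest label pair, internal
#' nodes carrying a deterministic label), pendant branch lengths computed from
#' the standard formulas, and the matrix reduced. Negative intermediate branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, so the output Newick is always valid. On an additive distance matrix
#' the generating tree is recovered exactly.
#'
#' @param d Symmetric labeled distance matrix (n >= 2).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 labels")
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) abort("distance matrix must be labeled")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  if (n == 2) {
    nwk <- sprintf("(%s:%.17g,%s:%.17g);", labs[1], d[1, 2] / 2, labs[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # newick fragment per active node
  frag <- labs
  key <- labs  # tie-break key per active node
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically lowest (sorted) label pair
    pair_key <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    newkey <- min(key[i], key[j])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    n <- n - 1
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  ape::read.tree(text = nwk)
}
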