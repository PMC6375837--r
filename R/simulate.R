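AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# deterministic back-translation: first codon (alphabetically) per amino acid
codon_for <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(AA20, function(a) sort(names(gc)[gc == a])[1], character(1))
    }
    tab
  }
})

back_translate <- function(aa) {
  tab <- codon_for()
  vapply(strsplit(aa, ""), function(x) paste(tab[x], collapse = ""), character(1))
}

#' Simulate a random coalescent genealogy
#'
#' A random binary coalescent tree with positive branch lengths, unrooted for
#' comparison with neighbor-joining output. Deterministic per seed.
#'
#' @param n_taxa Number of leaves (>= 2); labels `t1 ... tn`.
#' @param seed Integer seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) abort("n_taxa must be >= 2")
  set.seed(seed)
  tr <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  if (n_taxa > 2) tr <- ape::unroot(tr)
  tr
}

# preorder list of (parent, child, length) edges of a phylo tree
tree_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
             length = tr$edge.length)
}

#' Simulate gene content evolving by gain and loss along a tree
#'
#' Each genome carries `core_size` core gene families (never lost) plus
#' accessory families from a pool of size `accessory_pool`. Half the pool is
#' present at the root; along each branch the number of gains and losses is
#' Poisson in the branch length, gains drawing absent pool families and losses
#' removing present accessory families. Every family is realised as a distinct
#' random protein sequence (mutually unrelated by construction, so clustering
#' at 50% identity recovers families exactly) shared by all genomes carrying
#' it.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param core_size Number of core families (default 25).
#' @param accessory_pool Accessory family pool size (default 120).
#' @param gain_rate,loss_rate Events per unit branch length (defaults 8 and 8).
#' @param seed Integer seed.
#' @param protein_length_range Lengths for the random family proteins.
#' @return List: `gene_sets` (named list of integer family vectors per leaf),
#'   `proteins` (tibble `genome_id`, `protein_id`, `sequence`),
#'   `family_sequences`.
#' @export
simulate_gene_content <- function(tree, core_size = 25, accessory_pool = 120,
                                  gain_rate = 8, loss_rate = 8, seed = 1,
                                  protein_length_range = c(80, 300)) {
  if (gain_rate < 0 || loss_rate < 0) abort("rates must be >= 0")
  set.seed(seed)
  n_fam <- core_size + accessory_pool
  fam_len <- sample(protein_length_range[1]:protein_length_range[2],
                    n_fam, replace = TRUE)
  fam_seq <- vapply(fam_len, random_protein, character(1))
  names(fam_seq) <- sprintf("F%04d", seq_len(n_fam))
  core <- seq_len(core_size)
  pool <- core_size + seq_len(accessory_pool)
  root_set <- c(core, if (accessory_pool > 0)
    sort(sample(pool, max(1, accessory_pool %/% 2))) else integer(0))
  edges <- tree_edges_preorder(tree)
  root_node <- setdiff(edges$parent, edges$child)[1]
  sets <- list()
  sets[[as.character(root_node)]] <- root_set
  for (k in seq_len(nrow(edges))) {
    cur <- sets[[as.character(edges$parent[k])]]
    len <- edges$length[k]
    n_loss <- rpois(1, loss_rate * len)
    acc <- setdiff(cur, core)
    if (n_loss > 0 && length(acc) > 0) {
      cur <- setdiff(cur, sample(acc, min(n_loss, length(acc))))
    }
    n_gain <- rpois(1, gain_rate * len)
    absent <- setdiff(pool, cur)
    if (n_gain > 0 && length(absent) > 0) {
      cur <- c(cur, sample(absent, min(n_gain, length(absent))))
    }
    sets[[as.character(edges$child[k])]] <- sort(cur)
  }
  tips <- tree$tip.label
  gene_sets <- lapply(seq_along(tips), function(i) sets[[as.character(i)]])
  names(gene_sets) <- tips
  proteins <- purrr::map_dfr(tips, function(g) {
    fams <- gene_sets[[g]]
    tibble(genome_id = g,
           protein_id = paste0(g, "_", names(fam_seq)[fams]),
           sequence = unname(fam_seq[fams]))
  })
  list(gene_sets = gene_sets, proteins = proteins, family_sequences = fam_seq)
}

#' Simulate a marker protein evolving along a tree
#'
#' The root sequence is random; along each branch, `Poisson(rate * length)`
#' substitutions per site are applied (a substitution replaces the residue
#' with a different random amino acid). Returns full-length proteins, the
#' configured amplicon slice, and codon back-translations of the amplicons
#' for read simulation.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param length Protein length in amino acids (default 300).
#' @param rate Substitutions per site per unit branch length (default 0.3).
#' @param seed Integer seed.
#' @param amplicon_range 0-based half-open amino-acid interval of the
#'   amplified region (default `c(80, 238)`: 158 aa, a ~475 bp amplicon).
#' @return List: `proteins`, `amplicons_aa`, `amplicons_nt` (all named by
#'   leaf), and `amplicon_range`.
#' @export
simulate_marker <- function(tree, length = 300, rate = 0.3, seed = 1,
                            amplicon_range = c(80, 238)) {
  if (amplicon_range[2] > length) abort("amplicon range must lie within the marker")
  set.seed(seed)
  root_seq <- sample(AA20, length, replace = TRUE)
  edges <- tree_edges_preorder(tree)
  root_node <- setdiff(edges$parent, edges$child)[1]
  seqs <- list()
  seqs[[as.character(root_node)]] <- root_seq
  for (k in seq_len(nrow(edges))) {
    s <- seqs[[as.character(edges$parent[k])]]
    n_sub <- rpois(1, rate * edges$length[k] * length)
    if (n_sub > 0) {
      pos <- sample.int(length, min(n_sub, length))
      for (p in pos) {
        s[p] <- sample(setdiff(AA20, s[p]), 1)
      }
    }
    seqs[[as.character(edges$child[k])]] <- s
  }
  tips <- tree$tip.label
  prot <- vapply(seq_along(tips),
                 function(i) paste(seqs[[as.character(i)]], collapse = ""),
                 character(1))
  names(prot) <- tips
  amp <- substr(prot, amplicon_range[1] + 1, amplicon_range[2])
  names(amp) <- tips
  list(proteins = prot, amplicons_aa = amp,
       amplicons_nt = setNames(back_translate(amp), tips),
       amplicon_range = amplicon_range)
}

#' Simulate a panel of marker genotypes with bounded mutual identity
#'
#' Generates `n` genotypes by independently mutating a common ancestral
#' amplicon protein; extra substitutions are added until every pair sits at or
#' below `max_identity` (ungapped identity). Used to define the ground-truth
#' community for pipeline recovery experiments.
#'
#' @param n Number of genotypes.
#' @param amplicon_aa_len Amplicon protein length (default 158).
#' @param divergence Expected fraction of mutated sites per genotype
#'   (default 0.12).
#' @param max_identity Upper bound on pairwise identity (default 0.9).
#' @param seed Integer seed.
#' @return List: `amplicons_aa`, `amplicons_nt`, named `G01 ...`.
#' @export
simulate_genotype_panel <- function(n, amplicon_aa_len = 158, divergence = 0.12,
                                    max_identity = 0.9, seed = 1) {
  set.seed(seed)
  anc <- sample(AA20, amplicon_aa_len, replace = TRUE)
  mutate_at <- function(s, k) {
    pos <- sample.int(length(s), min(k, length(s)))
    for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1)
    s
  }
  geno <- lapply(seq_len(n), function(i) {
    mutate_at(anc, rpois(1, divergence * amplicon_aa_len))
  })
  ident <- function(a, b) mean(a == b)
  repeat {
    worst <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ident(geno[[i]], geno[[j]]) > max_identity) { worst <- c(i, j); break }
    }
    if (is.null(worst)) break
    geno[[worst[2]]] <- mutate_at(geno[[worst[2]]], 3)
  }
  aa <- vapply(geno, paste, character(1), collapse = "")
  names(aa) <- sprintf("G%02d", seq_len(n))
  list(amplicons_aa = aa, amplicons_nt = setNames(back_translate(aa), names(aa)))
}

#' Simulate an environmental gradient community
#'
#' Draws per-sample environmental variables from configured Gaussian
#' gradients and sets genotype relative abundances by Gaussian niche
#' responses to the designated driver variables times lognormal noise.
#' Non-driver variables influence nothing (pure noise covariates).
#'
#' @param genotypes Character vector of genotype names.
#' @param n_samples Number of samples.
#' @param env_config Named list of `c(mean, sd)` per variable; defaults to a
#'   coastal gradient: salinity 28 +/- 4 PSU, temperature 12 +/- 4 C,
#'   nitrate 10 +/- 6 uM (truncated at 0.1).
#' @param drivers Variables genotypes actually respond to
#'   (default salinity and nitrate).
#' @param niche_width Niche breadth in gradient standard deviations
#'   (default 1).
#' @param noise_sd Lognormal abundance noise sd (default 0.3).
#' @param seed Integer seed.
#' @return List: `abundances` (samples x genotypes matrix of relative
#'   abundances; rows sum to 1), `env` (tibble `sample` + variables),
#'   `optima` (genotypes x drivers matrix).
#' @export
simulate_community <- function(genotypes, n_samples,
                               env_config = list(salinity = c(28, 4),
                                                 temperature = c(12, 4),
                                                 nitrate = c(10, 6)),
                               drivers = c("salinity", "nitrate"),
                               niche_width = 1, noise_sd = 0.3, seed = 1) {
  if (length(genotypes) < 1) abort("need at least 1 genotype")
  set.seed(seed)
  vars <- names(env_config)
  env <- vapply(vars, function(v) {
    x <- rnorm(n_samples, env_config[[v]][1], env_config[[v]][2])
    pmax(x, 0.1)
  }, numeric(n_samples))
  env <- matrix(env, nrow = n_samples, dimnames = list(NULL, vars))
  opt <- vapply(drivers, function(v) {
    runif(length(genotypes), env_config[[v]][1] - 2 * env_config[[v]][2],
          env_config[[v]][1] + 2 * env_config[[v]][2])
  }, numeric(length(genotypes)))
  opt <- matrix(opt, nrow = length(genotypes),
                dimnames = list(genotypes, drivers))
  ab <- matrix(0, n_samples, length(genotypes),
               dimnames = list(sprintf("S%02d", seq_len(n_samples)), genotypes))
  for (s in seq_len(n_samples)) {
    resp <- rep(1, length(genotypes))
    for (v in drivers) {
      w <- niche_width * env_config[[v]][2]
      resp <- resp * exp(-0.5 * ((env[s, v] - opt[, v]) / w)^2)
    }
    resp <- resp * rlnorm(length(genotypes), 0, noise_sd)
    ab[s, ] <- resp / sum(resp)
  }
  list(abundances = ab,
       env = dplyr::bind_cols(tibble(sample = rownames(ab)),
                              as_tibble(env, .name_repair = "minimal")),
       optima = opt)
}

#' Simulate paired-end reads from genotype amplicons
#'
#' Reads are drawn per sample multinomially from the genotype abundances.
#' The forward read is the first `read_len` bases of the amplicon and the
#' reverse read the reverse complement of the last `read_len` bases, each
#' with independent substitution errors at `error_rate`. Base qualities use a
#' two-level model: a high-quality body plus, with probability `tail_prob`, a
#' low-quality 3' tail of up to `tail_max` bases (removed by Q30 trimming).
#'
#' @param amplicons_nt Named character vector of amplicon nucleotide
#'   sequences (equal lengths).
#' @param abundances Samples x genotypes relative abundance matrix.
#' @param reads_per_sample Pairs drawn per sample.
#' @param error_rate Per-base substitution probability (default 0.003).
#' @param read_len Read length (default 300); paired reads must overlap by at
#'   least `min_overlap` bases even after maximal tail trimming.
#' @param seed Integer seed.
#' @param tail_prob,tail_max,q_high,q_low Quality-model parameters.
#' @param min_overlap Overlap floor checked against the geometry (default 20).
#' @param reads_per_genotype If given, overrides `reads_per_sample`: each
#'   genotype receives exactly this many pairs, spread over samples in
#'   proportion to its abundance profile (fixed per-genotype sequencing
#'   effort for recovery experiments).
#' @return Tibble: `sample`, `id`, `genotype` (truth label), `seq1`, `qual1`,
#'   `seq2`, `qual2`; the realised samples x genotypes read-count matrix is
#'   in attribute `counts`.
#' @export
simulate_reads <- function(amplicons_nt, abundances, reads_per_sample,
                           error_rate = 0.003, read_len = 300, seed = 1,
                           tail_prob = 0.2, tail_max = 30,
                           q_high = 38, q_low = 10, min_overlap = 20,
                           reads_per_genotype = NULL) {
  L <- unique(nchar(amplicons_nt))
  if (length(L) != 1) abort("amplicons must have equal length")
  if (read_len > L) abort("read_len must not exceed the amplicon length")
  if (2 * (read_len - tail_max) - L < min_overlap) {
    abort("read geometry cannot guarantee the minimum overlap after trimming")
  }
  set.seed(seed)
  geno <- colnames(abundances)
  qh <- intToUtf8(q_high + 33)
  ql <- intToUtf8(q_low + 33)
  make_quals <- function(n) {
    base <- strrep(qh, read_len)
    tl <- ifelse(runif(n) < tail_prob, sample.int(tail_max, n, replace = TRUE), 0L)
    ifelse(tl == 0, base,
           paste0(strrep(qh, read_len - tl), strrep(ql, tl)))
  }
  # read allocation: per sample (multinomial over genotypes, the field
  # sampling design) or per genotype (multinomial over samples; guarantees a
  # fixed sequencing effort for every genotype in recovery experiments)
  if (is.null(reads_per_genotype)) {
    cmat <- vapply(seq_len(nrow(abundances)), function(s) {
      as.vector(rmultinom(1, reads_per_sample, abundances[s, ]))
    }, integer(length(geno)))
    cmat <- t(cmat)  # samples x genotypes
  } else {
    cmat <- vapply(seq_along(geno), function(g) {
      as.vector(rmultinom(1, reads_per_genotype,
                          abundances[, g] / sum(abundances[, g])))
    }, integer(nrow(abundances)))
  }
  dimnames(cmat) <- dimnames(abundances)
  out <- vector("list", nrow(abundances))
  for (s in seq_len(nrow(abundances))) {
    counts <- cmat[s, ]
    gl <- rep(geno, counts)
    t1 <- substr(amplicons_nt[gl], 1, read_len)
    t2 <- as.character(.revcomp_cpp(substr(amplicons_nt[gl], L - read_len + 1, L)))
    out[[s]] <- tibble(
      sample = rownames(abundances)[s],
      id = sprintf("%s_r%06d", rownames(abundances)[s], seq_along(gl)),
      genotype = gl,
      seq1 = as.character(.mutate_batch_cpp(unname(t1), error_rate)),
      qual1 = make_quals(length(gl)),
      seq2 = as.character(.mutate_batch_cpp(unname(t2), error_rate)),
      qual2 = make_quals(length(gl))
    )
  }
  res <- bind_rows(out)
  attr(res, "counts") <- cmat
  res
}
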