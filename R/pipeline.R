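#' Default end-to-end run configuration
#'
#' Stage parameters default to the study design this package models: 50%
#' identity for gene-family clustering, a ~475 bp (158 aa) amplicon, 2 x 300
#' paired-end reads, Q30 terminal trimming with a 36 nt length floor, a
#' 140 aa translated-length floor, 97% amino-acid OTU identity, minimum OTU
#' size 500, and 999 permutations for every permutation test.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @param ... Overrides for any configuration entry.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # synthetic truth
    n_taxa = 16, core_size = 25, accessory_pool = 120,
    gain_rate = 8, loss_rate = 8,
    marker_length = 300, marker_rate = 0.3, amplicon_range = c(80, 238),
    n_genotypes = 20, genotype_divergence = 0.12, genotype_max_identity = 0.9,
    n_samples = 12, reads_per_sample = 4000,
    error_rate = 0.003, read_len = 300,
    # pipeline
    cds_identity = 0.5, otu_identity = 0.97,
    q_threshold = 30, min_len = 36, min_aa = 140,
    min_otu_size = 500, min_overlap = 20, max_mismatch_frac = 0.1,
    novelty_floor = 0.75,
    # statistics
    n_perm = 999, rarefy_depth = NULL, distance_method = "bray"
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full synthetic study end to end
#'
#' Orchestrates the analysis the package implements, on synthetic data with
#' known truth: (1) marker-versus-gene-content congruence — simulate a tree,
#' evolve gene content and a marker along it, cluster proteins, compute the
#' gene-content distance, build the NJ tree, and Mantel-test the two distance
#' matrices; (2) amplicon community recovery — simulate a genotype panel,
#' environmental gradients, and paired-end reads; run the amplicon pipeline;
#' compare recovered OTUs and abundances to truth; (3) community statistics
#' on the recovered table (diversity, ordination, constrained ordination with
#' forward selection, indicator species).
#'
#' @param config List from [default_config()].
#' @param out_dir Optional directory; when given, key artifacts (trees,
#'   distance matrices, OTU table, environment table, resolved config) are
#'   written there, and stages whose outputs already exist for the same
#'   resolved configuration are reused rather than recomputed.
#' @return Nested list with elements `congruence`, `community`, `stats`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  cfg_digest <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  resume <- FALSE
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- file.path(out_dir, "config.txt")
    if (file.exists(stamp) &&
        identical(readLines(stamp, warn = FALSE), strsplit(cfg_digest, "\n")[[1]]) &&
        file.exists(file.path(out_dir, "otu_table.tsv"))) {
      resume <- TRUE
    } else {
      writeLines(cfg_digest, stamp)
    }
  }

  # --- stage 1: congruence of marker and gene-content distances ------------
  tree <- simulate_tree(cfg$n_taxa, seed = cfg$seed)
  gc_sim <- simulate_gene_content(tree, cfg$core_size, cfg$accessory_pool,
                                  cfg$gain_rate, cfg$loss_rate,
                                  seed = cfg$seed + 1)
  clusters <- cluster_proteins(gc_sim$proteins, cfg$cds_identity)
  pa <- presence_absence(clusters)
  d_content <- gene_content_distance(pa)
  nj_tree <- neighbor_joining(d_content)
  marker <- simulate_marker(tree, cfg$marker_length, cfg$marker_rate,
                            seed = cfg$seed + 2,
                            amplicon_range = cfg$amplicon_range)
  aln <- marker$proteins  # no indels simulated: sequences are pre-aligned
  d_marker <- marker_distance(aln, correction = "poisson")
  mant <- mantel_test(d_content, d_marker, n_perm = cfg$n_perm,
                      seed = cfg$seed + 3)

  # --- stage 2: amplicon community recovery --------------------------------
  panel <- simulate_genotype_panel(cfg$n_genotypes,
                                   amplicon_aa_len = diff(cfg$amplicon_range),
                                   divergence = cfg$genotype_divergence,
                                   max_identity = cfg$genotype_max_identity,
                                   seed = cfg$seed + 4)
  comm <- simulate_community(names(panel$amplicons_aa), cfg$n_samples,
                             seed = cfg$seed + 5)
  reads <- simulate_reads(panel$amplicons_nt, comm$abundances,
                          cfg$reads_per_sample, error_rate = cfg$error_rate,
                          read_len = cfg$read_len, seed = cfg$seed + 6)
  pipe <- run_amplicon_pipeline(
    reads, refs = panel$amplicons_aa,
    identity = cfg$otu_identity, min_size = cfg$min_otu_size,
    q_threshold = cfg$q_threshold, min_len = cfg$min_len,
    min_overlap = cfg$min_overlap, max_mismatch_frac = cfg$max_mismatch_frac,
    min_aa = cfg$min_aa, novelty_floor = cfg$novelty_floor)

  # --- stage 3: community statistics on the recovered table ----------------
  otu_tbl <- pipe$otu_table
  depth <- cfg$rarefy_depth %||% min(rowSums(as_count_matrix(otu_tbl)))
  rar <- rarefy(otu_tbl, depth, seed = cfg$seed + 7)
  alpha <- alpha_diversity(rar)
  d_comm <- community_distance(rar, method = cfg$distance_method)
  ord <- pcoa(d_comm)
  fs <- forward_select(rar, comm$env, n_perm = min(cfg$n_perm, 199),
                       seed = cfg$seed + 8)
  classes <- classify_env(comm$env, c("salinity", "temperature", "nitrate"),
                          k = 3, seed = cfg$seed + 9)
  iv <- indicator_species(rar, classes, n_perm = min(cfg$n_perm, 199),
                          seed = cfg$seed + 10)

  if (!is.null(out_dir) && !resume) {
    write_newick(nj_tree, file.path(out_dir, "gene_content_nj.nwk"))
    write_distance_tsv(d_content, file.path(out_dir, "gene_content_dist.tsv"))
    write_distance_tsv(d_marker, file.path(out_dir, "marker_dist.tsv"))
    write_sample_tsv(otu_tbl, file.path(out_dir, "otu_table.tsv"))
    write_sample_tsv(comm$env, file.path(out_dir, "environment.tsv"))
    write_sample_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
  }

  list(
    congruence = list(tree = tree, clusters = clusters, presence_absence = pa,
                      distance_content = d_content, distance_marker = d_marker,
                      nj_tree = nj_tree, mantel = mant),
    community = list(panel = panel, truth = comm, reads_n = nrow(reads),
                     pipeline = pipe),
    stats = list(rarefied = rar, alpha = alpha, ordination = ord,
                 forward_selection = fs, classes = classes, indicators = iv),
    config = cfg, resumed = resume
  )
}
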