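as_count_matrix <- function(table) {
  stopifnot(is.data.frame(table), "sample" %in% names(table))
  if (anyDuplicated(table$sample)) abort("duplicate sample labels")
  m <- as.matrix(table[, setdiff(names(table), "sample"), drop = FALSE])
  rownames(m) <- table$sample
  storage.mode(m) <- "numeric"
  m
}

as_sample_table <- function(m) {
  dplyr::bind_cols(tibble(sample = rownames(m)),
                   as_tibble(m, .name_repair = "minimal"))
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples `depth` reads without replacement from every sample, then drops
#' OTU columns that became all-zero. Deterministic for a given `seed`.
#'
#' @param table OTU tibble (`sample` column + integer OTU columns).
#' @param depth Reads per sample; must not exceed any sample total.
#' @param seed Integer seed.
#' @return Rarefied OTU tibble.
#' @export
rarefy <- function(table, depth, seed = 1) {
  m <- as_count_matrix(table)
  tot <- rowSums(m)
  low <- rownames(m)[tot < depth]
  if (length(low) > 0) {
    abort(paste0("depth ", depth, " exceeds total reads of sample(s): ",
                 paste(low, collapse = ", ")))
  }
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    pool <- rep.int(seq_len(ncol(m)), m[i, ])
    pick <- if (length(pool) == depth) pool else sample(pool, depth)
    out[i, ] <- tabulate(pick, nbins = ncol(m))
  }
  keep <- colSums(out) > 0
  as_sample_table(out[, keep, drop = FALSE])
}

#' Per-sample alpha diversity
#'
#' Richness (OTUs with nonzero count) and Shannon entropy
#' `H = -sum p_i ln p_i` in natural-log units.
#'
#' @param table OTU tibble.
#' @return Tibble with `sample`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  if (any(rowSums(m) == 0)) abort("every sample must have nonzero total count")
  tibble(
    sample = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = unname(apply(m, 1, function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * log(p))
    }))
  )
}

#' Beta diversity as an additive Shannon partition
#'
#' `H_gamma - mean(H_alpha)`: the Shannon entropy of the pooled community
#' minus the mean per-sample entropy. Zero when all samples share one
#' composition; at most `ln(n_samples)`. The multiplicative variant
#' `exp(H_gamma) / exp(mean H_alpha)` is available via `multiplicative`.
#'
#' @param table OTU tibble with >= 2 samples.
#' @param multiplicative Return the effective-communities ratio instead.
#' @return A single number.
#' @export
beta_shannon <- function(table, multiplicative = FALSE) {
  m <- as_count_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  h <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  gamma <- h(colSums(m))
  alpha <- mean(apply(m, 1, h))
  if (multiplicative) exp(gamma) / exp(alpha) else gamma - alpha
}

#' Community dissimilarity matrix
#'
#' Bray-Curtis (default), Jaccard (binary) or Euclidean dissimilarities on
#' per-sample relative abundances.
#'
#' @param table OTU tibble.
#' @param method `"bray"`, `"jaccard"` or `"euclidean"`.
#' @return Symmetric labeled dissimilarity matrix.
#' @export
community_distance <- function(table, method = c("bray", "jaccard", "euclidean")) {
  method <- match.arg(method)
  m <- as_count_matrix(table)
  rel <- m / rowSums(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- switch(method,
      bray = sum(abs(rel[i, ] - rel[j, ])) / sum(rel[i, ] + rel[j, ]),
      jaccard = {
        a <- m[i, ] > 0; b <- m[j, ] > 0
        1 - sum(a & b) / sum(a | b)
      },
      euclidean = sqrt(sum((rel[i, ] - rel[j, ])^2)))
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2`, then an
#' eigendecomposition. Coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues; axis percentages are taken over the sum of
#' positive eigenvalues, with negative eigenvalues reported but excluded.
#'
#' @param d Labeled dissimilarity matrix.
#' @param n_axes Number of axes to return (clipped to n - 1 with a warning).
#' @return A `pcoa_result`: list with `points` (tibble `sample`, `Axis1`...),
#'   `eigenvalues`, `percent`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n_axes > n - 1) {
    warn("n_axes clipped to n - 1")
    n_axes <- n - 1
  }
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > 1e-9 * max(abs(ev), 1))
  k <- min(n_axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k, k)
  colnames(coords) <- paste0("Axis", seq_len(k))
  pts <- dplyr::bind_cols(tibble(sample = rownames(d)),
                          as_tibble(coords, .name_repair = "minimal"))
  structure(list(points = pts, eigenvalues = ev,
                 percent = 100 * ev[pos] / sum(ev[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(2, length(x$percent))
  cat("PCoA:", nrow(x$points), "samples; first axes explain",
      paste0(sprintf("%.1f%%", x$percent[seq_len(k)]), collapse = ", "),
      "of positive-eigenvalue variation\n")
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation:
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` over the
#' mid-ranked pairwise dissimilarities (M = n(n-1)/2), with a one-tailed upper
#' permutation p-value (+1 correction) from shuffled group labels.
#'
#' @param d Labeled dissimilarity matrix.
#' @param groups Named vector or factor mapping sample label to group; at
#'   least 2 groups of 2.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An `anosim_result` with `R`, `p`, `n_perm`, `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  labs <- rownames(d)
  g <- groups[labs]
  if (any(is.na(g))) abort("groups must cover every sample label")
  g <- factor(unname(unlist(g)))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 members each")
  }
  ij <- which(upper.tri(d), arr.ind = TRUE)
  rk <- rank(d[ij])
  m <- length(rk)
  gint <- as.integer(g)
  stat <- function(p) {
    same <- p[ij[, 1]] == p[ij[, 2]]
    (mean(rk[!same]) - mean(rk[same])) / (m / 2)
  }
  r_obs <- stat(gint)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (stat(sample(gint)) >= r_obs - 1e-12) ge <- ge + 1L
  }
  structure(list(R = r_obs, p = (ge + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

#' Ordinary least-squares regression of diversity on an environmental variable
#'
#' @param y Numeric response (per-sample diversity or richness).
#' @param x Numeric environmental variable, same length; pairs with missing
#'   values are dropped.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
diversity_regression <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 paired non-missing observations")
  if (sd(x) == 0) abort("x has zero variance")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # silence the perfect-fit note
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = s$r.squared,
         p_value = s$coefficients[2, 4], n = length(x))
}

# chi-square standardized residual matrix and row weights of a count table
cca_prepare <- function(m) {
  if (any(rowSums(m) == 0)) abort("every sample needs nonzero total count")
  p <- m / sum(m)
  r <- rowSums(p); c <- colSums(p)
  qbar <- (p - outer(r, c)) / sqrt(outer(r, c))
  list(qbar = qbar, r = r)
}

# weighted standardization and row-weighted design matrix for the constraints
cca_design <- function(env_m, r) {
  xstd <- apply(env_m, 2, function(x) {
    mu <- sum(r * x) / sum(r)
    v <- sum(r * (x - mu)^2) / sum(r)
    if (v <= 0) abort("constraint variable has zero weighted variance")
    (x - mu) / sqrt(v)
  })
  sqrt(r) * xstd
}

cca_constrained_eigen <- function(qbar, xw) {
  xtx <- crossprod(xw)
  cond <- kappa(xtx, exact = TRUE)
  if (cond > 1e8) {
    abort(paste0("constraint variables are collinear (condition number ",
                 format(cond, digits = 3), "): ",
                 paste(colnames(xw), collapse = ", ")))
  }
  h <- xw %*% solve(xtx, t(xw))
  yhat <- h %*% qbar
  sv <- svd(yhat)
  list(eig = sv$d^2, u = sv$u, sv = sv)
}

#' Canonical correspondence analysis with a permutation test
#'
#' Constrained ordination of a community count table on environmental
#' variables: the chi-square standardized community matrix is projected onto
#' the row-weighted, standardized constraints; the eigenvalues of the fitted
#' space are the constrained axes. Axis importance is reported both as percent
#' of total inertia (community variation) and as percent of constrained
#' inertia (accumulated variation). Global significance is a pseudo-F
#' permutation test shuffling the sample rows of the environment table.
#'
#' @param table OTU tibble (`sample` + counts).
#' @param env Environment tibble (`sample` + numeric variables).
#' @param variables Character vector of constraint variables (default: all
#'   numeric columns of `env`). Samples with missing values in the used
#'   variables are dropped with a warning.
#' @param n_perm Permutations for the global test (default 999).
#' @param seed Integer seed.
#' @return A `cca_result`: constrained `eigenvalues`, `total_inertia`,
#'   `constrained_inertia`, `percent_total`, `percent_constrained`,
#'   `site_scores`, `biplot_scores`, `pseudo_f`, `p`.
#' @export
cca <- function(table, env, variables = NULL, n_perm = 999, seed = 1) {
  m <- as_count_matrix(table)
  stopifnot(is.data.frame(env), "sample" %in% names(env))
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  }
  ev <- env[match(rownames(m), env$sample), variables, drop = FALSE]
  complete <- stats::complete.cases(ev)
  if (!all(complete)) {
    warn(paste0("dropping sample(s) with missing environment values: ",
                paste(rownames(m)[!complete], collapse = ", ")))
    m <- m[complete, , drop = FALSE]
    ev <- ev[complete, , drop = FALSE]
  }
  if (nrow(m) <= length(variables) + 1) {
    abort("need n_samples > n_variables + 1")
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  prep <- cca_prepare(m)
  env_m <- as.matrix(ev)
  xw <- cca_design(env_m, prep$r)
  ce <- cca_constrained_eigen(prep$qbar, xw)
  q <- length(variables)
  total <- sum(prep$qbar^2)
  eig <- ce$eig[seq_len(min(q, length(ce$eig)))]
  eig <- eig[eig > 1e-12]
  ci <- sum(eig)
  n <- nrow(m)
  f_obs <- (ci / q) / ((total - ci) / (n - 1 - q))
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    xp <- cca_design(env_m[sample.int(n), , drop = FALSE], prep$r)
    cip <- sum(cca_constrained_eigen(prep$qbar, xp)$eig[seq_len(q)])
    fp <- (cip / q) / ((total - cip) / (n - 1 - q))
    if (fp >= f_obs - 1e-12) ge <- ge + 1L
  }
  k <- length(eig)
  site <- (1 / sqrt(prep$r)) * ce$u[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig), k, k)
  colnames(site) <- paste0("CCA", seq_len(k))
  biplot <- crossprod(xw, ce$u[, seq_len(k), drop = FALSE])
  biplot <- biplot / sqrt(rowSums(biplot^2) + 1e-300)
  colnames(biplot) <- paste0("CCA", seq_len(k))
  rownames(biplot) <- variables
  structure(list(
    eigenvalues = eig,
    total_inertia = total,
    constrained_inertia = ci,
    percent_total = 100 * eig / total,
    percent_constrained = 100 * eig / ci,
    site_scores = dplyr::bind_cols(tibble(sample = rownames(m)),
                                   as_tibble(site, .name_repair = "minimal")),
    biplot_scores = biplot,
    variables = variables,
    pseudo_f = f_obs,
    p = (ge + 1) / (n_perm + 1),
    n_perm = n_perm, seed = seed
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf(
    "CCA (%s): constrained %.1f%% of total inertia; CCA1 = %.2f%% of community / %.2f%% of constrained variation; global p = %.4g\n",
    paste(x$variables, collapse = " + "),
    100 * x$constrained_inertia / x$total_inertia,
    x$percent_total[1], x$percent_constrained[1], x$p))
  invisible(x)
}

#' Forward selection of environmental constraints
#'
#' Greedy stepwise construction of a CCA model: at each step the candidate
#' adding the most constrained inertia is tested by permuting its values
#' across samples (+1-corrected p of the added inertia); selection stops when
#' the best candidate's p exceeds `alpha`.
#'
#' @param table OTU tibble.
#' @param env Environment tibble.
#' @param candidates Candidate variable names (default: numeric columns).
#' @param alpha Entry threshold (default 0.05).
#' @param n_perm Permutations per test (default 199).
#' @param seed Integer seed.
#' @return Tibble with `variable`, `added_inertia`, `p`, in selection order.
#' @export
forward_select <- function(table, env, candidates = NULL, alpha = 0.05,
                           n_perm = 199, seed = 1) {
  m <- as_count_matrix(table)
  if (is.null(candidates)) {
    candidates <- setdiff(names(env)[vapply(env, is.numeric, logical(1))], "sample")
  }
  ev <- env[match(rownames(m), env$sample), candidates, drop = FALSE]
  complete <- stats::complete.cases(ev)
  m <- m[complete, , drop = FALSE]
  ev <- as.matrix(ev[complete, , drop = FALSE])
  m <- m[, colSums(m) > 0, drop = FALSE]
  prep <- cca_prepare(m)
  n <- nrow(m)
  inertia_of <- function(cols, envm) {
    xw <- cca_design(envm[, cols, drop = FALSE], prep$r)
    sum(cca_constrained_eigen(prep$qbar, xw)$eig[seq_along(cols)])
  }
  set.seed(seed)
  selected <- character(0)
  base_in <- 0
  out <- tibble(variable = character(), added_inertia = numeric(), p = numeric())
  remaining <- candidates
  while (length(remaining) > 0) {
    gains <- vapply(remaining, function(v) {
      inertia_of(c(selected, v), ev) - base_in
    }, numeric(1))
    best <- remaining[which.max(gains)]
    gain <- max(gains)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      evp <- ev
      evp[, best] <- ev[sample.int(n), best]
      if (inertia_of(c(selected, best), evp) - base_in >= gain - 1e-12) ge <- ge + 1L
    }
    pval <- (ge + 1) / (n_perm + 1)
    if (pval > alpha) break
    out <- bind_rows(out, tibble(variable = best, added_inertia = gain, p = pval))
    selected <- c(selected, best)
    base_in <- base_in + gain
    remaining <- setdiff(remaining, best)
    if (n <= length(selected) + 2) break
  }
  out
}

#' Partition samples into environmental classes
#'
#' z-scores the chosen variables and runs k-means (25 restarts, seeded).
#' Classes are numbered by descending mean of `order_by` (default `nitrate`
#' when present, else the first variable), so class 1 is the
#' highest-`order_by` class.
#'
#' @param env Environment tibble (`sample` + numeric variables).
#' @param variables Variables to cluster on.
#' @param k Number of classes (2 <= k <= n samples).
#' @param seed Integer seed.
#' @param order_by Variable used to order class labels.
#' @return Tibble with `sample`, `class` (integer).
#' @export
classify_env <- function(env, variables, k = 3, seed = 1, order_by = NULL) {
  stopifnot(is.data.frame(env), "sample" %in% names(env))
  if (k < 2 || k > nrow(env)) abort("k must be in [2, n_samples]")
  ev <- env[, variables, drop = FALSE]
  if (any(!stats::complete.cases(ev))) abort("variables must be complete")
  z <- scale(as.matrix(ev))
  set.seed(seed)
  if (k == nrow(env)) {
    km <- list(cluster = seq_len(k))  # singleton classes
  } else {
    km <- kmeans(z, centers = k, nstart = 25)
  }
  if (is.null(order_by)) {
    order_by <- if ("nitrate" %in% variables) "nitrate" else variables[1]
  }
  means <- tapply(env[[order_by]], km$cluster, mean)
  relabel <- match(names(sort(means, decreasing = TRUE)), names(means))
  new_label <- match(km$cluster, as.integer(names(means))[relabel])
  tibble(sample = env$sample, class = as.integer(new_label))
}

#' Indicator-species (IndVal) analysis
#'
#' Dufrene-Legendre indicator values: for OTU j and class k, specificity
#' `A = mean abundance in k / sum over classes of mean abundances` and
#' fidelity `B = fraction of class-k samples where j occurs`;
#' `IndVal = A * B`. Each OTU's significance is the +1-corrected permutation
#' p-value of its maximum IndVal under shuffled class labels.
#'
#' @param table OTU tibble.
#' @param classes Data frame `sample` / `class` (or named vector).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @param alpha Significance cut-off recorded in the summary (default 0.05).
#' @return An `indval_result`: list with `scores` (per OTU x class tibble of
#'   `A`, `B`, `indval`) and `summary` (per OTU: `best_class`, `indval`, `p`,
#'   `significant`).
#' @export
indicator_species <- function(table, classes, n_perm = 999, seed = 1, alpha = 0.05) {
  m <- as_count_matrix(table)
  if (is.data.frame(classes)) {
    cl <- setNames(classes$class, classes$sample)[rownames(m)]
  } else {
    cl <- classes[rownames(m)]
  }
  if (any(is.na(cl))) abort("classes must cover every sample")
  cl <- factor(unname(unlist(cl)))
  if (nlevels(cl) < 2) abort("need >= 2 classes")
  empty <- colSums(m) == 0
  if (any(empty)) {
    warn(paste0("dropping OTU(s) absent everywhere: ",
                paste(colnames(m)[empty], collapse = ", ")))
    m <- m[, !empty, drop = FALSE]
  }
  indval_mat <- function(cl) {
    mu <- apply(m, 2, function(x) tapply(x, cl, mean))      # k x j
    a <- sweep(mu, 2, colSums(mu), "/")
    b <- apply(m > 0, 2, function(x) tapply(x, cl, mean))
    a * b
  }
  iv_obs <- indval_mat(cl)
  max_obs <- apply(iv_obs, 2, max)
  set.seed(seed)
  ge <- rep(0L, ncol(m))
  for (bi in seq_len(n_perm)) {
    ivp <- indval_mat(sample(cl))
    ge <- ge + (apply(ivp, 2, max) >= max_obs - 1e-12)
  }
  pvals <- (ge + 1) / (n_perm + 1)
  scores <- as_tibble(expand.grid(class = rownames(iv_obs),
                                  otu_id = colnames(iv_obs),
                                  stringsAsFactors = FALSE)) |>
    mutate(A = as.vector(sweep(apply(m, 2, function(x) tapply(x, cl, mean)), 2,
                               colSums(apply(m, 2, function(x) tapply(x, cl, mean))), "/")),
           B = as.vector(apply(m > 0, 2, function(x) tapply(x, cl, mean))),
           indval = as.vector(iv_obs))
  summary <- tibble(
    otu_id = colnames(iv_obs),
    best_class = unname(rownames(iv_obs)[apply(iv_obs, 2, which.max)]),
    indval = unname(max_obs),
    p = unname(pvals),
    significant = pvals <= alpha
  )
  structure(list(scores = scores, summary = summary, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "indval_result")
}

#' @export
print.indval_result <- function(x, ...) {
  cat("Indicator-species analysis:", nrow(x$summary), "OTUs,",
      sum(x$summary$significant), "significant at p <=", x$alpha, "\n")
  invisible(x)
}
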