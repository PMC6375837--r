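test_that("rarefaction conserves depth, is cellwise-bounded and deterministic", {
  set.seed(51)
  m <- matrix(rpois(6 * 10, 40), 6, 10)
  tbl <- otu_tbl(m)
  r <- rarefy(tbl, depth = 100, seed = 9)
  rm_ <- as.matrix(r[, -1])
  expect_true(all(rowSums(rm_) == 100))
  expect_true(all(rm_ <= as.matrix(tbl[, -1])[, colnames(rm_)]))
  expect_identical(r, rarefy(tbl, depth = 100, seed = 9))
  # depth equal to a sample total reproduces that sample exactly
  full <- rarefy(tbl, depth = min(rowSums(m)), seed = 1)
  i <- which.min(rowSums(m))
  expect_equal(sum(full[i, -1]), min(rowSums(m)))
  # depth 1: single cell of 1 per row
  r1 <- as.matrix(rarefy(tbl, 1, seed = 2)[, -1])
  expect_true(all(rowSums(r1) == 1) && all(r1 %in% c(0, 1)))
  expect_error(rarefy(tbl, max(rowSums(m)) + 1), "exceeds")
})

test_that("alpha diversity matches hand-computed Shannon values", {
  tbl <- otu_tbl(rbind(c(5, 5, 5, 5), c(9, 0, 0, 0), c(3, 1, 0, 0)))
  a <- alpha_diversity(tbl)
  expect_equal(a$shannon, c(log(4), 0, -(0.75 * log(0.75) + 0.25 * log(0.25))),
               tolerance = 1e-4)
  expect_equal(a$richness, c(4L, 1L, 2L))
  expect_error(alpha_diversity(otu_tbl(rbind(c(1, 1), c(0, 0)))), "nonzero")
})

test_that("Shannon diversity respects its bounds with equality iff uniform", {
  set.seed(52)
  for (i in 1:20) {
    x <- rpois(8, 5) + (i %% 3 == 0)
    x[x < 0] <- 0
    if (sum(x) == 0) next
    a <- alpha_diversity(otu_tbl(matrix(x, 1)))
    expect_lte(a$shannon, log(a$richness) + 1e-12)
  }
  u <- alpha_diversity(otu_tbl(matrix(rep(7, 5), 1)))
  expect_equal(u$shannon, log(5))
})

test_that("beta Shannon partition matches closed-form toy cases", {
  same <- otu_tbl(rbind(c(2, 2), c(4, 4)))
  expect_equal(beta_shannon(same), 0)
  disjoint <- otu_tbl(rbind(c(5, 0), c(0, 5)))
  expect_equal(beta_shannon(disjoint), log(2))
  # partition bound: 0 <= beta <= ln(n_samples), fuzzed
  set.seed(53)
  for (i in 1:10) {
    m <- matrix(rpois(4 * 6, 3) + 1, 4, 6)
    b <- beta_shannon(otu_tbl(m))
    expect_gte(b, -1e-12)
    expect_lte(b, log(4) + 1e-12)
  }
})

test_that("PCoA recovers constructed geometries", {
  # three equidistant points: two equal positive eigenvalues, 50% each
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  p3 <- pcoa(d3)
  expect_equal(p3$percent[1:2], c(50, 50), tolerance = 1e-9)
  # collinear points: one positive eigenvalue carries ~100%
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x)); dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pl <- pcoa(dl)
  expect_equal(pl$percent[1], 100, tolerance = 1e-9)
  # Euclidean-embeddable: coordinates reproduce all pairwise distances
  set.seed(54)
  pts <- matrix(rnorm(6 * 3), 6, 3)
  de <- as.matrix(dist(pts)); dimnames(de) <- list(paste0("s", 1:6), paste0("s", 1:6))
  pe <- pcoa(de, n_axes = 5)
  rec <- as.matrix(dist(as.matrix(pe$points[, -1])))
  expect_lt(max(abs(rec - de)), 1e-9)
  # duplicated sample lands on coincident coordinates
  dd <- de[c(1, 1, 2:6), c(1, 1, 2:6)]
  dimnames(dd) <- list(paste0("s", 1:7), paste0("s", 1:7))
  pd <- pcoa(dd)
  expect_equal(unlist(pd$points[1, -1]), unlist(pd$points[2, -1]),
               tolerance = 1e-9)
  expect_warning(pcoa(d3, n_axes = 5), "clipped")
  # cross-check against classical scaling in stats
  ref <- cmdscale(de, k = 2, eig = TRUE)
  expect_equal(abs(as.matrix(pe$points[, 2:3])), abs(unname(ref$points)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ANOSIM matches vegan and hits its bounds on separated clouds", {
  set.seed(55)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 5, 0.1), 5))
  d <- as.matrix(dist(pts))
  labs <- paste0("s", 1:10); dimnames(d) <- list(labs, labs)
  g <- setNames(rep(c("a", "b"), each = 5), labs)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p, 0.05)
  # rank-based: invariant under monotone transforms of the dissimilarity
  expect_equal(anosim(d^2, g, n_perm = 49, seed = 2)$R, 1)
  # toy 6-sample matrix agrees with the vegan reference implementation
  set.seed(56)
  pts2 <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(pts2))
  labs2 <- paste0("s", 1:6); dimnames(d2) <- list(labs2, labs2)
  g2 <- setNames(rep(c("a", "b"), 3), labs2)
  ours <- anosim(d2, g2, n_perm = 99, seed = 3)$R
  ref <- vegan::anosim(as.dist(d2), factor(g2), permutations = 1)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
  expect_gte(ours, -1); expect_lte(ours, 1)
  expect_error(anosim(d2, setNames(c("a", rep("b", 5)), labs2)), ">= 2 groups")
})

test_that("diversity regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 5, 4, 5)
  fit <- diversity_regression(y, x)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx; intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, intercept)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2)
  exact <- diversity_regression(2 * x + 1, x)
  expect_equal(exact$r_squared, 1)
  expect_error(diversity_regression(y, rep(3, 5)), "zero variance")
  expect_error(diversity_regression(y[1:2], x[1:2]), ">= 3")
})

test_that("CCA matches vegan eigenvalues and isolates a constructed gradient", {
  set.seed(57)
  n <- 12
  grad <- seq(-2, 2, length.out = n)
  m <- cbind(
    o1 = rpois(n, exp(2 + 1.5 * grad)),
    o2 = rpois(n, exp(2 - 1.5 * grad)),
    o3 = rpois(n, 20),
    o4 = rpois(n, 10))
  tbl <- otu_tbl(m)
  env <- tibble::tibble(sample = tbl$sample, driver = grad,
                        noise = rnorm(n))
  res <- cca(tbl, env, c("driver", "noise"), n_perm = 99, seed = 1)
  ref <- vegan::cca(m ~ driver + noise, data = env)
  expect_equal(unname(res$eigenvalues),
               unname(ref$CCA$eig), tolerance = 1e-8)
  expect_equal(res$total_inertia, ref$tot.chi, tolerance = 1e-8)
  # the real driver dominates the constrained space
  expect_gt(res$percent_constrained[1], 90)
  expect_lte(res$p, 0.05)
  # constrained inertia can never exceed total inertia (fuzz)
  for (i in 1:5) {
    mf <- matrix(rpois(n * 5, 15), n)
    rf <- cca(otu_tbl(mf), env, c("driver", "noise"), n_perm = 9, seed = i)
    expect_lte(rf$constrained_inertia, rf$total_inertia + 1e-12)
  }
  # collinear constraints are refused
  env$dup <- env$driver * 2
  expect_error(cca(tbl, env, c("driver", "dup"), n_perm = 9), "collinear")
})

test_that("forward selection keeps true drivers and respects alpha", {
  set.seed(58)
  n <- 16
  grad <- rnorm(n)
  m <- cbind(o1 = rpois(n, exp(2 + 1.2 * grad)),
             o2 = rpois(n, exp(2 - 1.2 * grad)),
             o3 = rpois(n, 15))
  env <- tibble::tibble(sample = paste0("s", 1:n), driver = grad,
                        n1 = rnorm(n), n2 = rnorm(n))
  sel <- forward_select(otu_tbl(m), env, c("driver", "n1", "n2"),
                        n_perm = 99, seed = 2)
  expect_equal(sel$variable[1], "driver")
  expect_lte(sel$p[1], 0.05)
  # single-candidate selection reduces to the global constrained test
  sel1 <- forward_select(otu_tbl(m), env, "driver", n_perm = 99, seed = 3)
  expect_equal(nrow(sel1), 1)
})

test_that("environmental classification recovers separated clusters deterministically", {
  set.seed(59)
  env <- tibble::tibble(
    sample = paste0("s", 1:15),
    salinity = c(rnorm(5, 10, 0.2), rnorm(5, 25, 0.2), rnorm(5, 32, 0.2)),
    nitrate = c(rnorm(5, 30, 0.3), rnorm(5, 12, 0.3), rnorm(5, 2, 0.3)))
  cl <- classify_env(env, c("salinity", "nitrate"), k = 3, seed = 4)
  # exact recovery of the three generating groups
  expect_equal(length(unique(cl$class[1:5])), 1)
  expect_equal(length(unique(cl$class[6:10])), 1)
  expect_equal(length(unique(cl$class[11:15])), 1)
  # classes ordered by descending mean nitrate: class 1 = high-nitrate group
  expect_equal(cl$class[1], 1L)
  expect_equal(cl$class[11], 3L)
  # permuting sample order leaves the partition unchanged
  perm <- sample(15)
  cl2 <- classify_env(env[perm, ], c("salinity", "nitrate"), k = 3, seed = 4)
  expect_equal(cl2$class[match(cl$sample, cl2$sample)], cl$class)
  # k = n gives singleton classes
  cln <- classify_env(env[1:4, ], c("salinity", "nitrate"), k = 4, seed = 5)
  expect_equal(sort(cln$class), 1:4)
  expect_error(classify_env(env, c("salinity"), k = 1), "k must be")
})

test_that("IndVal matches hand-evaluated formulas and flags exclusivity", {
  classes <- tibble::tibble(sample = paste0("s", 1:4),
                            class = c(1, 1, 2, 2))
  m <- cbind(excl = c(7, 3, 0, 0),   # class-1 exclusive: IndVal 1
             unif = c(5, 5, 5, 5),   # uniform: A = 1/2
             hand = c(4, 4, 0, 2))   # A = 0.8, B = 1 for class 1
  res <- indicator_species(otu_tbl(m), classes, n_perm = 199, seed = 6)
  s <- res$summary
  expect_equal(s$indval[s$otu_id == "excl"], 1)
  expect_equal(s$indval[s$otu_id == "hand"], 0.8)
  un <- res$scores[res$scores$otu_id == "unif", ]
  expect_equal(un$A, c(0.5, 0.5))
  # agreement with the oracle formulas on every OTU/class
  for (o in colnames(m)) {
    got <- res$scores[res$scores$otu_id == o, ]
    expect_equal(got$indval, indval_by_hand(m[, o], classes$class))
  }
  expect_warning(
    indicator_species(otu_tbl(cbind(m, dead = c(0, 0, 0, 0))), classes,
                      n_perm = 9, seed = 1), "absent")
})

test_that("community distances behave like dissimilarities", {
  m <- rbind(a = c(5, 0, 5), b = c(0, 5, 5), cc = c(5, 0, 5))
  tbl <- otu_tbl(m)
  for (meth in c("bray", "jaccard", "euclidean")) {
    d <- community_distance(tbl, meth)
    expect_true(isSymmetric(unname(d)))
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_equal(unname(d[1, 3]), 0)  # identical compositions
  }
  expect_equal(unname(community_distance(tbl, "bray")[1, 2]), 0.5)
  ref <- vegan::vegdist(m / rowSums(m), "bray")
  expect_equal(unname(community_distance(tbl, "bray")[lower.tri(diag(3))]),
               as.vector(ref), tolerance = 1e-12)
})
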