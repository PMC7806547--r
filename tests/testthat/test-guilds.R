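test_that("correlation-to-distance is 1 - r with a zero diagonal", {
  r <- matrix(c(1, 1, -1, 0.4, 1, 1, 0, 0, -1, 0, 1, 0, 0.4, 0, 0, 1), 4, 4)
  r <- (r + t(r)) / 2; diag(r) <- 1
  d <- to_distance(r)
  expect_equal(d[1, 2], 1 - r[1, 2])
  expect_equal(to_distance(diag(2))[1, 2], 1)
  expect_equal(max(to_distance(matrix(c(1, -1, -1, 1), 2))), 2)
  expect_equal(diag(d), rep(0, 4))
})

test_that("ward linkage separates two tight blocks at the root and handles n=2", {
  d <- block_distance(c(4, 4), within = 0.1, between = 1.8)
  tree <- ward_linkage(d)
  root_left <- sort(.hclust_leaves(tree, nrow(tree$merge), 1))
  expect_true(identical(root_left, 1:4) || identical(root_left, 5:8))
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- ward_linkage(d2)
  expect_equal(t2$height, 0.6)
  expect_identical(t2$merge, matrix(c(-1L, -2L), 1))
  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ward linkage matches stats::hclust ward.D2 on random instances", {
  for (s in 1:10) {
    d <- random_distance(sample(4:12, 1), seed = 100 + s)
    mine <- ward_linkage(d)
    ref <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
    expect_equal(as.matrix(stats::cophenetic(mine)),
                 as.matrix(stats::cophenetic(ref))[rownames(d), rownames(d)],
                 tolerance = 1e-10)
  }
})

test_that("ward.D dialect reproduces stats::hclust ward.D heights", {
  d <- random_distance(9, seed = 77)
  mine <- ward_linkage(d, dialect = "ward.D")
  ref <- stats::hclust(stats::as.dist(d), method = "ward.D")
  expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
})

test_that("permanova matches the partition-of-sums formula and vegan::adonis2", {
  set.seed(51)
  x <- matrix(rnorm(30), 10, 3)
  x[6:10, ] <- x[6:10, ] + 1
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:10)
  g <- rep(c("A", "B"), each = 5)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(unname(res$SS["between"]), ref$SumOfSqs[1], tolerance = 1e-10)
  expect_error(permanova(d, rep("A", 10)), "2 groups")
})

test_that("permanova on exchangeable distances gives constant F and p = 1", {
  d <- block_distance(8, within = 0.7)      # all off-diagonals equal
  g <- rep(c("A", "B"), each = 4)
  res <- permanova(d, g, complete = TRUE)
  expect_equal(res$p_value, 1)
  # every labeling has the same F
  labs <- guildscan:::.all_labelings(g)
  Fs <- guildscan:::.permanova_F(d^2, labs, 2)
  expect_equal(max(Fs) - min(Fs), 0, tolerance = 1e-12)
})

test_that("permanova permutation p agrees with exhaustive enumeration", {
  d <- random_distance(6, seed = 31)
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, complete = TRUE)
  orc <- oracle_permanova(d, g)
  expect_identical(orc$n_labelings, 20L)
  expect_equal(res$pseudo_F, orc$F, tolerance = 1e-12)
  expect_identical(res$p_value, orc$p)
  # sampled permutations converge to the enumeration value
  res2 <- permanova(d, g, n_perm = 9999, seed = 4)
  expect_lt(abs(res2$p_value - orc$p), 0.03)
  expect_gte(permanova(d, g, n_perm = 999, seed = 1)$p_value, 1 / 1000)
})

test_that("tree-cut collapses structureless distances to one guild", {
  d <- block_distance(12, within = 0.9)
  tree <- ward_linkage(d)
  asg <- cut_tree_by_permanova(tree, d, alpha = 0.001, n_perm = 999, seed = 2)
  expect_identical(unique(asg$cag), "CAG1")
})

test_that("tree-cut recovers a planted 3-block partition exactly", {
  d <- block_distance(c(6, 7, 8), within = 0.1, between = 1.8)
  tree <- ward_linkage(d)
  asg <- cut_tree_by_permanova(tree, d, alpha = 0.001, n_perm = 999, seed = 3)
  expect_identical(length(unique(asg$cag)), 3L)
  truth <- setNames(rep(c("b1", "b2", "b3"), c(6, 7, 8)), rownames(d))
  expect_equal(adjusted_rand_index(
    setNames(asg$cag, asg$asv_id), truth), 1)
  expect_error(cut_tree_by_permanova(tree, d, alpha = 1.5), "alpha")
})

test_that("tree-cut guild count grows with alpha and is seed-reproducible", {
  d <- to_distance(sparcc(generate_dataset(simulation_config(
    D = 24, K = 3, n_groups = 1, group_labels = "A", n_mice_per_group = 40,
    timepoints = "d0", group_effects = matrix(0, 3, 1), rng_seed = 5))$counts,
    n_dirichlet_draws = 3, seed = 6))
  tree <- ward_linkage(d)
  n_cags <- vapply(c(0.001, 0.05, 0.5), function(a)
    length(unique(cut_tree_by_permanova(tree, d, alpha = a, n_perm = 999,
                                        seed = 11)$cag)), numeric(1))
  expect_true(all(diff(n_cags) >= 0))
  a1 <- cut_tree_by_permanova(tree, d, alpha = 0.001, n_perm = 999, seed = 11)
  a2 <- cut_tree_by_permanova(tree, d, alpha = 0.001, n_perm = 999, seed = 11)
  expect_identical(a1, a2)
  # partition covers every leaf exactly once, no empty guild
  expect_setequal(a1$asv_id, rownames(d))
  expect_true(all(table(a1$cag) >= 1))
})

test_that("guild abundances add member fractions and per-group CV behaves", {
  rel <- rbind(s1 = c(0.1, 0.25, 0.65), s2 = c(0.2, 0.2, 0.6))
  colnames(rel) <- c("A", "B", "C")
  asg <- data.frame(asv_id = c("A", "B", "C"),
                    cag = c("CAG1", "CAG1", "CAG2"))
  gab <- guild_abundance(rel, asg)
  expect_equal(gab["s1", "CAG1"], 0.35)
  # one CAG holding everything reproduces row totals
  asg1 <- data.frame(asv_id = c("A", "B", "C"), cag = "CAG1")
  expect_equal(unname(guild_abundance(rel, asg1)[, 1]),
               unname(rowSums(rel)))
  md <- data.frame(sample_id = c("s1", "s2"), group = "HF", timepoint = "d0")
  rel_eq <- rbind(s1 = c(0.1, 0.25, 0.65), s2 = c(0.1, 0.25, 0.65))
  colnames(rel_eq) <- c("A", "B", "C")
  sm <- guild_summary(guild_abundance(rel_eq, asg), md)
  expect_equal(sm$cv, c(0, 0))
})

test_that("network edges obey the display threshold monotonically", {
  set.seed(61)
  r <- diag(6)
  vals <- c(0.59, 0.6, -0.7, 0.3, 0.95, -0.2)
  k <- 1
  for (i in 1:3) for (j in (i + 1):4) { r[i, j] <- r[j, i] <- vals[k]; k <- k + 1 }
  dimnames(r) <- list(paste0("a", 1:6), paste0("a", 1:6))
  asg <- data.frame(asv_id = paste0("a", 1:6), cag = "CAG1")
  rel <- matrix(1 / 6, 3, 6, dimnames = list(paste0("s", 1:3), paste0("a", 1:6)))
  g <- build_network(r, asg, rel, min_abs_r = 0.6)
  ed <- igraph::as_data_frame(g)
  expect_false(any(abs(ed$r) < 0.6))              # 0.59 edge absent
  expect_true(any(ed$r == -0.7 & ed$sign == "negative"))
  counts <- vapply(c(0.2, 0.6, 0.8, 0.99), function(t)
    igraph::ecount(build_network(r, asg, rel, min_abs_r = t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
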