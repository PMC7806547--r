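test_that("shannon entropy in bits matches hand-computed values", {
  expect_equal(shannon(c(8, 8, 8, 8)), 2)
  expect_equal(shannon(c(16, 0, 0, 0)), 0)
  expect_equal(shannon(c(12, 4)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(shannon(c(12, 4)), 0.811278, tolerance = 1e-6)
  expect_equal(shannon(c(9, 3, 3), base = exp(1)),
               -sum(c(.6, .2, .2) * log(c(.6, .2, .2))))
  expect_error(shannon(c(0, 0)), "zero")
})

test_that("observed ASVs counts positive entries and shrinks under rarefaction", {
  expect_identical(observed_asvs(c(8, 8, 8, 8)), 4L)
  expect_identical(observed_asvs(c(0, 0)), 0L)
  set.seed(71)
  m <- matrix(rpois(40, 2), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("a", 1:10)))
  m[, 1] <- m[, 1] + 30L
  rar <- suppressMessages(rarefy(m, depth = min(rowSums(m)), seed = 1))
  expect_true(all(observed_asvs(rar) <= observed_asvs(m[rownames(rar), ])))
  # shannon bounded by log2 richness
  a <- alpha_diversity(rar)
  expect_true(all(a$shannon <= log2(pmax(a$observed_asvs, 2))))
})

test_that("bray-curtis matches the min-sum formula and its bounds", {
  u <- c(6, 2); v <- c(2, 6)
  d <- as.matrix(bray_curtis(rbind(s1 = u, s2 = v)))
  expect_equal(d["s1", "s2"], 1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v)))
  expect_equal(d["s1", "s2"], 0.5)
  ident <- as.matrix(bray_curtis(rbind(a = u, b = u)))
  expect_equal(ident["a", "b"], 0)
  disj <- as.matrix(bray_curtis(rbind(a = c(5, 0), b = c(0, 3))))
  expect_equal(disj["a", "b"], 1)
  # equal row sums: counts and their fractions give identical BC
  m <- rbind(s1 = c(6, 2, 2), s2 = c(2, 6, 2), s3 = c(1, 1, 8))
  expect_equal(as.matrix(bray_curtis(m)), as.matrix(bray_curtis(m / rowSums(m))))
  expect_error(bray_curtis(rbind(a = c(1, 1), z = c(0, 0))), "z")
})

test_that("pcoa reproduces embeddable geometries and reports eigenvalues", {
  # equilateral triangle: two equal positive eigenvalues, distances preserved
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  p3 <- pcoa(d3)
  pos <- p3$eig[p3$eig > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  expect_equal(as.matrix(dist(p3$points)), d3, tolerance = 1e-8,
               ignore_attr = TRUE)
  # collinear points: a single positive eigenvalue recovers the line
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x)); dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pl <- pcoa(dl)
  expect_length(pl$eig[pl$eig > 1e-8], 1)
  expect_equal(as.matrix(dist(pl$points[, 1])), dl, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pl$prop_explained) <= 1e-12))
  expect_true(all(pl$prop_explained <= 1 + 1e-12))
})

test_that("pcoa reconstructs random Bray-Curtis matrices from full-rank coordinates", {
  set.seed(81)
  m <- matrix(rpois(6 * 20, 10), 6, 20,
              dimnames = list(paste0("s", 1:6), paste0("a", 1:20)))
  d <- as.matrix(bray_curtis(m))
  p <- pcoa(d)
  if (all(p$eig >= -1e-10))
    expect_equal(as.matrix(dist(p$points)), d, tolerance = 1e-8,
                 ignore_attr = TRUE)
  # sample order only permutes the solution
  perm <- c(3, 1, 6, 2, 5, 4)
  p2 <- pcoa(d[perm, perm])
  expect_equal(as.matrix(dist(p2$points))[rownames(d), rownames(d)],
               as.matrix(dist(p$points)), tolerance = 1e-8)
})

test_that("kruskal-wallis per timepoint: identical groups give H = 0, p = 1", {
  at <- data.frame(sample_id = paste0("s", 1:9),
                   shannon = rep(c(1, 2, 3), 3),
                   observed_asvs = rep(c(5L, 6L, 7L), 3))
  md <- data.frame(sample_id = paste0("s", 1:9),
                   group = rep(c("A", "B", "C"), each = 3),
                   timepoint = "d0")
  res <- kruskal_by_timepoint(at, md)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("kruskal-wallis H matches the direct rank formula on separated groups", {
  at <- data.frame(sample_id = paste0("s", 1:6),
                   shannon = c(1, 2, 3, 10, 11, 12),
                   observed_asvs = 1L)
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("lo", "hi"), each = 3), timepoint = "d7")
  res <- kruskal_by_timepoint(at, md, metrics = "shannon")
  # H = 12/(N(N+1)) * sum n_g (Rbar_g - (N+1)/2)^2 with ranks 1..6
  H <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(res$statistic, H)
  # the same split through the Mann-Whitney path gives the exact 2/20 p
  expect_equal(stats::wilcox.test(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1)
})

test_that("benjamini-hochberg step-up matches the closed form and is monotone", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(91)
  p <- runif(25)
  adj <- stats::p.adjust(p, "BH")
  expect_identical(order(adj[order(p)]), seq_len(25))  # order preserved
})

test_that("pairwise permanova separates shifted groups and adjusts within timepoint", {
  set.seed(95)
  x <- matrix(rpois(24 * 8, 20), 24, 8)
  x[9:16, 1:4] <- x[9:16, 1:4] + 40      # group B shifted
  rownames(x) <- paste0("s", 1:24); colnames(x) <- paste0("a", 1:8)
  md <- data.frame(sample_id = paste0("s", 1:24),
                   group = rep(c("A", "B", "C"), each = 8),
                   timepoint = rep(c("d0", "d7"), 12))
  res <- pairwise_permanova(bray_curtis(x), md, n_perm = 199, seed = 1)
  expect_setequal(unique(res$timepoint), c("d0", "d7"))
  expect_identical(nrow(res), 6L)
  ab <- res[res$group1 == "A" & res$group2 == "B", ]
  expect_true(all(ab$p_value <= 0.05))
  for (t_ in c("d0", "d7")) {
    sub <- res[res$timepoint == t_, ]
    expect_equal(sub$p_adjusted, stats::p.adjust(sub$p_value, "BH"))
  }
})
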