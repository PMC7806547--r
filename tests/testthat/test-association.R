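make_gab <- function(values, cags = "CAG1") {
  m <- as.matrix(values)
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))), cags)
  m
}

test_that("spearman association hits +/-1 on monotone data and handles missingness", {
  gab <- make_gab(1:8)
  ph <- data.frame(sample_id = paste0("s", 1:8),
                   up = (1:8)^3, down = exp(-(1:8)), short = c(2, 1, NA, NA,
                                                               NA, NA, NA, NA))
  res <- spearman_assoc(gab, ph)
  expect_equal(res$rho[res$variable == "up"], 1)
  expect_equal(res$rho[res$variable == "down"], -1)
  # <3 complete pairs: untestable, excluded from the BH family
  expect_true(is.na(res$fdr[res$variable == "short"]))
  expect_identical(res$n[res$variable == "short"], 2L)
  tested <- !is.na(res$p_value)
  expect_equal(res$fdr[tested], stats::p.adjust(res$p_value[tested], "BH"))
})

test_that("spearman rho and exact p match the rank formula and full enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 1, 2, 4, 5)                       # sum d^2 = 6 -> rho = 0.7
  expect_equal(1 - 6 * sum((rank(x) - rank(y))^2) / (5 * 24), 0.7)
  gab <- make_gab(x)
  ph <- data.frame(sample_id = paste0("s", 1:5), v = y)
  res <- spearman_assoc(gab, ph)
  expect_equal(res$rho, 0.7)
  expect_equal(res$p_value, oracle_spearman_p(x, y))
})

test_that("spearman association is invariant to strictly monotone transforms", {
  set.seed(101)
  x <- rnorm(12); y <- rnorm(12)
  gab <- make_gab(x)
  p1 <- spearman_assoc(gab, data.frame(sample_id = rownames(gab), v = y))
  p2 <- spearman_assoc(make_gab(exp(2 * x)),
                       data.frame(sample_id = rownames(gab), v = y^3 + 5 * y))
  expect_equal(p1$rho, p2$rho)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("mann-whitney differential matches exhaustive enumeration on {1,2,3} vs {4,5,6}", {
  gab <- make_gab(c(1, 2, 3, 4, 5, 6))
  md <- data.frame(sample_id = rownames(gab),
                   group = rep(c("lo", "hi"), each = 3))
  res <- mann_whitney_da(gab, md)
  expect_equal(res$p_value, 0.1)              # 2 of the 20 labelings as extreme
  expect_true(res$U %in% c(0, 9))
  expect_identical(res$direction, "hi")
  # identical groups: p = 1
  gab2 <- make_gab(rep(0.25, 6))
  expect_equal(mann_whitney_da(gab2, md)$p_value, 1)
  # rank invariance under location shift
  res_shift <- mann_whitney_da(make_gab(c(1, 2, 3, 4, 5, 6) + 100), md)
  expect_equal(res_shift$U, res$U)
  expect_equal(res_shift$p_value, res$p_value)
})

test_that("mann-whitney BH families are per pair by default, global on request", {
  set.seed(111)
  gab <- make_gab(cbind(rnorm(18), rnorm(18), rnorm(18)),
                  c("CAG1", "CAG2", "CAG3"))
  md <- data.frame(sample_id = rownames(gab),
                   group = rep(c("A", "B", "C"), each = 6))
  res <- mann_whitney_da(gab, md)
  for (pr in split(res, paste(res$group1, res$group2)))
    expect_equal(pr$fdr, stats::p.adjust(pr$p_value, "BH"))
  resg <- mann_whitney_da(gab, md, family = "global")
  expect_equal(resg$fdr, stats::p.adjust(resg$p_value, "BH"))
  expect_true(all(res$U >= 0 & res$U <= 36))
})

test_that("z-scores standardise group means and flag flat guilds", {
  gab <- make_gab(cbind(c(1, 1, 2, 2, 3, 3), rep(0.2, 6)), c("CAG1", "CAG2"))
  md <- data.frame(sample_id = rownames(gab),
                   group = rep(c("g1", "g2", "g3"), each = 2))
  z <- zscore_table(gab, md)
  expect_equal(unname(z["CAG1", ]), c(-1, 0, 1))
  expect_equal(unname(z["CAG2", ]), c(0, 0, 0))
  expect_identical(attr(z, "flat"), "CAG2")
  expect_equal(unname(rowSums(z)), c(0, 0), tolerance = 1e-12)
})

test_that("a planted guild-phenotype link is detected at FDR < 0.05 in >= 90% of replicates", {
  # moderately even community (mu_sd = 0.5): with the default, highly uneven
  # baseline the guild-abundance marginal is so skewed that rank correlation
  # loses power even at 50% explained variance
  base_cfg <- function(n_mice, noise_sd, seed)
    simulation_config(
      D = 40, K = 4, n_groups = 1, group_labels = "A",
      n_mice_per_group = n_mice, timepoints = "d105", mu_sd = 0.5,
      group_effects = matrix(0, 4, 1),
      phenotype_weights = list(
        tg = list(weights = c(1, 0, 0, 0), intercept = 1,
                  noise_sd = noise_sd)),
      rng_seed = seed)
  # calibrate the noise so the planted guild explains half of the phenotype
  # variance: noise SD = population SD of the guild-1 abundance signal
  pilot <- generate_dataset(base_cfg(400, 0, 4999))
  sd_signal <- stats::sd(pilot$phenotypes$tg)
  nrep <- 100
  hits <- logical(nrep)
  for (r in seq_len(nrep)) {
    cfg <- base_cfg(30, sd_signal, 5000 + r)
    ds <- generate_dataset(cfg)
    rel <- to_relative(ds$counts)
    truth <- ds$truth$guilds[colnames(rel)]
    asg <- data.frame(asv_id = names(truth), cag = unname(truth))
    gab <- guild_abundance(rel, asg)
    res <- spearman_assoc(gab, ds$phenotypes)
    hits[r] <- res$fdr[res$cag == "G1" & res$variable == "tg"] < 0.05
  }
  expect_gte(mean(hits), 0.9)
})
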