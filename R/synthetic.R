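# Synthetic ASV tables with planted guild structure, group effects and
# coupled phenotypes — the ground truth every pipeline stage is tested
# against.
#
# Generative model, per sample s: each guild k draws a shared factor
# f_ks ~ N(0, 1); ASV i in guild k has log basis abundance
#   a_is = mu_i + effect(group(s), k) + lambda * f_ks + e_is,
# with e_is ~ N(0, sigma_resid) and lambda set so the within-guild log-scale
# correlation lambda^2 / (lambda^2 + sigma_resid^2) equals
# `intra_guild_corr`. Fractions are the softmax of the log abundances;
# sequencing depth is negative binomial; counts are multinomial at that
# depth. Phenotypes are linear in the terminal-sample guild relative
# abundances plus Gaussian noise.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_dataset()]. Defaults
#' emulate a three-group prebiotic mouse study: 10 mice per group sampled at
#' five days (d0 baseline, then d7/d77/d84/d105), 300 ASVs in 30 guilds of
#' 10, within-guild correlation 0.8, negative-binomial depths around 32,000
#' reads, a quarter of the guilds promoted by treatment (+1.5 log units in
#' both treated groups after baseline) and about half suppressed (-1.0), and
#' terminal phenotypes (hepatic TG, serum TC, cecal SCFAs) linear in the
#' promoted/suppressed guild abundances with opposite signs.
#'
#' @param n_groups Number of groups (default 3).
#' @param group_labels Group names (default HF, HF-UP, HF-ARP style).
#' @param n_mice_per_group Mice per group (default 10).
#' @param timepoints Timepoint labels; the first is an untreated baseline
#'   when `baseline_null` is TRUE (default d0, d7, d77, d84, d105).
#' @param D Number of ASVs (default 300).
#' @param K Number of guilds (default 30).
#' @param guild_sizes Integer vector summing to `D` (default equal).
#' @param intra_guild_corr Target within-guild log-scale correlation in
#'   \[0, 1) (default 0.8).
#' @param mu Optional length-`D` baseline log-abundance vector; by default
#'   drawn once as N(0, `mu_sd`) from the seed.
#' @param mu_sd SD of the default baseline draw (default 1.5; spreads ASVs
#'   over ~3 orders of magnitude, so a 20% prevalence filter bites).
#' @param sigma_resid Residual log-scale SD (default 1).
#' @param group_effects K x n_groups matrix of log-fold group effects, or
#'   `NULL` for the default promoted/suppressed pattern; use a zero matrix
#'   for a null simulation.
#' @param baseline_null Apply group effects only after the first timepoint
#'   (default TRUE).
#' @param depth_mean,depth_dispersion Negative-binomial depth model (mean
#'   32000, size 30 — SD about 5,900, so a 16,500-read rarefaction
#'   occasionally drops a sample).
#' @param phenotype_weights Named list per phenotype:
#'   `list(weights = K-vector, intercept, noise_sd)`; `NULL` for defaults.
#' @param rng_seed Seed (default 1).
#' @return Validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_groups = 3,
                              group_labels = NULL,
                              n_mice_per_group = 10,
                              timepoints = c("d0", "d7", "d77", "d84", "d105"),
                              D = 300, K = 30, guild_sizes = NULL,
                              intra_guild_corr = 0.8,
                              mu = NULL, mu_sd = 1.5, sigma_resid = 1,
                              group_effects = NULL, baseline_null = TRUE,
                              depth_mean = 32000, depth_dispersion = 30,
                              phenotype_weights = NULL, rng_seed = 1L) {
  if (is.null(group_labels))
    group_labels <- c("HF", "HF-UP", "HF-ARP", paste0("G", seq_len(max(0, n_groups - 3))))[seq_len(n_groups)]
  if (is.null(guild_sizes)) {
    guild_sizes <- rep(D %/% K, K)
    guild_sizes[seq_len(D %% K)] <- guild_sizes[seq_len(D %% K)] + 1L
  }
  problems <- character()
  if (length(group_labels) != n_groups) problems <- c(problems, "group_labels length != n_groups")
  if (sum(guild_sizes) != D) problems <- c(problems, "guild_sizes must sum to D")
  if (any(guild_sizes < 1)) problems <- c(problems, "guild_sizes must be >= 1")
  if (intra_guild_corr < 0 || intra_guild_corr >= 1)
    problems <- c(problems, "intra_guild_corr must be in [0, 1)")
  if (!is.null(mu) && length(mu) != D) problems <- c(problems, "mu must have length D")
  if (sigma_resid <= 0) problems <- c(problems, "sigma_resid must be > 0")
  if (depth_mean < 1) problems <- c(problems, "depth_mean must be >= 1")
  if (n_mice_per_group < 1) problems <- c(problems, "n_mice_per_group must be >= 1")
  if (is.null(group_effects)) {
    n_prom <- max(1L, round(0.25 * K))
    n_supp <- min(K - n_prom, round(0.47 * K))
    group_effects <- matrix(0, K, n_groups,
                            dimnames = list(paste0("G", seq_len(K)), group_labels))
    if (n_groups >= 2) {
      treated <- seq(2L, n_groups)
      group_effects[seq_len(n_prom), treated] <- 1.5
      if (n_supp > 0)
        group_effects[n_prom + seq_len(n_supp), treated] <- -1.0
    }
  }
  group_effects <- as.matrix(group_effects)
  if (!all(dim(group_effects) == c(K, n_groups)))
    problems <- c(problems, "group_effects must be a K x n_groups matrix")
  if (is.null(phenotype_weights)) {
    prom <- which(apply(group_effects, 1L, max) > 0)
    supp <- which(apply(group_effects, 1L, min) < 0)
    if (!length(prom)) prom <- 1L
    mk <- function(wp, ws, intercept, noise_sd) {
      w <- numeric(K); w[prom] <- wp; w[supp] <- ws
      list(weights = w, intercept = intercept, noise_sd = noise_sd)
    }
    phenotype_weights <- list(
      TG_liver   = mk(-6,   3,   6,  0.6),
      TC_serum   = mk(-5,   2.5, 4,  0.4),
      acetate    = mk( 3,  -1.5, 30, 3),
      propionate = mk( 6,  -3,   10, 1),
      butyrate   = mk( 2,  -1,   8,  0.8))
  }
  for (nm in names(phenotype_weights)) {
    pw <- phenotype_weights[[nm]]
    if (length(pw$weights) != K)
      problems <- c(problems, paste0("phenotype '", nm, "' weights must have length K"))
  }
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(n_groups = n_groups, group_labels = group_labels,
                 n_mice_per_group = n_mice_per_group, timepoints = timepoints,
                 D = D, K = K, guild_sizes = as.integer(guild_sizes),
                 intra_guild_corr = intra_guild_corr, mu = mu, mu_sd = mu_sd,
                 sigma_resid = sigma_resid, group_effects = group_effects,
                 baseline_null = baseline_null, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 phenotype_weights = phenotype_weights,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Generate a synthetic dataset with planted guilds
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$rng_seed` when given.
#' @return List of class `"synthetic_dataset"`: `counts` (samples x ASVs),
#'   `metadata` (`sample_id`, `group`, `timepoint`, `cage`, `mouse`),
#'   `phenotypes` (terminal samples only), and `truth` (`guilds` named
#'   ASV -> guild map, `group_effects`, `phenotype_weights`, `lambda`).
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$rng_seed
  cf <- config
  asv_ids <- sprintf("ASV%03d", seq_len(cf$D))
  guild_of <- rep(seq_len(cf$K), cf$guild_sizes)
  guild_labels <- paste0("G", seq_len(cf$K))
  mu <- if (is.null(cf$mu))
    .with_seed(.child_seed(seed, "mu"), stats::rnorm(cf$D, 0, cf$mu_sd))
  else cf$mu
  icc <- cf$intra_guild_corr
  lambda <- cf$sigma_resid * sqrt(icc / (1 - icc))
  grid <- expand.grid(timepoint = cf$timepoints,
                      mouse = seq_len(cf$n_mice_per_group),
                      group = cf$group_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$group, cf$group_labels), grid$mouse,
                     match(grid$timepoint, cf$timepoints)), , drop = FALSE]
  n_s <- nrow(grid)
  sample_id <- sprintf("%s.m%02d.%s", grid$group, grid$mouse, grid$timepoint)
  g_idx <- match(grid$group, cf$group_labels)
  baseline <- cf$baseline_null & grid$timepoint == cf$timepoints[1L]
  counts <- matrix(0L, n_s, cf$D, dimnames = list(sample_id, asv_ids))
  rel_guild <- matrix(0, n_s, cf$K)
  .with_seed(.child_seed(seed, "data"), {
    f <- matrix(stats::rnorm(n_s * cf$K), n_s, cf$K)
    e <- matrix(stats::rnorm(n_s * cf$D, 0, cf$sigma_resid), n_s, cf$D)
    eff <- t(cf$group_effects)[g_idx, , drop = FALSE]  # n_s x K
    eff[baseline, ] <- 0
    loga <- matrix(mu, n_s, cf$D, byrow = TRUE) +
      eff[, guild_of, drop = FALSE] + lambda * f[, guild_of, drop = FALSE] + e
    frac <- exp(loga - apply(loga, 1L, max))
    frac <- frac / rowSums(frac)
    depth <- pmax(1L, stats::rnbinom(n_s, mu = cf$depth_mean,
                                     size = cf$depth_dispersion))
    for (s in seq_len(n_s)) {
      counts[s, ] <- as.integer(stats::rmultinom(1L, depth[s], frac[s, ]))
      rel_guild[s, ] <- rowsum(frac[s, ], guild_of)[, 1L]
    }
  })
  metadata <- data.frame(sample_id = sample_id, group = grid$group,
                         timepoint = grid$timepoint, mouse = grid$mouse,
                         cage = sprintf("%s.c%d", grid$group,
                                        ceiling(grid$mouse / 5)),
                         stringsAsFactors = FALSE)
  terminal <- grid$timepoint == cf$timepoints[length(cf$timepoints)]
  phen <- data.frame(sample_id = sample_id[terminal],
                     stringsAsFactors = FALSE)
  .with_seed(.child_seed(seed, "phen"), {
    for (nm in names(cf$phenotype_weights)) {
      pw <- cf$phenotype_weights[[nm]]
      phen[[nm]] <- pw$intercept +
        as.numeric(rel_guild[terminal, , drop = FALSE] %*% pw$weights) +
        stats::rnorm(sum(terminal), 0, pw$noise_sd)
    }
  })
  if (all(c("acetate", "propionate", "butyrate") %in% names(phen)))
    phen$total_SCFA <- phen$acetate + phen$propionate + phen$butyrate
  truth_guilds <- stats::setNames(guild_labels[guild_of], asv_ids)
  structure(list(counts = counts, metadata = metadata, phenotypes = phen,
                 truth = list(guilds = truth_guilds,
                              group_effects = cf$group_effects,
                              phenotype_weights = cf$phenotype_weights,
                              lambda = lambda),
                 config = cf, seed = seed),
            class = "synthetic_dataset")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions, about 0 for
#' unrelated ones. When the expected index equals the maximum index (e.g.
#' all-singletons vs one block) the usual formula is 0/0; the convention here
#' returns 0.
#'
#' @param a,b Partition label vectors over the same items (named vectors are
#'   matched by name).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different item sets", call. = FALSE)
    b <- b[names(a)]
  }
  if (length(a) != length(b))
    stop("partitions cover different item sets", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Score guild recovery against planted truth
#'
#' @param assignment Guild assignment (data frame with `asv_id`/`cag`, or a
#'   named label vector).
#' @param truth Named ASV -> guild vector (e.g. `dataset$truth$guilds`),
#'   subset to the ASVs that survived filtering if needed.
#' @return Adjusted Rand index.
#' @export
evaluate_recovery <- function(assignment, truth) {
  if (is.data.frame(assignment))
    assignment <- stats::setNames(assignment$cag, assignment$asv_id)
  if (!setequal(names(assignment), names(truth)))
    stop("assignment and truth cover different ASV sets (",
         length(setdiff(names(truth), names(assignment))), " missing, ",
         length(setdiff(names(assignment), names(truth))), " extra)",
         call. = FALSE)
  adjusted_rand_index(assignment, truth[names(assignment)])
}
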