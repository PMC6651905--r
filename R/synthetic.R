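#' Cohort simulation configuration
#'
#' Describes one synthetic cohort: a marker gene whose activity score in
#' \[0,1\] follows a two-component truncated-Gaussian mixture, a module of
#' genes rank-correlated with the marker, background noise genes, and
#' right-censored exponential survival whose hazard depends on the true
#' marker stratum.
#'
#' Defaults mirror the stated study world: a high-expression fraction of
#' 0.267, component means 0.2/0.8 with sd 0.1, a co-expression module at
#' Spearman rho 0.45, and a stratum hazard ratio of 2 on a yearly time scale.
#'
#' @param n_samples,n_genes positive integers; `n_genes` counts non-marker
#'   genes (module genes included).
#' @param marker_mix_weight fraction in (0,1) of samples in the "high"
#'   component.
#' @param marker_high_mean,marker_low_mean component means on the activity
#'   scale, with `marker_low_mean < marker_high_mean`.
#' @param marker_sd common component standard deviation.
#' @param module_genes number of genes rank-correlated with the marker;
#'   defaults to `min(20, n_genes)`.
#' @param module_rho target Spearman correlation in (-1, 1).
#' @param hazard_low,hazard_high event rates per time unit for the low/high
#'   marker strata.
#' @param censor_rate rate of independent exponential censoring.
#' @param max_followup administrative cutoff in time units.
#' @param seed integer seed for this cohort's random stream.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 226L, n_genes = 200L,
                          marker_mix_weight = 0.267,
                          marker_low_mean = 0.2, marker_high_mean = 0.8,
                          marker_sd = 0.1,
                          module_genes = NULL, module_rho = 0.45,
                          hazard_low = 0.15, hazard_high = 0.075,
                          censor_rate = 0.05, max_followup = 12,
                          seed = 1L) {
  stopifnot(length(n_samples) == 1, length(n_genes) == 1)
  if (n_samples < 1 || n_genes < 1)
    stop("n_samples and n_genes must be positive integers")
  if (!(marker_mix_weight > 0 && marker_mix_weight < 1))
    stop("marker_mix_weight must lie in (0,1)")
  if (!(marker_low_mean < marker_high_mean))
    stop("marker_low_mean must be smaller than marker_high_mean")
  if (marker_sd <= 0) stop("marker_sd must be positive")
  if (abs(module_rho) >= 1) stop("module_rho must lie in (-1,1)")
  if (is.null(module_genes)) module_genes <- min(20L, n_genes)
  if (module_genes < 0 || module_genes > n_genes)
    stop("module_genes must be between 0 and n_genes")
  if (hazard_low <= 0 || hazard_high <= 0 || censor_rate <= 0 ||
      max_followup <= 0)
    stop("all rates and max_followup must be positive")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    marker_mix_weight = marker_mix_weight,
    marker_low_mean = marker_low_mean, marker_high_mean = marker_high_mean,
    marker_sd = marker_sd,
    module_genes = as.integer(module_genes), module_rho = module_rho,
    hazard_low = hazard_low, hazard_high = hazard_high,
    censor_rate = censor_rate, max_followup = max_followup,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Deterministic per-cohort substream seed: index 1 keeps the config's own
# seed (so a singleton multi-cohort equals generate_cohort), later indices
# shift it so adding cohorts never perturbs earlier ones. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) + (index - 1) * 69621) %% 2147483647)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; exact, no rejection.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Density of the [0,1]-truncated two-component marker mixture.
marker_mixture_density <- function(x, config) {
  tn <- function(x, m, s) {
    z <- stats::pnorm(1, m, s) - stats::pnorm(0, m, s)
    ifelse(x >= 0 & x <= 1, stats::dnorm(x, m, s) / z, 0)
  }
  w <- config$marker_mix_weight
  (1 - w) * tn(x, config$marker_low_mean, config$marker_sd) +
    w * tn(x, config$marker_high_mean, config$marker_sd)
}

# Analytic valley: minimum of the mixture density between the component means.
true_valley <- function(config) {
  stats::optimize(function(x) marker_mixture_density(x, config),
                  c(config$marker_low_mean, config$marker_high_mean))$minimum
}

#' Simulate one cohort
#'
#' Marker activity scores are drawn from a two-component Gaussian mixture
#' truncated to \[0,1\]. Module genes are built copula-style: the marker's
#' normal scores form a shared latent variable and each module gene is a
#' linear blend of that latent with independent noise, using the
#' `2*sin(pi*rho/6)` Pearson-from-Spearman conversion so the empirical
#' Spearman correlation targets `module_rho`. Remaining genes are i.i.d.
#' standard Gaussian intensities. Survival is exponential with
#' stratum-specific hazard, censored by an independent exponential time and
#' an administrative cutoff at `max_followup`.
#'
#' @param config a [cohort_config()].
#' @param cohort_id string used to build sample/feature identifiers.
#' @return A `synthetic_cohort`: list with `expression` (marker activity
#'   track plus gene intensities, an [expression_matrix()]), `clinical`
#'   (data frame with `sample_id`, `dfs_time`, `dfs_event`, `stage`, `sex`,
#'   `age`), and `truth` (true stratum labels, analytic valley location,
#'   true hazard ratio hazard_high/hazard_low).
#' @export
generate_cohort <- function(config, cohort_id = "cohort1") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("%s_S%03d", cohort_id, seq_len(n))

  stratum <- ifelse(stats::runif(n) < config$marker_mix_weight, "high", "low")
  mu <- ifelse(stratum == "high", config$marker_high_mean,
               config$marker_low_mean)
  marker <- rtruncnorm(n, mu, config$marker_sd)

  # Shared latent = normal scores of the marker ranks (copula construction).
  z <- stats::qnorm((rank(marker, ties.method = "average") - 0.5) / n)
  rp <- 2 * sin(pi * config$module_rho / 6)
  m <- config$module_genes
  genes <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes)
  if (m > 0) {
    noise <- matrix(stats::rnorm(m * n), nrow = m)
    genes[seq_len(m), ] <- rp * matrix(z, nrow = m, ncol = n, byrow = TRUE) +
      sqrt(1 - rp^2) * noise
  }
  feature_ids <- c("MARKER",
                   if (m > 0) sprintf("MOD%03d", seq_len(m)),
                   if (config$n_genes > m)
                     sprintf("BG%04d", seq_len(config$n_genes - m)))
  values <- rbind(marker, genes)
  dimnames(values) <- list(feature_ids, sample_ids)

  hz <- ifelse(stratum == "high", config$hazard_high, config$hazard_low)
  t_event <- stats::rexp(n, hz)
  t_cens <- pmin(stats::rexp(n, config$censor_rate), config$max_followup)
  dfs_time <- pmin(t_event, t_cens)
  dfs_event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(
    sample_id = sample_ids,
    dfs_time = dfs_time,
    dfs_event = dfs_event,
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::rnorm(n, 67, 10), 1),
    stringsAsFactors = FALSE
  )

  structure(list(
    expression = expression_matrix(values, value_kind = "mixed"),
    clinical = clinical,
    truth = list(stratum = stats::setNames(stratum, sample_ids),
                 valley = true_valley(config),
                 hazard_ratio = config$hazard_high / config$hazard_low),
    config = config
  ), class = "synthetic_cohort")
}

#' Simulate several cohorts
#'
#' Each cohort gets an independent random substream derived from the global
#' seeds in its config, so cohorts are reproducible individually and adding
#' a cohort does not perturb earlier ones. With `shared_truth = TRUE` all
#' cohorts reuse the first config's component means, spread and mixture
#' weight, so one pooled threshold is correct for all of them.
#'
#' @param configs non-empty list of [cohort_config()] objects.
#' @param shared_truth logical; harmonize marker mixture parameters.
#' @param ids optional character vector of cohort aliases.
#' @return Named list of `synthetic_cohort` objects.
#' @export
generate_multi_cohort <- function(configs, shared_truth = FALSE, ids = NULL) {
  if (length(configs) == 0) stop("configs must be a non-empty list")
  if (is.null(ids)) ids <- sprintf("cohort%d", seq_along(configs))
  stopifnot(length(ids) == length(configs))
  if (shared_truth) {
    ref <- configs[[1]]
    configs <- lapply(configs, function(cf) {
      cf$marker_mix_weight <- ref$marker_mix_weight
      cf$marker_low_mean <- ref$marker_low_mean
      cf$marker_high_mean <- ref$marker_high_mean
      cf$marker_sd <- ref$marker_sd
      cf
    })
  }
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    cf$seed <- derive_seed(cf$seed, i)
    out[[i]] <- generate_cohort(cf, cohort_id = ids[i])
  }
  stats::setNames(out, ids)
}

#' Write a synthetic cohort to TSV files
#'
#' Emits the expression matrix and the clinical table in the formats read
#' back by [read_expression()] and [read_clinical()], plus a `*_truth.tsv`
#' sidecar with the true stratum per sample.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_expression.tsv",
                                           "_clinical.tsv", "_truth.tsv")))
  write_expression(cohort$expression, paths[1])
  write_tsv_full(cohort$clinical, paths[2])
  truth <- data.frame(sample_id = names(cohort$truth$stratum),
                      true_stratum = unname(cohort$truth$stratum),
                      true_valley = cohort$truth$valley,
                      true_hazard_ratio = cohort$truth$hazard_ratio)
  write_tsv_full(truth, paths[3])
  invisible(paths)
}
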