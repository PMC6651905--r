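# Average ranks plus the tie-correction term sum(t^3 - t).
rank_with_ties <- function(x) {
  r <- rank(x)
  tie_sizes <- table(x)
  list(ranks = r, tie_term = sum(tie_sizes^3 - tie_sizes))
}

# Wilcoxon rank-sum, normal approximation with tie correction, no
# continuity correction. Statistic reported as the rank sum of group 1.
wilcoxon_ranksum <- function(x, g) {
  lev <- sort(unique(g))
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2]); N <- n1 + n2
  rt <- rank_with_ties(x)
  R1 <- sum(rt$ranks[g == lev[1]])
  mu <- n1 * (N + 1) / 2
  v <- n1 * n2 / 12 * ((N + 1) - rt$tie_term / (N * (N - 1)))
  if (v <= 0) stop("zero rank variance")
  z <- (R1 - mu) / sqrt(v)
  list(statistic = R1, p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction, chi-square approximation (k-1 df).
kruskal_wallis <- function(x, g) {
  N <- length(x)
  rt <- rank_with_ties(x)
  groups <- split(rt$ranks, g)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(groups, function(r) sum(r)^2 / length(r), numeric(1))) -
    3 * (N + 1)
  C <- 1 - rt$tie_term / (N^3 - N)
  if (C <= 0) stop("all observations tied")
  H <- H / C
  list(statistic = H,
       p_value = stats::pchisq(H, df = length(groups) - 1,
                               lower.tail = FALSE))
}

# Pearson correlation with the t-test on n-2 df.
pearson_assoc <- function(x, y) {
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(statistic = r, p_value = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = r,
       p_value = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
}

#' Test the association of marker expression with one covariate
#'
#' Dispatch follows covariate arity: two categories use the Wilcoxon
#' rank-sum test (statistic = group-1 rank sum), more than two use
#' Kruskal-Wallis, and continuous covariates use Pearson correlation.
#' Missing covariate values are dropped with a logged count; categories
#' with fewer than 2 observations are dropped with a warning.
#'
#' @param scores numeric marker expression per sample.
#' @param covariate same-length vector (factor/character = categorical,
#'   numeric = continuous).
#' @param name covariate label carried into the result.
#' @return An `association_result`: `covariate`, `test`, `statistic`,
#'   `p_value`, `group_sizes`.
#' @export
associate <- function(scores, covariate, name = "covariate") {
  ok <- !is.na(covariate) & is.finite(scores)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " observation(s) with missing values dropped for ", name)
  x <- scores[ok]; cv <- covariate[ok]
  if (!length(x)) stop("covariate '", name, "' has no usable observations")
  if (is.numeric(cv)) {
    if (length(x) < 3) stop("need at least 3 observations for correlation")
    res <- pearson_assoc(x, cv)
    return(structure(list(covariate = name, test = "pearson",
                          statistic = res$statistic, p_value = res$p_value,
                          group_sizes = length(x)),
                     class = "association_result"))
  }
  cv <- as.character(cv)
  sizes <- table(cv)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("category(ies) with < 2 observations dropped for ", name, ": ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(cv %in% small)
    x <- x[keep]; cv <- cv[keep]
    sizes <- table(cv)
  }
  if (length(sizes) < 2)
    stop("covariate '", name, "' has fewer than two usable categories")
  res <- if (length(sizes) == 2) {
    c(wilcoxon_ranksum(x, cv), test = "wilcoxon")
  } else {
    c(kruskal_wallis(x, cv), test = "kruskal_wallis")
  }
  structure(list(covariate = name, test = res$test,
                 statistic = res$statistic, p_value = res$p_value,
                 group_sizes = as.integer(sizes)),
            class = "association_result")
}

#' Association panel across all covariates of a clinical table
#'
#' Runs [associate()] for every covariate column (everything except
#' `sample_id`, `dfs_time`, `dfs_event`) and appends BH-adjusted p-values
#' across the panel; raw p-values are reported alongside.
#'
#' @param scores named numeric vector of marker expression (names = sample
#'   ids) or unnamed vector aligned with the clinical rows.
#' @param clinical clinical table.
#' @return Data frame: `covariate`, `test`, `statistic`, `p_value`, `fdr`.
#' @export
association_panel <- function(scores, clinical) {
  covars <- setdiff(names(clinical), c("sample_id", "dfs_time", "dfs_event"))
  if (!is.null(names(scores)))
    scores <- scores[match(clinical$sample_id, names(scores))]
  if (!length(covars))
    return(data.frame(covariate = character(0), test = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  rows <- lapply(covars, function(cv) {
    a <- suppressMessages(associate(scores, clinical[[cv]], name = cv))
    data.frame(covariate = a$covariate, test = a$test,
               statistic = a$statistic, p_value = a$p_value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}
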