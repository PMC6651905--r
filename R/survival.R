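#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod over event times t_j <= t of (1 - d_j / n_j)`,
#' where `n_j` counts subjects with observed time `>= t_j` (so censorings
#' tied with events are still at risk: events precede censorings at ties)
#' and `d_j` counts events at `t_j`.
#'
#' @param times non-negative observed times.
#' @param events 0 (censored) / 1 (event) indicators.
#' @return A `km_curve`: `event_times` (ascending distinct event times),
#'   `survival`, `at_risk`, `events`, `n`, plus the input `times`/`status`
#'   for risk tables.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0) {
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), events = integer(0),
                          n = length(times), times = times, status = events),
                     class = "km_curve"))
  }
  n_at_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  d <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  s <- cumprod(1 - d / n_at_risk)
  structure(list(event_times = et, survival = s,
                 at_risk = as.integer(n_at_risk), events = as.integer(d),
                 n = length(times), times = times, status = events),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @return `S(t)` (right-continuous step function, `S(t) = 1` before the
#'   first event).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    idx <- which(curve$event_times <= tt)
    if (!length(idx)) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation;
#' `U = sum(d1j - n1j * dj / nj)`,
#' `V = sum(n1j * n2j * dj * (nj - dj) / (nj^2 * (nj - 1)))`, and
#' `chi_square = U^2 / V` is referred to a chi-square with 1 df. No
#' continuity correction is applied.
#'
#' @param times,events as in [kaplan_meier()].
#' @param groups binary group labels (two levels).
#' @return A `logrank_result`: `chi_square`, `p_value`, `observed` and
#'   `expected` events per group, `U`, `V`.
#' @export
logrank <- function(times, events, groups) {
  if (length(unique(stats::na.omit(groups))) != 2)
    stop("groups must contain exactly two levels")
  g <- as.integer(factor(groups))  # 1/2
  if (any(tabulate(g, 2) == 0)) stop("a group has zero samples")
  if (sum(events) < 1) stop("no events observed")
  et <- sort(unique(times[events == 1]))
  nj <- vapply(et, function(t) sum(times >= t), numeric(1))
  n1j <- vapply(et, function(t) sum(times >= t & g == 1), numeric(1))
  dj <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  d1j <- vapply(et, function(t) sum(times == t & events == 1 & g == 1),
                numeric(1))
  e1j <- n1j * dj / nj
  keep <- nj > 1
  vj <- numeric(length(et))
  vj[keep] <- (n1j * (nj - n1j) * dj * (nj - dj) / (nj^2 * (nj - 1)))[keep]
  U <- sum(d1j - e1j)
  V <- sum(vj)
  if (V <= 0) stop("zero log-rank variance: no comparable events")
  chi <- U^2 / V
  structure(list(
    chi_square = chi,
    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    observed = c(group1 = sum(d1j), group2 = sum(dj - d1j)),
    expected = c(group1 = sum(e1j), group2 = sum(dj - e1j)),
    U = U, V = V
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi^2 = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Number-at-risk table
#'
#' The number at risk at time t counts samples with observed time `>= t`.
#'
#' @param curve a `km_curve`.
#' @param timepoints ascending times at which to report.
#' @return Data frame with `time` and `at_risk`.
#' @export
risk_table <- function(curve, timepoints) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.unsorted(timepoints)) stop("timepoints must be ascending")
  data.frame(
    time = timepoints,
    at_risk = vapply(timepoints, function(t) sum(curve$times >= t),
                     numeric(1))
  )
}

# Dichotomize one gene's expression with the valley -> mixture(ratio=1) ->
# median fallback chain; returns strata plus the method that succeeded.
dichotomize_gene <- function(scores, activity = FALSE) {
  thr <- tryCatch(
    threshold_estimate(
      find_valley(estimate_density(scores, activity = activity)),
      method = "valley"),
    error = function(e) NULL)
  if (is.null(thr)) {
    thr <- tryCatch(
      mixture_ratio_threshold(fit_mixture_1d(scores), ratio = 1),
      error = function(e) NULL)
  }
  if (is.null(thr)) {
    thr <- threshold_estimate(stats::median(scores, na.rm = TRUE),
                              method = "median")
  }
  classify(scores, thr)
}

#' Per-gene survival screen
#'
#' Each gene is dichotomized (density-valley threshold; if the density is
#' unimodal, the equal-ratio Gaussian-mixture crossing; if that fails too,
#' a median split — the method used is recorded per gene) and the two
#' strata compared by log-rank. A gene whose dichotomy leaves one stratum
#' empty is flagged not assessable.
#'
#' @param expression an [expression_matrix()].
#' @param clinical clinical table with `sample_id`, `dfs_time`, `dfs_event`.
#' @param genes feature ids to screen.
#' @return Data frame: `gene`, `p_value`, `chi_square`, `n_high`, `n_low`,
#'   `method`, `assessable`.
#' @export
per_gene_survival_screen <- function(expression, clinical, genes) {
  stopifnot(inherits(expression, "expression_matrix"))
  absent <- setdiff(genes, expression$feature_ids)
  if (length(absent))
    stop("gene(s) absent from the matrix: ", paste(absent, collapse = ", "))
  common <- intersect(expression$sample_ids, clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  ok <- !is.na(cl$dfs_time) & !is.na(cl$dfs_event)
  cl <- cl[ok, ]
  rows <- lapply(genes, function(gene) {
    scores <- expression$values[gene, cl$sample_id]
    res <- tryCatch({
      strata <- suppressMessages(dichotomize_gene(scores))
      lab <- strata$labels[cl$sample_id]
      if (length(unique(lab)) < 2) stop("degenerate dichotomy")
      lr <- logrank(cl$dfs_time, cl$dfs_event, lab)
      data.frame(gene = gene, p_value = lr$p_value,
                 chi_square = lr$chi_square,
                 n_high = sum(lab == "high"), n_low = sum(lab == "low"),
                 method = strata$threshold$method, assessable = TRUE)
    }, error = function(e) {
      data.frame(gene = gene, p_value = NA_real_, chi_square = NA_real_,
                 n_high = NA_integer_, n_low = NA_integer_,
                 method = NA_character_, assessable = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Flag genes significant in at least k cohorts
#'
#' @param screens named list of per-cohort screen tables from
#'   [per_gene_survival_screen()].
#' @param level significance level (default 0.05).
#' @param min_cohorts minimum number of cohorts with `p < level`.
#' @return Data frame: `gene`, one p-value column per cohort,
#'   `n_significant`, `significant`.
#' @export
flag_significant <- function(screens, level = 0.05, min_cohorts = 2) {
  genes <- Reduce(intersect, lapply(screens, `[[`, "gene"))
  pm <- sapply(screens, function(s) s$p_value[match(genes, s$gene)])
  pm <- matrix(pm, nrow = length(genes),
               dimnames = list(genes, names(screens)))
  nsig <- rowSums(pm < level, na.rm = TRUE)
  out <- data.frame(gene = genes, pm, n_significant = nsig,
                    significant = nsig >= min_cohorts,
                    check.names = FALSE, row.names = NULL)
  out[order(-out$n_significant, out$gene), ]
}
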