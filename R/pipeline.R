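#' Summarize stratification counts across cohorts
#'
#' Per-cohort and pooled high/low counts with the percentage of high
#' samples, rounded to one decimal in the report (full precision is a
#' plain ratio the caller can recompute).
#'
#' @param strata named list; each element either a `sample_strata` from
#'   [classify()] or a numeric vector `c(high = ..., low = ...)`.
#' @param total_label label for the pooled row.
#' @return Data frame: `cohort`, `high`, `low`, `total`, `percent_high`.
#' @export
summarize_stratification <- function(strata, total_label = "Total") {
  counts <- lapply(strata, function(s) {
    if (inherits(s, "sample_strata")) {
      c(high = sum(s$labels == "high"), low = sum(s$labels == "low"))
    } else {
      if (!all(c("high", "low") %in% names(s)))
        stop("count entries need named elements 'high' and 'low'")
      c(high = s[["high"]], low = s[["low"]])
    }
  })
  high <- vapply(counts, `[[`, numeric(1), "high")
  low <- vapply(counts, `[[`, numeric(1), "low")
  df <- data.frame(cohort = names(strata), high = high, low = low,
                   total = high + low, row.names = NULL)
  df <- rbind(df, data.frame(cohort = total_label, high = sum(high),
                             low = sum(low), total = sum(high + low)))
  df$percent_high <- round(100 * df$high / df$total, 1)
  df
}

#' Build a pipeline configuration
#'
#' @param cohorts list of cohort entries, each a list with `alias`,
#'   `expression` (path), `clinical` (path), `value_kind`.
#' @param marker marker gene/probe id.
#' @param primary_probe optional fixed primary probe id.
#' @param partners optional path to a gene-set file of interaction partners.
#' @param threshold_method `"pooled_valley"`, `"valley"`, `"mixture"` or
#'   `"fixed"`.
#' @param threshold_override fixed cut-point (required for `"fixed"`).
#' @param mixture_ratio density ratio for the mixture method.
#' @param k top-list size.
#' @param level significance level for the screen.
#' @param min_cohorts cohorts required for screen significance.
#' @param seed integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts, marker, primary_probe = NULL,
                            partners = NULL,
                            threshold_method = "pooled_valley",
                            threshold_override = NULL, mixture_ratio = 1,
                            k = 20, level = 0.05, min_cohorts = 2,
                            seed = 1L) {
  if (length(cohorts) < 1) stop("need at least one cohort")
  if (k < 1) stop("k must be >= 1")
  if (!(level > 0 && level < 1)) stop("level must lie in (0,1)")
  structure(list(cohorts = cohorts, marker = marker,
                 primary_probe = primary_probe, partners = partners,
                 threshold_method = threshold_method,
                 threshold_override = threshold_override,
                 mixture_ratio = mixture_ratio, k = k, level = level,
                 min_cohorts = min_cohorts, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(pipeline_config, c(
    list(cohorts = j$cohorts, marker = j$marker),
    j[setdiff(names(j), c("cohorts", "marker"))]))
}

#' Run the full analysis
#'
#' Loads every cohort, derives the marker threshold (pooled density valley
#' by default, with mixture or fixed alternatives), stratifies samples,
#' compares disease-free survival between strata per cohort (Kaplan-Meier +
#' log-rank + risk table), builds the pooled stratification summary, the
#' marker correlation tables with cross-cohort max-rank aggregation, the
#' per-gene survival screen over the selected genes, signed-p matrices, and
#' the clinicopathological association panel. Every fallback decision is
#' recorded in the run manifest.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional directory; when given, report tables, per-cohort
#'   outputs and the manifest are written there.
#' @return A list report bundle (see components in the description).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  manifest <- c(sprintf("seed\t%d", config$seed),
                sprintf("threshold_method\t%s", config$threshold_method))
  log_line <- function(...) manifest <<- c(manifest, sprintf(...))

  load_one <- function(entry) {
    if (!is.null(entry$cohort)) return(entry$cohort)  # in-memory cohort
    expr <- read_expression(entry$expression,
                            value_kind = entry$value_kind %||% "mixed")
    clin <- read_clinical(entry$clinical)
    list(expression = expr, clinical = clin)
  }
  aliases <- vapply(config$cohorts, function(e) e$alias %||% "cohort",
                    character(1))
  cohorts <- lapply(config$cohorts, load_one)
  names(cohorts) <- aliases

  stage <- function(what, alias, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for cohort '%s': %s",
                   what, alias, conditionMessage(e)), call. = FALSE))
  }

  harmonized <- lapply(aliases, function(a) {
    h <- stage("harmonize", a, suppressMessages(
      harmonize_cohort(cohorts[[a]]$expression, cohorts[[a]]$clinical)))
    if (h$n_dropped > 0)
      log_line("dropped_no_survival\t%s\t%d", a, h$n_dropped)
    h
  })
  names(harmonized) <- aliases

  marker_id <- vapply(aliases, function(a) {
    suppressMessages(select_marker_probe(
      cohorts[[a]]$expression,
      candidates = config$marker,
      primary = config$primary_probe))
  }, character(1))

  marker_scores <- lapply(aliases, function(a)
    cohorts[[a]]$expression$values[marker_id[[a]], ])
  names(marker_scores) <- aliases

  # --- threshold -----------------------------------------------------------
  threshold <- switch(
    config$threshold_method,
    fixed = threshold_estimate(config$threshold_override, method = "fixed"),
    pooled_valley = ,
    valley = tryCatch(
      pooled_valley_threshold(marker_scores, activity = TRUE),
      error = function(e) {
        log_line("threshold_fallback\tmixture\t%s", conditionMessage(e))
        fit <- fit_mixture_1d(unlist(marker_scores))
        mixture_ratio_threshold(fit, ratio = config$mixture_ratio)
      }),
    mixture = {
      fit <- fit_mixture_1d(unlist(marker_scores))
      mixture_ratio_threshold(fit, ratio = config$mixture_ratio)
    },
    stop("unknown threshold_method: ", config$threshold_method))
  log_line("threshold\t%g\t%s", threshold$value, threshold$method)

  # --- per-cohort strata + survival ---------------------------------------
  per_cohort <- lapply(aliases, function(a) {
    h <- harmonized[[a]]
    strata <- stage("classify", a, suppressMessages(
      classify(h$expression$values[marker_id[[a]],
                                   h$clinical$sample_id], threshold)))
    lab <- strata$labels[h$clinical$sample_id]
    km_high <- kaplan_meier(h$clinical$dfs_time[lab == "high"],
                            h$clinical$dfs_event[lab == "high"])
    km_low <- kaplan_meier(h$clinical$dfs_time[lab == "low"],
                           h$clinical$dfs_event[lab == "low"])
    lr <- stage("logrank", a,
                logrank(h$clinical$dfs_time, h$clinical$dfs_event, lab))
    tp <- pretty(c(0, max(h$clinical$dfs_time)))
    list(strata = strata, km = list(high = km_high, low = km_low),
         logrank = lr,
         risk = list(high = risk_table(km_high, tp),
                     low = risk_table(km_low, tp)))
  })
  names(per_cohort) <- aliases

  stratification <- summarize_stratification(
    lapply(per_cohort, `[[`, "strata"))

  # --- co-expression -------------------------------------------------------
  corr_tables <- lapply(aliases, function(a) {
    genes <- setdiff(cohorts[[a]]$expression$feature_ids, marker_id[[a]])
    stage("correlation", a, marker_correlation_table(
      cohorts[[a]]$expression, marker_id[[a]], genes))
  })
  names(corr_tables) <- aliases
  shared <- Reduce(intersect, lapply(corr_tables, `[[`, "gene"))
  k_eff <- min(config$k, length(shared))
  if (k_eff < config$k)
    log_line("k_capped\t%d\t%d", config$k, k_eff)
  aggregation <- aggregate_max_rank(corr_tables, k = k_eff)

  partners_agg <- NULL
  if (!is.null(config$partners)) {
    pset <- if (inherits(config$partners, "gene_set")) config$partners
            else read_geneset(config$partners)
    partners_agg <- tryCatch(
      top_partners(corr_tables, pset, k = config$k),
      error = function(e) {
        log_line("partners_skipped\t%s", conditionMessage(e))
        NULL
      })
  }

  top_genes <- aggregation$selection
  correlation <- data.frame(gene = top_genes)
  for (a in aliases) {
    tab <- corr_tables[[a]]
    idx <- match(top_genes, tab$gene)
    correlation[[paste0("r_s.", a)]] <- tab$r_s[idx]
    correlation[[paste0("fdr.", a)]] <- tab$fdr[idx]
  }
  correlation$max_rank <- aggregation$max_rank[top_genes]

  # --- per-gene survival screen over the top genes ------------------------
  screens <- lapply(aliases, function(a) {
    h <- harmonized[[a]]
    stage("screen", a, per_gene_survival_screen(
      h$expression, h$clinical, c(marker_id[[a]], top_genes)))
  })
  names(screens) <- aliases
  screen <- flag_significant(screens, level = config$level,
                             min_cohorts = config$min_cohorts)

  signed_p <- lapply(aliases, function(a)
    stage("signed_p", a, signed_p_matrix(
      cohorts[[a]]$expression, c(marker_id[[a]], top_genes))))
  names(signed_p) <- aliases

  associations <- lapply(aliases, function(a) {
    h <- harmonized[[a]]
    stage("association", a, suppressWarnings(association_panel(
      h$expression$values[marker_id[[a]], h$clinical$sample_id],
      h$clinical)))
  })
  names(associations) <- aliases

  bundle <- list(threshold = threshold, per_cohort = per_cohort,
                 stratification = stratification,
                 correlation_tables = corr_tables,
                 correlation = correlation, aggregation = aggregation,
                 partners = partners_agg, screens = screens,
                 screen = screen, signed_p = signed_p,
                 associations = associations, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tables(bundle, out_dir)
    for (a in aliases) {
      st <- per_cohort[[a]]$strata
      utils::write.table(
        data.frame(sample_id = names(st$labels), stratum = st$labels),
        file.path(out_dir, paste0(a, "_strata.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      lr <- per_cohort[[a]]$logrank
      utils::write.table(
        data.frame(cohort = a, chi_square = lr$chi_square,
                   p_value = lr$p_value),
        file.path(out_dir, paste0(a, "_logrank.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
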