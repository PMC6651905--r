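# Shared fixtures and independent brute-force oracles.

make_expr <- function(values, kind = "mixed") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expression_matrix(values, value_kind = kind)
}

small_cohort <- function(seed = 1, n = 120, ...) {
  generate_cohort(cohort_config(n_samples = n, n_genes = 30,
                                module_genes = 10, seed = seed, ...))
}

# Brute-force product-limit oracle: explicit loop over event times.
km_oracle <- function(times, events, t) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  for (tj in et[et <= t]) {
    n_at_risk <- sum(times >= tj)
    d <- sum(times == tj & events == 1)
    s <- s * (1 - d / n_at_risk)
  }
  s
}

# Label-permutation oracle for the log-rank chi-square.
logrank_perm_p <- function(times, events, groups, B = 20000) {
  obs <- logrank(times, events, groups)$chi_square
  chis <- replicate(B, {
    tryCatch(logrank(times, events, sample(groups))$chi_square,
             error = function(e) NA_real_)
  })
  chis <- chis[!is.na(chis)]
  list(p = mean(chis >= obs - 1e-12), n = length(chis))
}

# Literal step-up BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

# Exhaustive max-rank aggregation oracle over correlation tables.
max_rank_oracle <- function(tables, k) {
  genes <- sort(Reduce(intersect, lapply(tables, function(t) t$gene)))
  best <- data.frame(gene = genes, max_rank = NA_real_)
  for (gi in seq_along(genes)) {
    worst <- 0
    for (tab in tables) {
      tab <- tab[tab$gene %in% genes, ]
      # competition rank: 1 + number of genes strictly better, where
      # "better" is larger r_s or equal r_s with smaller gene id
      r_g <- tab$r_s[tab$gene == genes[gi]]
      better <- sum(tab$r_s > r_g |
                      (tab$r_s == r_g & tab$gene < genes[gi]))
      worst <- max(worst, better + 1)
    }
    best$max_rank[gi] <- worst
  }
  best <- best[order(best$max_rank, best$gene), ]
  best$gene[seq_len(k)]
}

random_corr_table <- function(genes, seed) {
  set.seed(seed)
  data.frame(gene = genes,
             r_s = round(runif(length(genes), -1, 1), 2),  # rounded => ties
             p_value = runif(length(genes)),
             stringsAsFactors = FALSE)
}
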