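test_that("spearman handles monotone, tied and degenerate inputs", {
  expect_equal(spearman(1:10, (1:10)^2)$r_s, 1)
  expect_equal(spearman(1:10, -(1:10))$r_s, -1)

  # tied data vs brute-force average-rank Pearson
  set.seed(1)
  for (i in 1:5) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(1:4, 30, replace = TRUE) + 0.1 * x
    expect_equal(spearman(x, y)$r_s, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }

  expect_error(spearman(1:2, 2:3), "at least 3")
  expect_error(spearman(rep(1, 10), 1:10), "constant")
})

test_that("spearman p-values match stats::cor.test", {
  # exact enumeration regime (n <= 8, no ties)
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    sp <- spearman(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(sp$p_value, ct$p.value, tolerance = 1e-12)
    expect_equal(sp$r_s, unname(ct$estimate), tolerance = 1e-12)
  }
  # t-approximation regime
  set.seed(3)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  sp <- spearman(x, y)
  n <- 50; r <- sp$r_s
  expect_equal(sp$p_value,
               2 * pt(abs(r * sqrt((n - 2) / (1 - r^2))), n - 2,
                      lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("bh_fdr equals the step-up oracle and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(4)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  # NA passthrough keeps positions
  p <- c(0.01, NA, 0.5)
  expect_true(is.na(bh_fdr(p)[2]))
  expect_equal(bh_fdr(p)[-2], p.adjust(p, "BH")[!is.na(p)])
})

test_that("marker_correlation_table wires spearman + BH together", {
  co <- small_cohort(seed = 5, n = 200)
  genes <- setdiff(co$expression$feature_ids, "MARKER")
  tab <- marker_correlation_table(co$expression, "MARKER", genes)
  expect_identical(nrow(tab), length(genes))
  i <- which(tab$gene == "MOD001")
  sp <- spearman(co$expression$values["MARKER", ],
                 co$expression$values["MOD001", ])
  expect_equal(tab$r_s[i], sp$r_s)
  expect_equal(tab$fdr, bh_fdr(tab$p_value))
  expect_error(marker_correlation_table(co$expression, "nope", genes),
               "marker")
})

test_that("signed_p_matrix satisfies the formula, symmetry and diagonal", {
  co <- small_cohort(seed = 6, n = 60)
  genes <- c("MARKER", sprintf("MOD%03d", 1:4), "BG0001")
  s <- signed_p_matrix(co$expression, genes)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, length(genes)))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      sp <- spearman(co$expression$values[genes[i], ],
                     co$expression$values[genes[j], ])
      expect_equal(s[i, j], sign(sp$r_s) * (1 - sp$p_value))
    }
  }
  expect_true(all(abs(s) <= 1))

  # constant row yields 0 with a warning
  vals <- co$expression$values[genes, ]
  vals["BG0001", ] <- 3
  m <- make_expr(vals)
  expect_warning(signed_p_matrix(m, c("MARKER", "BG0001")), "constant")
  s2 <- suppressWarnings(signed_p_matrix(m, genes))
  expect_equal(unname(s2["BG0001", "MARKER"]), 0)
})

test_that("max-rank aggregation follows max semantics", {
  genes <- sprintf("g%02d", 1:60)
  # one cohort: selection is the top-k by r_s directly
  tab <- random_corr_table(genes, seed = 7)
  agg <- aggregate_max_rank(list(tab), k = 10)
  expect_identical(agg$selection,
                   tab$gene[order(-tab$r_s, tab$gene)][1:10])
  expect_identical(sort(unname(agg$per_cohort_ranks[, 1])), 1:60)

  # gene ranked 1,1,50 loses to one ranked 10 everywhere
  mk_tab <- function(rank_a, rank_b) {
    r <- rep(0, 60); r[1] <- 1 - rank_a / 100; r[2] <- 1 - rank_b / 100
    other <- setdiff(seq_len(60), 1:2)
    r[other] <- seq(0.5, 0.01, length.out = 58)
    # force ranks: gene g01 at rank_a, g02 at rank_b
    rr <- rep(NA_real_, 60)
    pool <- seq(1, 0.01, length.out = 60)
    rr[1] <- pool[rank_a]; rr[2] <- pool[rank_b]
    rr[other] <- pool[-c(rank_a, rank_b)]
    data.frame(gene = genes, r_s = rr, p_value = 0.5)
  }
  tabs <- list(mk_tab(1, 10), mk_tab(1, 10), mk_tab(50, 10))
  agg2 <- aggregate_max_rank(tabs, k = 60)
  expect_equal(unname(agg2$max_rank["g01"]), 50)
  expect_equal(unname(agg2$max_rank["g02"]), 10)
  expect_lt(which(agg2$selection == "g02"), which(agg2$selection == "g01"))
})

test_that("aggregation equals the brute-force oracle, any cohort order", {
  genes <- sprintf("g%02d", 1:40)
  for (seed in 1:4) {
    tabs <- lapply(seed * 10 + 1:3, random_corr_table, genes = genes)
    agg <- aggregate_max_rank(tabs, k = 15)
    expect_identical(agg$selection, max_rank_oracle(tabs, 15))
    perm <- aggregate_max_rank(rev(tabs), k = 15)
    expect_identical(perm$selection, agg$selection)
    expect_identical(perm$max_rank, agg$max_rank)
  }
  expect_error(aggregate_max_rank(list(), 5), "at least one")
  expect_error(aggregate_max_rank(list(random_corr_table(genes, 1)), 99),
               "exceeds")
})

test_that("top_partners restricts aggregation to the partner set", {
  genes <- sprintf("g%02d", 1:30)
  tabs <- lapply(1:2, random_corr_table, genes = genes)
  pset <- structure(list(name = "p", members = genes[1:5]),
                    class = "gene_set")
  agg <- top_partners(tabs, pset, k = 5)
  expect_setequal(agg$selection, genes[1:5])      # whole set, ordered
  expect_identical(agg$selection,
                   max_rank_oracle(lapply(tabs, function(t)
                     t[t$gene %in% genes[1:5], ]), 5))
  expect_error(top_partners(tabs, c("zz1", "zz2")), "intersect")
})

test_that("partners correlate only in stem-like cohorts by construction", {
  mk <- function(rho, seed) generate_cohort(
    cohort_config(n_samples = 120, n_genes = 30, module_genes = 10,
                  module_rho = rho, seed = seed))
  stem <- lapply(1:2, function(i) mk(0.6, 20 + i))
  colon <- lapply(1:2, function(i) mk(0.0, 30 + i))
  partners <- sprintf("MOD%03d", 1:10)
  tabs <- lapply(c(stem, colon), function(co)
    marker_correlation_table(co$expression, "MARKER", partners))
  sel <- top_partners(tabs[1:2], partners, k = 5)$selection
  mean_r <- function(tab) mean(tab$r_s[tab$gene %in% sel])
  expect_gt(min(vapply(tabs[1:2], mean_r, numeric(1))),
            max(vapply(tabs[3:4], mean_r, numeric(1))))
})

test_that("module correlations at rho = 0.45, n = 557 land in [0.3, 0.6]", {
  ok <- vapply(1:20, function(seed) {
    co <- generate_cohort(cohort_config(n_samples = 557, n_genes = 5,
                                        module_genes = 5, module_rho = 0.45,
                                        seed = 40 + seed))
    rs <- vapply(sprintf("MOD%03d", 1:5), function(g)
      spearman(co$expression$values["MARKER", ],
               co$expression$values[g, ])$r_s, numeric(1))
    all(rs >= 0.3 & rs <= 0.6)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
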