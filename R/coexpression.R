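# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with p-value
#'
#' Tie-corrected Spearman computed as the Pearson correlation of average
#' ranks. For n <= 8 without ties the two-sided p-value is exact (full
#' enumeration of the permutation null); otherwise it comes from the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors with at least 3 finite pairs.
#' @return List with `r_s`, `p_value`, `n_pairs`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance: a variable is constant")
  r <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !has_ties) {
    perms <- all_permutations(n)
    # Pearson of ranks reduces to a monotone function of sum(rx * ry[perm])
    obs <- sum(rx * ry)
    null_s <- perms %*% seq_len(n)  # sum of i * perm(i) over all pairings
    center <- n * (n + 1)^2 / 4
    p <- mean(abs(null_s - center) >= abs(obs - center) - 1e-12)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(r_s = r, p_value = min(p, 1), n_pairs = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p_values numeric vector in \[0,1\] (`NA` passed through).
#' @return Adjusted values in the original order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m == 0) return(out)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[ord]))[order(ord)]
  out[ok] <- adj
  out
}

#' Marker-centric correlation table
#'
#' Spearman correlation of each gene with the marker, with BH-adjusted
#' p-values across the tested genes. Correlations belong on continuous
#' intensities, not \[0,1\] activity scores.
#'
#' @param expression an [expression_matrix()].
#' @param marker marker feature id.
#' @param genes feature ids to correlate (marker excluded automatically).
#' @return Data frame: `gene`, `r_s`, `p_value`, `fdr`, `n_pairs`.
#' @export
marker_correlation_table <- function(expression, marker, genes) {
  stopifnot(inherits(expression, "expression_matrix"))
  if (!marker %in% expression$feature_ids) stop("marker not in matrix")
  genes <- setdiff(intersect(genes, expression$feature_ids), marker)
  if (!length(genes)) stop("no genes to correlate")
  mk <- expression$values[marker, ]
  rows <- lapply(genes, function(gene) {
    sp <- spearman(mk, expression$values[gene, ])
    data.frame(gene = gene, r_s = sp$r_s, p_value = sp$p_value,
               n_pairs = sp$n_pairs)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p_value)
  tab[, c("gene", "r_s", "p_value", "fdr", "n_pairs")]
}

#' Signed-p co-expression matrix
#'
#' Pairwise statistic `s = sign(r_s) * (1 - p)`, the heatmap rendering of a
#' correlation's strength of evidence with its direction. Diagonal entries
#' are +1 (r = 1, p -> 0). A constant gene row yields 0 entries with a
#' warning.
#'
#' @param expression an [expression_matrix()].
#' @param genes feature ids.
#' @return Symmetric numeric matrix with `genes` dimnames.
#' @export
signed_p_matrix <- function(expression, genes) {
  stopifnot(inherits(expression, "expression_matrix"))
  absent <- setdiff(genes, expression$feature_ids)
  if (length(absent))
    stop("gene(s) absent: ", paste(absent, collapse = ", "))
  g <- length(genes)
  s <- diag(1, g)
  dimnames(s) <- list(genes, genes)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (j <= i) next
      val <- tryCatch({
        sp <- spearman(expression$values[genes[i], ],
                       expression$values[genes[j], ])
        sign(sp$r_s) * (1 - sp$p_value)
      }, error = function(e) {
        warning("constant gene row: ", genes[i], " or ", genes[j],
                "; entry set to 0", call. = FALSE)
        0
      })
      s[i, j] <- s[j, i] <- val
    }
  }
  s
}

#' Cross-cohort maximum-rank aggregation
#'
#' Within each cohort genes are ranked in descending order of their
#' correlation with the marker (rank 1 = strongest positive r_s); equal
#' correlations get competition ranks broken lexicographically by gene id
#' so each cohort's ranks are a permutation of 1..G. Each gene's statistic
#' is its worst (maximum) rank over cohorts; the selection is the first `k`
#' genes after sorting ascending by that maximum (gene id breaks ties).
#'
#' @param per_cohort_tables list of correlation tables from
#'   [marker_correlation_table()] (at least one); genes are intersected
#'   across cohorts.
#' @param k number of genes to select.
#' @return A `rank_aggregation`: `per_cohort_ranks` (genes x cohorts
#'   matrix), `max_rank` (named vector), `selection` (ordered top-k ids).
#' @export
aggregate_max_rank <- function(per_cohort_tables, k) {
  if (length(per_cohort_tables) == 0) stop("need at least one cohort table")
  genes <- sort(Reduce(intersect, lapply(per_cohort_tables, `[[`, "gene")))
  if (!length(genes)) stop("empty gene intersection across cohorts")
  if (k > length(genes))
    stop("k (", k, ") exceeds the gene intersection (", length(genes), ")")
  ranks <- sapply(per_cohort_tables, function(tab) {
    r <- tab$r_s[match(genes, tab$gene)]
    ord <- order(-r, genes)          # descending r_s, gene id tie-break
    rk <- integer(length(genes))
    rk[ord] <- seq_along(genes)      # competition-style permutation ranks
    rk
  })
  ranks <- matrix(ranks, nrow = length(genes),
                  dimnames = list(genes, names(per_cohort_tables)))
  max_rank <- apply(ranks, 1, max)
  sel_order <- order(max_rank, genes)
  structure(list(per_cohort_ranks = ranks,
                 max_rank = max_rank,
                 selection = genes[sel_order][seq_len(k)]),
            class = "rank_aggregation")
}

#' Top co-expressed interaction partners
#'
#' [aggregate_max_rank()] restricted to an externally determined partner
#' gene set; `k` defaults to 20 and is capped at the number of partners
#' present in every cohort.
#'
#' @param per_cohort_tables list of correlation tables.
#' @param partner_set a `gene_set` from [read_geneset()] (or a character
#'   vector of gene ids).
#' @param k selection size.
#' @return A `rank_aggregation` over the partner set.
#' @export
top_partners <- function(per_cohort_tables, partner_set, k = 20) {
  members <- if (inherits(partner_set, "gene_set")) partner_set$members
             else as.character(partner_set)
  restricted <- lapply(per_cohort_tables, function(tab)
    tab[tab$gene %in% members, , drop = FALSE])
  common <- Reduce(intersect, lapply(restricted, `[[`, "gene"))
  if (!length(common))
    stop("partner set does not intersect the expression features")
  aggregate_max_rank(restricted, k = min(k, length(common)))
}
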