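# Hierarchical cluster analysis of freezing-positive (s_ppn, s_cnf)
# pairs, cluster-count selection by the agglomeration-coefficient
# stopping rule, and nonparametric cluster comparisons.

#' Ward-linkage hierarchical clustering with agglomeration coefficients
#'
#' Agglomerative clustering of 2-D points with Euclidean distance and
#' Ward's linkage. The agglomeration coefficient for k clusters is the
#' linkage height of the merge that forms the k-cluster partition;
#' the percent change of the coefficient between successive cluster
#' counts feeds the stopping rule of [choose_k()].
#'
#' @param points Matrix or data frame of points (rows), typically columns
#'   (s_ppn, s_cnf).
#' @param k_max Largest cluster count profiled (default 10, capped at
#'   n - 1).
#' @return List of class `fogsim_hca`: `hclust` (the tree),
#'   `coefficients` (data.frame k, coefficient, pct_change), `points`.
#' @export
hca <- function(points, k_max = 10) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  stopifnot(n >= 2)
  hc <- stats::hclust(stats::dist(pts), method = "ward.D2")
  heights <- hc$height               # nondecreasing, length n - 1
  k_max <- min(k_max, n - 1)
  ks <- seq_len(k_max)
  coef <- heights[n - ks]            # height of the merge forming k clusters
  pct <- c(NA, ifelse(coef[-1] > 0,
                      100 * (coef[-length(coef)] - coef[-1]) / coef[-1],
                      NA))
  structure(list(hclust = hc,
                 coefficients = data.frame(k = ks, coefficient = coef,
                                           pct_change = pct),
                 points = pts),
            class = "fogsim_hca")
}

#' @export
print.fogsim_hca <- function(x, ...) {
  cat(sprintf("fogsim HCA: %d points, Ward linkage\n", nrow(x$points)))
  print(utils::head(x$coefficients, 8), row.names = FALSE)
  invisible(x)
}

#' Cluster assignments at a given count
#'
#' @param h A `fogsim_hca`.
#' @param k Cluster count.
#' @return Integer vector of assignments.
#' @export
cluster_assignments <- function(h, k) as.integer(stats::cutree(h$hclust, k))

#' Choose the cluster count by the agglomeration-coefficient rule
#'
#' Picks the count at the largest percent increase of the coefficient
#' decrease, provided the following changes plateau (each below
#' `plateau_frac` of the spike). A profile with no change reaching
#' `min_spike` percent is featureless: k = 1 with a warning.
#'
#' @param coefficients The `coefficients` data.frame of a `fogsim_hca`
#'   (columns k, coefficient, pct_change), or a `fogsim_hca`.
#' @param min_spike Smallest percent change that counts as a spike.
#' @param plateau_frac Subsequent changes must stay below this fraction
#'   of the spike.
#' @return Integer k.
#' @export
choose_k <- function(coefficients, min_spike = 20, plateau_frac = 0.7) {
  if (inherits(coefficients, "fogsim_hca"))
    coefficients <- coefficients$coefficients
  pc <- coefficients$pct_change
  ks <- coefficients$k
  cand <- which(!is.na(pc) & pc >= min_spike)
  if (!length(cand)) {
    warning("choose_k: featureless coefficient profile; returning k = 1")
    return(1L)
  }
  for (i in cand[order(pc[cand], decreasing = TRUE)]) {
    later <- pc[seq_along(pc) > i & !is.na(pc)]
    if (!length(later) || all(later < plateau_frac * pc[i]))
      return(as.integer(ks[i]))
  }
  # spikes exist but none followed by a plateau: take the largest spike
  as.integer(ks[cand[which.max(pc[cand])]])
}

#' Nonparametric comparison of variables across clusters
#'
#' For each variable: Shapiro-Wilk normality per cluster and Levene's
#' test of variance equality decide the path. When both hold, one-way
#' analysis of variance with pairwise t-tests; otherwise the
#' Kruskal-Wallis test with pairwise Mann-Whitney U tests. Pairwise
#' p-values are Bonferroni-adjusted (min(1, p x number of comparisons)).
#' Clusters of size 1 are excluded from the pairwise tests with a
#' warning.
#'
#' @param data Data frame containing the variables.
#' @param assignments Cluster labels (length nrow(data)).
#' @param variables Character vector of column names to compare.
#' @param alpha Significance level for the assumption gates.
#' @param force Override the path: NULL (auto), "parametric" or
#'   "nonparametric".
#' @return List of class `fogsim_stats`, one element per variable:
#'   `parametric`, `shapiro_p` (per cluster), `levene_p`, `omnibus_p`,
#'   `omnibus_method`, `pairwise` (data.frame cluster_a, cluster_b,
#'   p_raw, p_adjusted).
#' @export
compare_clusters <- function(data, assignments, variables,
                             alpha = 0.05, force = NULL) {
  assignments <- as.factor(assignments)
  stopifnot(length(assignments) == nrow(data), nlevels(assignments) >= 2)
  sizes <- table(assignments)
  if (any(sizes == 1))
    warning("compare_clusters: singleton cluster(s) excluded from ",
            "pairwise tests")
  out <- lapply(variables, function(v) {
    x <- data[[v]]
    groups <- split(x, assignments)
    shapiro_p <- vapply(groups, function(g) {
      if (length(g) < 3 || stats::sd(g) == 0) return(NA_real_)
      stats::shapiro.test(g)$p.value
    }, numeric(1))
    levene_p <- tryCatch(
      car::leveneTest(x ~ assignments)[1, "Pr(>F)"],
      error = function(e) NA_real_)
    parametric <- if (!is.null(force)) force == "parametric"
      else all(shapiro_p > alpha, na.rm = TRUE) &&
        isTRUE(levene_p > alpha) && !all(is.na(shapiro_p))
    if (parametric) {
      om <- summary(stats::aov(x ~ assignments))[[1]]
      omnibus_p <- om[1, "Pr(>F)"]
      omnibus_method <- "one-way ANOVA"
    } else {
      omnibus_p <- stats::kruskal.test(x, assignments)$p.value
      omnibus_method <- "Kruskal-Wallis"
    }
    keep <- names(sizes)[sizes >= 2]
    pairs <- utils::combn(keep, 2, simplify = FALSE)
    m <- length(pairs)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
      p <- if (parametric) stats::t.test(a, b)$p.value
           else stats::wilcox.test(a, b, exact = FALSE)$p.value
      data.frame(cluster_a = pr[1], cluster_b = pr[2], p_raw = p)
    }))
    pw$p_adjusted <- pmin(1, pw$p_raw * m)
    list(variable = v, parametric = parametric, shapiro_p = shapiro_p,
         levene_p = levene_p, omnibus_method = omnibus_method,
         omnibus_p = omnibus_p, pairwise = pw)
  })
  names(out) <- variables
  class(out) <- "fogsim_stats"
  out
}

#' @export
print.fogsim_stats <- function(x, ...) {
  for (v in x) {
    cat(sprintf("%s: %s omnibus p = %.3g (%s path)\n", v$variable,
                v$omnibus_method, v$omnibus_p,
                if (v$parametric) "parametric" else "nonparametric"))
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same points;
#' 1 for identical partitions (up to label names), ~0 for independent
#' ones. Used to score recovery of planted clusters.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
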