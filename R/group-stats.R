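#' One-way independent-design ANOVA
#'
#' Classical between/within F for k independent groups (equal variances
#' assumed), with `df = (k - 1, sum(n) - k)`. With the study's group sizes —
#' 30 blank controls plus 29 thermal-stimulation subjects at each of four
#' temperatures — this yields the df pattern (4, 141). Computed via
#' [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups a named list of numeric vectors, one per group, each with
#'   at least 2 observations.
#' @return An object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_ns`. Zero within-group variance everywhere
#'   gives `F = NA` with a warning.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  stopifnot(all(is.finite(values)))
  g <- factor(rep(seq_along(groups), ns))
  k <- length(groups)
  df_b <- k - 1L
  df_w <- length(values) - k
  res <- structure(list(F = NA_real_, df_between = df_b, df_within = df_w,
                        p = NA_real_, group_ns = as.integer(ns)),
                   class = "anova_result")
  if (all(vapply(groups, function(x) stats::var(x) == 0, logical(1)))) {
    warning("zero within-group variance in every group: F undefined")
    return(res)
  }
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  res$F <- unname(ow$statistic)
  res$p <- unname(ow$p.value)
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %s, p = %s  (n = %s)\n",
              x$df_between, x$df_within, format(x$F, digits = 4),
              format(x$p, digits = 4), paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' Two-sided permutation test for a difference in group means
#'
#' The observed statistic is `mean(a) - mean(b)`. Group labels of the
#' pooled sample are reshuffled `n_perm` times with the seeded generator
#' and the two-sided p-value uses the add-one correction
#' `p = (1 + #\{|perm| >= |obs|\}) / (1 + n_perm)`. When the pooled sample
#' has at most 10 observations all distinct label assignments are
#' enumerated instead and p is the exact proportion.
#'
#' @param a,b numeric vectors (non-empty).
#' @param n_perm number of label shuffles (>= 99) in the Monte-Carlo mode.
#' @param seed integer seed for the shuffles.
#' @param pair optional label pair carried into the result.
#' @return An object of class `permutation_result`: list with `statistic`,
#'   `p`, `n_perm` (the shuffle count, or the enumeration size), `exact`,
#'   `seed`, `pair`. Degenerate pooled variance gives `p = 1` with a
#'   warning.
#' @export
permutation_pairwise <- function(a, b, n_perm = 10000L, seed = 1L,
                                 pair = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1L, length(b) >= 1L,
            all(is.finite(a)), all(is.finite(b)))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- mean(a) - mean(b)
  res <- structure(list(statistic = obs, p = NA_real_, n_perm = n_perm,
                        exact = FALSE, seed = as.integer(seed), pair = pair),
                   class = "permutation_result")
  if (stats::var(pooled) == 0) {
    warning("degenerate pooled variance: p = 1")
    res$p <- 1
    return(res)
  }
  tol <- 1e-12 * max(1, abs(obs))
  if (n <= 10L) {
    splits <- combn(n, na)
    stats_all <- apply(splits, 2L, function(ix)
      mean(pooled[ix]) - mean(pooled[-ix]))
    res$p <- mean(abs(stats_all) >= abs(obs) - tol)
    res$n_perm <- ncol(splits)
    res$exact <- TRUE
  } else {
    perm_stats <- local_seed(seed, vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n, na)
      mean(pooled[ix]) - mean(pooled[-ix])
    }, numeric(1)))
    res$p <- (1 + sum(abs(perm_stats) >= abs(obs) - tol)) / (1 + n_perm)
  }
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test%s: mean difference = %s, p = %s (%s, %d %s)\n",
              if (is.null(x$pair)) "" else paste0(" [", paste(x$pair,
                                                              collapse = " vs "),
                                                  "]"),
              format(x$statistic, digits = 4), format(x$p, digits = 4),
              if (x$exact) "exact" else "Monte-Carlo", x$n_perm,
              if (x$exact) "arrangements" else "shuffles"))
  invisible(x)
}

#' Omnibus F plus all pairwise permutation posttests across conditions
#'
#' Runs the one-way independent-design ANOVA over the five condition groups
#' and a seeded two-sided permutation test for each of the 10 pairwise
#' contrasts. Significance is flagged at alpha = 0.05 with no multiplicity
#' correction by default; `holm = TRUE` applies a Holm adjustment to the
#' pairwise p-values first.
#'
#' @param values_by_condition named list of numeric vectors, one per
#'   condition; all of `"BC"`, `"38"`, `"40"`, `"42"`, `"44"` must be
#'   present.
#' @param n_perm permutation count per pairwise test.
#' @param seed master seed; each pair gets a derived sub-seed.
#' @param alpha significance level for the flags.
#' @param holm apply a Holm correction to the pairwise p-values.
#' @return A list with `anova` (an `anova_result`), `pairwise` (data.frame
#'   with columns a, b, statistic, p, significant) and `p_matrix` (symmetric
#'   5 x 5 matrix of pairwise p-values).
#' @export
compare_conditions <- function(values_by_condition, n_perm = 10000L,
                               seed = 1L, alpha = 0.05, holm = FALSE) {
  absent <- setdiff(CONDITIONS, names(values_by_condition))
  if (length(absent))
    stop("missing condition groups: ", paste(absent, collapse = ", "))
  groups <- values_by_condition[CONDITIONS]
  aov_res <- oneway_anova(groups)
  pairs <- combn(CONDITIONS, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    pr <- permutation_pairwise(groups[[a]], groups[[b]], n_perm = n_perm,
                               seed = derive_seed(seed, 17L, i),
                               pair = c(a, b))
    data.frame(a = a, b = b, statistic = pr$statistic, p = pr$p)
  })
  pw <- do.call(rbind, rows)
  p_use <- if (holm) stats::p.adjust(pw$p, method = "holm") else pw$p
  pw$significant <- p_use < alpha
  pm <- matrix(NA_real_, 5L, 5L, dimnames = list(CONDITIONS, CONDITIONS))
  for (i in seq_len(nrow(pw))) {
    pm[pw$a[i], pw$b[i]] <- pw$p[i]
    pm[pw$b[i], pw$a[i]] <- pw$p[i]
  }
  list(anova = aov_res, pairwise = pw, p_matrix = pm)
}
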