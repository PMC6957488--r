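#' Spearman rank correlation with large-sample or exact p-value
#'
#' Spearman's rho is the Pearson correlation of mid-ranks (tied values get
#' average ranks). The default p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom; for
#' small samples an exact permutation p-value (proportion of the n!
#' orderings of `y` with `|rho|` at least the observed, ties handled by
#' mid-ranks) is available and is the automatic choice for n <= 8.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"auto"` (exact for n <= 8, t otherwise), `"t"` or
#'   `"exact"` (allowed for n <= 10).
#' @param pair,condition,epoch optional labels carried into the result.
#' @return An object of class `correlation_result`: a list with `rho`, `n`,
#'   `p`, `p_method` and the labels. A constant input yields `rho = NA` with
#'   a warning.
#' @export
spearman_cor <- function(x, y, method = c("auto", "t", "exact"),
                         pair = NULL, condition = NULL, epoch = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3L) stop("fewer than 3 complete observations")
  res <- structure(list(pair = pair, condition = condition, epoch = epoch,
                        rho = NA_real_, n = n, p = NA_real_,
                        p_method = NA_character_),
                   class = "correlation_result")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(res)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "auto") method <- if (n <= 8L) "exact" else "t"
  if (method == "exact") {
    if (n > 10L) stop("exact permutation p only available for n <= 10")
    p <- spearman_exact_p(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  res$rho <- rho
  res$p <- min(1, p)
  res$p_method <- method
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %s (n = %d, p = %s, %s)\n",
              format(x$rho, digits = 4), x$n, format(x$p, digits = 4),
              x$p_method))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); n <= 9.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Exact two-sided permutation p for Spearman rho with mid-ranks:
# P(|rho_perm| >= |rho_obs|) over all n! orderings of y. For n = 10 the
# enumeration is chunked by the first position to bound memory.
spearman_exact_p <- function(rx, ry, tol = 1e-12) {
  n <- length(rx)
  rho_obs <- abs(cor(rx, ry))
  count_block <- function(perms) {
    ry_perm <- matrix(ry[perms], nrow(perms), n)  # [i, j] = ry[perms[i, j]]
    rhos <- as.vector(cor(rx, t(ry_perm)))
    sum(abs(rhos) >= rho_obs - tol)
  }
  if (n <= 9L) {
    count <- count_block(perm_matrix(n))
    total <- factorial(n)
  } else {
    sub <- perm_matrix(n - 1L)
    count <- 0
    for (k in seq_len(n)) {
      rest <- seq_len(n)[-k]
      perms <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
      count <- count + count_block(perms)
    }
    total <- factorial(n)
  }
  count / total
}

#' Per-subject time-domain correlations between perfusion and oxygen saturation
#'
#' For every subject/condition, the Spearman correlation between each
#' requested perfusion component and the oxygen-saturation channel over the
#' samples of one protocol epoch. Subjects missing a channel are skipped
#' with a logged warning. The resulting table is the input for the group
#' comparisons across stimulation temperatures.
#'
#' @param dataset a `signal_dataset`.
#' @param spec an [epoch_spec()].
#' @param which epoch to correlate over (`"baseline"`, `"stimulation"` or
#'   `"post"`).
#' @param pairs character vector of perfusion channels to pair with
#'   `oxy_sat`.
#' @return A data.frame with columns subject_id, group, condition, epoch,
#'   pair, rho, n, p.
#' @export
timecourse_correlations <- function(dataset, spec,
                                    which = c("baseline", "stimulation",
                                              "post"),
                                    pairs = c("V1", "V2", "V3")) {
  which <- match.arg(which, several.ok = TRUE)
  stopifnot(inherits(dataset, "signal_dataset"), inherits(spec, "epoch_spec"))
  idx <- dataset_index(dataset)
  combos <- unique(idx[, c("subject_id", "group", "condition")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- combos$subject_id[i]; cond <- combos$condition[i]
    oxy <- tryCatch(get_record(dataset, sub, cond, "oxy_sat"),
                    error = function(e) NULL)
    if (is.null(oxy)) {
      warning("skipping ", sub, "/", cond, ": oxy_sat channel missing")
      log_event("missing_channel", subject = sub, condition = cond,
                channel = "oxy_sat")
      next
    }
    oxy_e <- extract_epochs(oxy, spec, which)
    for (ch in pairs) {
      v <- tryCatch(get_record(dataset, sub, cond, ch),
                    error = function(e) NULL)
      if (is.null(v)) {
        warning("skipping ", sub, "/", cond, ": ", ch, " channel missing")
        log_event("missing_channel", subject = sub, condition = cond,
                  channel = ch)
        next
      }
      v_e <- extract_epochs(v, spec, which)
      cr <- spearman_cor(v_e$values, oxy_e$values, method = "t")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sub, group = combos$group[i], condition = cond,
        epoch = paste(which, collapse = "+"), pair = paste0(ch, "-oxy"),
        rho = cr$rho, n = cr$n, p = cr$p)
    }
  }
  do.call(rbind, rows)
}

#' Complexity area indices for every record of a dataset
#'
#' Computes the MSE or MFE complexity area index of each requested channel,
#' per subject and condition, over one protocol epoch. Undefined entropies
#' propagate to `NA` CAIs (never interpolated).
#'
#' @param dataset a `signal_dataset`.
#' @param spec an [epoch_spec()].
#' @param which epoch to analyse.
#' @param params an [entropy_params()].
#' @param kind `"MSE"` or `"MFE"`.
#' @param channels channels to analyse.
#' @return A data.frame with columns subject_id, group, condition, epoch,
#'   channel, kind, cai.
#' @export
cai_table <- function(dataset, spec,
                      which = c("baseline", "stimulation", "post"),
                      params = entropy_params(), kind = c("MSE", "MFE"),
                      channels = c("oxy_sat", "V1", "V2", "V3")) {
  which <- match.arg(which, several.ok = TRUE)
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "signal_dataset"), inherits(spec, "epoch_spec"))
  idx <- dataset_index(dataset)
  idx <- idx[idx$channel %in% channels, ]
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    rec <- get_record(dataset, idx$subject_id[i], idx$condition[i],
                      idx$channel[i])
    seg <- extract_epochs(rec, spec, which)
    val <- tryCatch(
      withCallingHandlers(
        entropy_curve(seg$values, params, kind)$cai,
        warning = function(w) {
          log_event("entropy_warning", subject = idx$subject_id[i],
                    condition = idx$condition[i], channel = idx$channel[i],
                    message = conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) NA_real_)
    data.frame(subject_id = idx$subject_id[i], group = idx$group[i],
               condition = idx$condition[i],
               epoch = paste(which, collapse = "+"),
               channel = idx$channel[i], kind = kind, cai = val)
  })
  do.call(rbind, rows)
}

#' Cross-subject correlation of complexity indices
#'
#' For one condition, the Spearman correlation across subjects between the
#' CAI of each perfusion component and the CAI of oxygen saturation.
#' Subjects with a missing CAI in either member of a pair are dropped
#' pairwise, with the remaining n reported.
#'
#' @param cai_tab a table from [cai_table()].
#' @param condition condition label to analyse.
#' @param pairs perfusion channels to pair with `oxy_sat`.
#' @return A data.frame with columns condition, pair, rho, n, p.
#' @export
cai_correlations <- function(cai_tab, condition,
                             pairs = c("V1", "V2", "V3")) {
  tab <- cai_tab[cai_tab$condition == condition, ]
  if (!nrow(tab)) stop("no CAI rows for condition ", condition)
  oxy <- tab[tab$channel == "oxy_sat", c("subject_id", "cai")]
  rows <- list()
  for (ch in pairs) {
    v <- tab[tab$channel == ch, c("subject_id", "cai")]
    mrg <- merge(oxy, v, by = "subject_id", suffixes = c("_oxy", "_v"))
    mrg <- mrg[is.finite(mrg$cai_oxy) & is.finite(mrg$cai_v), ]
    if (nrow(mrg) < 3L)
      stop("fewer than 3 complete subject pairs for ", ch, " in condition ",
           condition)
    cr <- spearman_cor(mrg$cai_v, mrg$cai_oxy, method = "t")
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, pair = paste0(ch, "-oxy"),
      rho = cr$rho, n = cr$n, p = cr$p)
  }
  do.call(rbind, rows)
}
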