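# Independent brute-force reference implementations used as oracles.
# These deliberately mirror the textbook definitions with plain double
# loops, independent of the package's compiled kernels.

# Sample entropy match counts: pairs i < j of length-m templates
# (i, j <= N - m), Chebyshev distance strictly below r.
sampen_bf_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

sampen_bf <- function(x, m, r) {
  ab <- sampen_bf_counts(x, m, r)
  if (ab["B"] == 0L) stop("B = 0")
  if (ab["A"] == 0L) return(NA_real_)
  -log(ab[["A"]] / ab[["B"]])
}

# Fuzzy entropy: mean-removed templates, similarity exp(-(d/r)^p),
# phi averaged over unordered pairs among the N - m extendable templates.
fuzzen_bf <- function(x, m, r, p) {
  n <- length(x)
  nt <- n - m
  phi <- function(len) {
    tpl <- lapply(seq_len(nt), function(i) {
      w <- x[i:(i + len - 1L)]
      w - mean(w)
    })
    s <- 0
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        d <- max(abs(tpl[[i]] - tpl[[j]]))
        s <- s + exp(-(d / r)^p)
      }
    }
    s / (nt * (nt - 1L) / 2)
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Small synthetic cohort shared across pipeline-level tests.
mini_design <- function(ts = 4L, bc = 4L, seed = 1L) {
  study_design(ts, bc, seed = seed)
}

mini_config <- function(seed = 1L, ...) {
  synthetic_config(epoch_minutes = c(2, 2, 2), seed = seed, ...)
}
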