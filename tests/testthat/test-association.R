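test_that("spearman correlation honours monotone invariance and symmetry", {
  x <- c(0.3, 1.1, 2.7, 3.0, 5.9, 7.2, 8.8, 9.1, 10.5, 12.0, 13.3, 15.1)
  expect_equal(spearman_cor(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(1)
  y <- rnorm(length(x))
  base <- spearman_cor(x, y)
  expect_identical(spearman_cor(y, x)$rho, base$rho)
  # strictly monotone transforms of either argument leave rho unchanged
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, rank(y))$rho, base$rho)
  expect_warning(res <- spearman_cor(rep(1, 10), y[1:10]), "constant")
  expect_true(is.na(res$rho))
})

test_that("tied data uses mid-ranks, matching the hand computation", {
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  # mid-ranks: rx = 1, 2.5, 2.5, 4; ry = 2, 1, 3.5, 3.5
  rx <- c(1, 2.5, 2.5, 4)
  ry <- c(2, 1, 3.5, 3.5)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y)$rho, hand, tolerance = 1e-12)
  # and agrees with the standard library estimate
  expect_equal(spearman_cor(x, y)$rho,
               suppressWarnings(cor(x, y, method = "spearman")))
})

test_that("t-approximation and exact permutation p-values mostly agree", {
  # independent random instances; the t approximation is anti-conservative
  # close to the rejection boundary, so agreement is a calibration check
  set.seed(21)
  agree <- 0
  n_inst <- 200
  for (i in seq_len(n_inst)) {
    n <- sample(5:8, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    pe <- spearman_cor(x, y, method = "exact")$p
    pt_ <- spearman_cor(x, y, method = "t")$p
    agree <- agree + ((pe < 0.05) == (pt_ < 0.05))
  }
  expect_gte(agree / n_inst, 0.95)
  # exact p itself is a valid probability and reproducible
  x <- c(2, 5, 1, 4, 3)
  y <- c(1, 4, 2, 5, 3)
  p1 <- spearman_cor(x, y, method = "exact")$p
  expect_identical(p1, spearman_cor(x, y, method = "exact")$p)
  expect_true(p1 > 0 && p1 <= 1)
  expect_error(spearman_cor(rnorm(12), rnorm(12), method = "exact"),
               "n <= 10")
})

test_that("per-subject time-domain correlation tables are well-formed", {
  set.seed(2)
  cohort <- generate_cohort(study_design(2, 2, seed = 1), mini_config())
  es <- config_epochs(mini_config())
  tab <- timecourse_correlations(cohort, es, "stimulation")
  # 2 TS subjects x 4 temps + 2 BC subjects, 3 pairs each
  expect_equal(nrow(tab), (2 * 4 + 2) * 3)
  expect_true(all(abs(tab$rho) <= 1))
  expect_true(all(tab$n == 360))
  # the oxygen channel against itself is always a perfect correlation
  self <- timecourse_correlations(cohort, es, "baseline", pairs = "oxy_sat")
  expect_true(all(self$rho == 1))
  # a missing channel skips that subject/pair with a warning
  broken <- cohort[!grepl("TS01/38/V2", names(cohort))]
  class(broken) <- "signal_dataset"
  expect_warning(tab2 <- timecourse_correlations(broken, es, "stimulation"),
                 "V2 channel missing")
  expect_equal(nrow(tab2), nrow(tab) - 1)
})

test_that("CAI correlations detect comonotone indices and report n pairwise", {
  subs <- sprintf("S%02d", 1:8)
  jitter <- seq(0.1, 0.8, by = 0.1)
  tab <- rbind(
    data.frame(subject_id = subs, group = "TS", condition = "38",
               epoch = "stimulation", channel = "oxy_sat", kind = "MSE",
               cai = 10 + jitter),
    data.frame(subject_id = subs, group = "TS", condition = "38",
               epoch = "stimulation", channel = "V1", kind = "MSE",
               cai = 20 + jitter))
  res <- cai_correlations(tab, "38", pairs = "V1")
  expect_equal(res$rho, 1)
  expect_equal(res$n, 8)
  # a missing CAI drops that subject pairwise
  tab$cai[tab$channel == "V1" & tab$subject_id == "S03"] <- NA
  res2 <- cai_correlations(tab, "38", pairs = "V1")
  expect_equal(res2$n, 7)
  expect_equal(res2$rho, 1)
  # fewer than 3 complete pairs is a degeneracy error
  tab$cai[tab$channel == "V1" & tab$subject_id %in% subs[3:8]] <- NA
  expect_error(cai_correlations(tab, "38", pairs = "V1"), "fewer than 3")
})

test_that("shared complexity jitter induces positive CAI coupling", {
  # per-subject white_fraction shared across channels drives the CAIs of
  # oxygen and perfusion up and down together across subjects
  rhos <- sapply(1:5, function(s) {
    cfg <- synthetic_config(epoch_minutes = c(3, 3, 3), seed = s,
                            white_fraction = 0.5,
                            white_fraction_jitter_sd = 0.35,
                            white_fraction_jitter = "shared")
    cohort <- generate_cohort(study_design(1, 10, seed = s), cfg)
    tab <- cai_table(cohort, config_epochs(cfg), "baseline",
                     entropy_params(max_scale = 8), "MSE",
                     channels = c("oxy_sat", "V1"))
    cai_correlations(tab, "BC", pairs = "V1")$rho
  })
  # the contract is recovery of a positive complexity coupling
  expect_gt(mean(rhos), 0.25)
  expect_gte(mean(rhos > 0), 0.8)
})
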