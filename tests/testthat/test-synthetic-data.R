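test_that("noise generator is deterministic with exact SD and sensible spectra", {
  n1 <- generate_noise(5000, 0.5, 1.5, seed = 9)
  n2 <- generate_noise(5000, 0.5, 1.5, seed = 9)
  expect_identical(n1, n2)
  expect_equal(sd(n1), 1.5, tolerance = 1e-9)
  expect_equal(mean(n1), 0, tolerance = 1e-9)
  expect_equal(sd(generate_noise(1000, 0, 2, seed = 1)), 2, tolerance = 1e-9)
  # iid case: lag-1 autocorrelation within 3/sqrt(n) of zero
  w <- generate_noise(10000, 1, 1, seed = 4)
  ac1 <- cor(w[-1], w[-length(w)])
  expect_lt(abs(ac1), 3 / sqrt(10000))
  # 1/f noise is strongly positively autocorrelated at lag 1
  p <- generate_noise(10000, 0, 1, seed = 4)
  expect_gt(cor(p[-1], p[-length(p)]), 0.5)
  expect_error(generate_noise(1, 0.5, 1), "n")
  expect_error(generate_noise(100, 1.5, 1))
})

test_that("response curve reproduces the protocol shape templates", {
  cfg <- mini_config()
  t <- seq(0, 6 * 60 - 1 / 3, by = 1 / 3)
  expect_equal(response_curve("BC", t, cfg),
               rep(cfg$baseline_oxy_pct, length(t)))
  # zero amplitude collapses any temperature to the flat baseline
  cfg0 <- mini_config(response_amplitude_pct = 0)
  expect_equal(response_curve("42", t, cfg0),
               rep(cfg0$baseline_oxy_pct, length(t)))
  # monotone saturating rise during stimulation
  y <- response_curve("40", t, cfg)
  stim <- t >= 120 & t < 240
  expect_true(all(diff(y[stim]) > 0))
  expect_true(all(y[t < 120] == cfg$baseline_oxy_pct))
  # zero decay rate: post epoch frozen at the stimulation-end level
  cfg_nd <- mini_config(post_decay_rate_per_s = 0)
  ynd <- response_curve("44", t, cfg_nd)
  expect_equal(unique(ynd[t >= 240]), max(ynd))
  # positive decay brings the signal back toward baseline
  ydec <- response_curve("38", t, cfg)
  expect_lt(ydec[length(ydec)], max(ydec))
  expect_error(response_curve("39", t, cfg), "unknown condition")
})

test_that("generated recordings respect the protocol sample counts", {
  des <- study_design(2, 2, seed = 1)
  cfg <- synthetic_config(seed = 1)  # default 30/30/30 min at 3 Hz
  ds <- generate_subject("TS01", "40", des, cfg)
  expect_length(ds, 5)
  for (rec in ds) expect_length(rec$values, 16200)
  es <- config_epochs(cfg)
  oxy <- get_record(ds, "TS01", "40", "oxy_sat")
  for (ep in c("baseline", "stimulation", "post"))
    expect_length(extract_epoch(oxy, es, ep)$values, 5400)
  # temperature channel is the programmed set-point trace
  tc <- get_record(ds, "TS01", "40", "temperature")$values
  expect_equal(unique(tc[1:5400]), cfg$skin_temp_c)
  expect_equal(unique(tc[5401:10800]), 40)
})

test_that("generation is reproducible bit-for-bit and validates design", {
  des <- mini_design()
  cfg <- mini_config(seed = 5)
  a <- generate_subject("TS02", "44", des, cfg)
  b <- generate_subject("TS02", "44", des, cfg)
  expect_identical(a, b)
  expect_error(generate_subject("BC01", "38", des, cfg), "cannot be recorded")
  expect_error(generate_subject("TS01", "BC", des, cfg), "cannot be recorded")
  expect_error(generate_subject("XX01", "38", des, cfg), "not in design")
})

test_that("full shared noise gives near-perfect rank coupling", {
  des <- mini_design()
  cfg <- mini_config(coupling = 1, seed = 2)
  ds <- generate_subject("TS01", "40", des, cfg)
  es <- config_epochs(cfg)
  oxy <- extract_epoch(get_record(ds, "TS01", "40", "oxy_sat"), es,
                       "stimulation")
  v1 <- extract_epoch(get_record(ds, "TS01", "40", "V1"), es, "stimulation")
  expect_gt(spearman_cor(v1$values, oxy$values, method = "t")$rho, 0.99)
})

test_that("empirical rank coupling is monotone in the configured coupling", {
  des <- mini_design()
  grid <- c(-0.8, 0, 0.4, 0.8)
  mean_rho <- sapply(grid, function(cp) {
    rhos <- sapply(1:20, function(s) {
      cfg <- synthetic_config(epoch_minutes = c(1, 1, 1), coupling = cp,
                              seed = s)
      ds <- generate_subject("BC01", "BC", des, cfg)
      oxy <- get_record(ds, "BC01", "BC", "oxy_sat")$values
      v1 <- get_record(ds, "BC01", "BC", "V1")$values
      spearman_cor(v1, oxy, method = "t")$rho
    })
    mean(rhos)
  })
  expect_true(all(diff(mean_rho) > 0))
  # null coupling: mean rho within 4/sqrt(n) of zero (n = 180 per replicate)
  expect_lt(abs(mean_rho[2]), 4 / sqrt(180))
})

test_that("study design assigns each subject its full condition set", {
  des <- study_design(5, 3, seed = 11)
  expect_length(des$ts_ids, 5)
  for (ord in des$stimulation_order)
    expect_setequal(ord, c("38", "40", "42", "44"))
  expect_identical(des$stimulation_order,
                   study_design(5, 3, seed = 11)$stimulation_order)
  # different subjects get (generally) different orders under a fixed seed
  expect_gt(length(unique(vapply(des$stimulation_order, paste,
                                 character(1), collapse = ""))), 1)
  cohort <- generate_cohort(study_design(2, 3, seed = 1), mini_config())
  idx <- dataset_index(cohort)
  expect_equal(nrow(idx), (2 * 4 + 3) * 5)
  counts <- table(idx$subject_id[idx$channel == "oxy_sat"])
  expect_true(all(counts[grep("TS", names(counts))] == 4))
  expect_true(all(counts[grep("BC", names(counts))] == 1))
})

test_that("oxygen clipping is applied and logged", {
  thermosat_log(clear = TRUE)
  des <- mini_design()
  cfg <- mini_config(baseline_oxy_pct = 99, noise_sd = 3, seed = 3)
  ds <- generate_subject("BC01", "BC", des, cfg)
  oxy <- get_record(ds, "BC01", "BC", "oxy_sat")$values
  expect_true(all(oxy >= 0 & oxy <= 100))
  ev <- thermosat_log()
  expect_true(any(vapply(ev, function(e) e$type == "clipped_samples",
                         logical(1))))
})
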