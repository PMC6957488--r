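#' End-to-end run configuration
#'
#' Everything [run_all()] needs: the input (a recordings CSV, or
#' `"simulate"` to generate a cohort), the protocol epochs, the entropy
#' parameters, the choice of "after stimulation" analysis window, the
#' permutation budget and the master seed. Fully serialisable; an MD5 hash
#' of the serialised configuration is embedded in every output file header
#' so results can be traced back to their settings.
#'
#' @param input `"simulate"` or a path to a long-format recordings CSV.
#' @param design a [study_design()] (used when simulating).
#' @param config a [synthetic_config()] (used when simulating).
#' @param epochs an [epoch_spec()]; defaults to the one implied by `config`.
#' @param params an [entropy_params()].
#' @param after_window which samples constitute the "after stimulation"
#'   analyses: the stimulation epoch (default), the post epoch, or both
#'   concatenated.
#' @param n_perm permutation count for the posttests.
#' @param seed master seed for simulation and permutations.
#' @param output_dir directory for the results bundle.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = "simulate",
                       design = study_design(),
                       config = synthetic_config(),
                       epochs = NULL,
                       params = entropy_params(),
                       after_window = c("stimulation", "post", "both"),
                       n_perm = 10000L, seed = 1L,
                       output_dir = "thermosat-results") {
  after_window <- match.arg(after_window)
  if (is.null(epochs)) epochs <- config_epochs(config)
  stopifnot(inherits(design, "study_design"),
            inherits(config, "synthetic_config"),
            inherits(epochs, "epoch_spec"),
            inherits(params, "entropy_params"))
  structure(list(input = input, design = design, config = config,
                 epochs = epochs, params = params,
                 after_window = after_window, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

config_hash <- function(rc) {
  json <- jsonlite::toJSON(rapply(unclass(rc), unclass, how = "replace"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_with_header <- function(df, path, hash) {
  writeLines(paste0("# config_hash=", hash), path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  path
}

after_epochs <- function(after_window) {
  switch(after_window,
         stimulation = "stimulation",
         post = "post",
         both = c("stimulation", "post"))
}

#' Run the complete analysis pipeline
#'
#' Simulates or loads a cohort, then runs the four analysis families in
#' order: (1) minute-averaged oxygen-saturation time courses per condition;
#' (2) MSE and MFE complexity area indices of every channel before and
#' after stimulation, with the omnibus F and pairwise permutation posttests
#' on the oxygen-saturation CAIs; (3) per-subject time-domain Spearman
#' correlations between each perfusion component and oxygen saturation,
#' before and after, with group comparisons of the after-stimulation
#' correlations; (4) cross-subject correlations of the CAIs per condition.
#' All tables are written as tab-separated files with the configuration
#' hash in a header line, together with a JSON run manifest (configuration,
#' seed, package version, structured warnings). Any stage failure aborts
#' the run, names the stage, and removes the partial outputs.
#'
#' @param rc a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`timecourse`,
#'   `cai`, `cai_comparisons`, `rho`, `rho_comparisons`,
#'   `cai_correlations`, `manifest`) and the output file paths.
#' @export
run_all <- function(rc, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  hash <- config_hash(rc)
  thermosat_log(clear = TRUE)
  say <- function(...) if (!quiet) message(...)
  emit <- function(df, name) {
    path <- file.path(rc$output_dir, name)
    write_tsv_with_header(df, path, hash)
    written <<- c(written, path)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  aft <- after_epochs(rc$after_window)

  dataset <- stage("data", {
    if (identical(rc$input, "simulate")) generate_cohort(rc$design, rc$config)
    else read_dataset(rc$input)
  })
  say("data: ", length(dataset), " records")

  tc <- stage("timecourse", {
    idx <- dataset_index(dataset)
    oxy_idx <- idx[idx$channel == "oxy_sat", ]
    rows <- lapply(seq_len(nrow(oxy_idx)), function(i) {
      rec <- get_record(dataset, oxy_idx$subject_id[i], oxy_idx$condition[i],
                        "oxy_sat")
      ma <- minute_average(rec)
      data.frame(subject_id = rec$subject_id, condition = rec$condition,
                 minute = ma$time_s / 60, mean_oxy = ma$mean)
    })
    do.call(rbind, rows)
  })
  emit(tc, "timecourse.tsv")

  cais <- stage("entropy", {
    tabs <- list()
    for (kind in c("MSE", "MFE")) {
      tabs[[paste0(kind, "_before")]] <-
        cai_table(dataset, rc$epochs, "baseline", rc$params, kind)
      tabs[[paste0(kind, "_after")]] <-
        cai_table(dataset, rc$epochs, aft, rc$params, kind)
    }
    do.call(rbind, tabs)
  })
  emit(cais, "cai.tsv")

  cai_cmp <- stage("entropy_comparisons", {
    rows <- list()
    for (kind in c("MSE", "MFE")) for (ep in unique(cais$epoch)) {
      sub <- cais[cais$kind == kind & cais$epoch == ep &
                    cais$channel == "oxy_sat" & is.finite(cais$cai), ]
      groups <- split(sub$cai, factor(sub$condition, levels = CONDITIONS))
      cmp <- compare_conditions(groups, n_perm = rc$n_perm,
                                seed = derive_seed(rc$seed, 31L,
                                                   match(kind, c("MSE", "MFE"))))
      rows[[paste(kind, ep)]] <- data.frame(
        kind = kind, epoch = ep, contrast = c("omnibus",
                                              paste(cmp$pairwise$a,
                                                    cmp$pairwise$b, sep = ":")),
        statistic = c(cmp$anova$F, cmp$pairwise$statistic),
        df = c(sprintf("(%d,%d)", cmp$anova$df_between, cmp$anova$df_within),
               rep(NA, nrow(cmp$pairwise))),
        p = c(cmp$anova$p, cmp$pairwise$p))
    }
    do.call(rbind, rows)
  })
  emit(cai_cmp, "cai_comparisons.tsv")

  rho_tab <- stage("association", {
    rbind(timecourse_correlations(dataset, rc$epochs, "baseline"),
          timecourse_correlations(dataset, rc$epochs, aft))
  })
  emit(rho_tab, "timecourse_correlations.tsv")

  rho_cmp <- stage("association_comparisons", {
    after_label <- paste(aft, collapse = "+")
    rows <- list()
    for (pr in unique(rho_tab$pair)) for (ep in c("baseline", after_label)) {
      sub <- rho_tab[rho_tab$pair == pr & rho_tab$epoch == ep &
                       is.finite(rho_tab$rho), ]
      groups <- split(sub$rho, factor(sub$condition, levels = CONDITIONS))
      cmp <- compare_conditions(groups, n_perm = rc$n_perm,
                                seed = derive_seed(rc$seed, 47L,
                                                   match(pr,
                                                         unique(rho_tab$pair))))
      rows[[paste(pr, ep)]] <- data.frame(
        pair = pr, epoch = ep,
        contrast = c("omnibus", paste(cmp$pairwise$a, cmp$pairwise$b,
                                      sep = ":")),
        statistic = c(cmp$anova$F, cmp$pairwise$statistic),
        df = c(sprintf("(%d,%d)", cmp$anova$df_between, cmp$anova$df_within),
               rep(NA, nrow(cmp$pairwise))),
        p = c(cmp$anova$p, cmp$pairwise$p))
    }
    do.call(rbind, rows)
  })
  emit(rho_cmp, "correlation_comparisons.tsv")

  cai_cor <- stage("cai_correlations", {
    mse_after <- cais[cais$kind == "MSE" &
                        cais$epoch == paste(aft, collapse = "+"), ]
    rows <- lapply(CONDITIONS, function(cond)
      tryCatch(cai_correlations(mse_after, cond), error = function(e) {
        log_event("cai_correlation_skipped", condition = cond,
                  message = conditionMessage(e))
        NULL
      }))
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no condition had enough complete CAI pairs")
    out
  })
  emit(cai_cor, "cai_correlations.tsv")

  manifest <- list(
    package = "thermosat",
    version = as.character(utils::packageVersion("thermosat")),
    config_hash = hash,
    config = rapply(unclass(rc), unclass, how = "replace"),
    files = basename(written),
    log = thermosat_log())
  manifest_path <- file.path(rc$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  written <- c(written, manifest_path)
  say("wrote ", length(written), " files to ", rc$output_dir)

  invisible(list(timecourse = tc, cai = cais, cai_comparisons = cai_cmp,
                 rho = rho_tab, rho_comparisons = rho_cmp,
                 cai_correlations = cai_cor, manifest = manifest,
                 files = written))
}
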