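# End-to-end orchestration: simulate (or ingest) -> preprocess -> fit per
# occasion -> diagnose -> stability analyses -> report. One run = one
# immutable output directory; every numeric decision is a config key.

#' Default pipeline configuration
#'
#' Flat key-value configuration covering every tunable numeric decision
#' of the pipeline: cohort design, generating growth model, artifact
#' rates, preprocessing rules, fit and sampler geometry, prior
#' hyperparameters, diagnostic thresholds, and analysis settings.
#'
#' @return Named list (storable as YAML via \code{\link{write_config}}).
#' @export
default_config <- function() {
  pr <- default_priors()
  pr$note <- NULL
  names(pr) <- paste0("prior_", names(pr))
  c(list(
    seed = 1,
    # cohort design
    subgroup_sizes = c(113, 109, 26, 63, 58),
    retention = c(369, 358, 327, 327),
    months = c(0, 6, 12, 24),
    age_young_mean = 21.57, age_young_sd = 2.20,
    age_old_mean = 67.76, age_old_sd = 5.31,
    trials_per_block = 60, training_trials = 20,
    dropout = "random",
    # generating growth model (per family: mean_i, var_i, mean_s, var_s,
    # cov_is, loadings 3:4, residual variances)
    nu_mean_i = 2.104, nu_var_i = 0.164, nu_mean_s = 0.112,
    nu_var_s = 0.026, nu_cov_is = 0, nu_l3 = 1.142, nu_l4 = 1.297,
    nu_resid = c(0.020, 0.036, 0.060, 0.082),
    a_mean_i = 2.053, a_var_i = 0.274, a_mean_s = -0.123,
    a_var_s = 0, a_cov_is = 0, a_l3 = 1.233, a_l4 = 1.334,
    a_resid = c(0.060, 0.020, 0.036, 0.045),
    tau_mean_i = 0.436, tau_var_i = 0.006, tau_mean_s = -0.010,
    tau_var_s = 0, tau_cov_is = 0, tau_l3 = -0.358, tau_l4 = 0.509,
    tau_resid = c(0.001, 1e-4, 0.001, 0.002),
    correction = 0.3,
    truncation_a_min = 0.2, truncation_tau_min = 0.05,
    # condition effects (congruent sign; incongruent is the negative)
    effect_drift_congruent = 0.2,
    effect_boundary_congruent = -0.05,
    # artifact injection
    fast_rate = 0.012, slow_rate = 0.006, nonrecorded_rate = 0.01,
    # preprocessing
    rt_low = 0.3, rt_high = 3.0, iqr_multiplier = 3,
    accuracy_before_rt_filter = TRUE,
    # hierarchical fit
    fit_chains = 4, fit_iter = 6000, fit_burnin = 1000, min_trials = 20,
    # diagnostics
    rhat_threshold = 1.01, ess_threshold = 400, ppc_draws = 500,
    # stability analyses
    growth_chains = 3, growth_iter = 10000, growth_burnin = 5000,
    growth_missing = "fiml",
    hdi_mass = 0.95, cauchy_scale = round(sqrt(2) / 2, 7),
    z_scope = "per_time_point"),
    pr)
}

#' Write / read a pipeline configuration
#' @param config Configuration list.
#' @param path YAML file path.
#' @return \code{read_config} returns the configuration list merged over
#'   the defaults.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  cfg
}

config_model <- function(cfg) {
  longitudinal_model(
    nu = growth_params(cfg$nu_mean_i, cfg$nu_var_i, cfg$nu_mean_s,
                       cfg$nu_var_s, cfg$nu_cov_is,
                       c(0, 1, cfg$nu_l3, cfg$nu_l4), cfg$nu_resid),
    a = growth_params(cfg$a_mean_i, cfg$a_var_i, cfg$a_mean_s,
                      cfg$a_var_s, cfg$a_cov_is,
                      c(0, 1, cfg$a_l3, cfg$a_l4), cfg$a_resid),
    tau = growth_params(cfg$tau_mean_i, cfg$tau_var_i, cfg$tau_mean_s,
                        cfg$tau_var_s, cfg$tau_cov_is,
                        c(0, 1, cfg$tau_l3, cfg$tau_l4), cfg$tau_resid),
    correction = cfg$correction)
}

config_cohort <- function(cfg) {
  cohort_config(
    subgroup_sizes = cfg$subgroup_sizes, retention = cfg$retention,
    age_young = c(mean = cfg$age_young_mean, sd = cfg$age_young_sd),
    age_old = c(mean = cfg$age_old_mean, sd = cfg$age_old_sd),
    trials_per_block = cfg$trials_per_block,
    training_trials = cfg$training_trials,
    effects = condition_effects(
      default_condition_labels(),
      drift_effects = ifelse(grepl(":congruent$",
                                   default_condition_labels()),
                             cfg$effect_drift_congruent,
                             -cfg$effect_drift_congruent),
      boundary_effects = ifelse(grepl(":congruent$",
                                      default_condition_labels()),
                                cfg$effect_boundary_congruent,
                                -cfg$effect_boundary_congruent)),
    months = cfg$months, dropout = cfg$dropout)
}

config_priors <- function(cfg) {
  pr <- cfg[grepl("^prior_", names(cfg))]
  names(pr) <- sub("^prior_", "", names(pr))
  pr
}

stage_msg <- function(run_dir, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(run_dir, "pipeline.log"),
      append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — simulate (or ingest a trial CSV),
#' preprocess, fit one hierarchical model per occasion, diagnose,
#' stability analyses, report — writing each stage's outputs as CSV/JSON
#' into \code{outdir}. A config snapshot is written alongside the
#' outputs; rerunning with the same config and seed reproduces all CSVs.
#' Any stage failure halts with the stage name; outputs of completed
#' stages persist. The error non-decision time is carried through fit
#' outputs but excluded from all stability outputs.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @param outdir Output directory (created; must not already contain a
#'   run).
#' @param stages Subset of stages to run, in pipeline order.
#' @param trials_csv Optional path to an existing trial CSV to ingest
#'   instead of simulating.
#' @return Invisibly, a list with the run directory and the main result
#'   objects.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = c("simulate", "preprocess", "fit",
                                    "diagnose", "analyze", "report"),
                         trials_csv = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(outdir, "config.yaml"))
  manifest <- list(r_version = R.version.string,
                   package = as.character(utils::packageVersion("ddmlong")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  run_stage <- function(name, expr) {
    stage_msg(outdir, "stage ", name, " start")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(run_dir = outdir)

  if ("simulate" %in% stages) {
    res$trials <- run_stage("simulate", {
      set.seed(config$seed)
      if (!is.null(trials_csv)) {
        tr <- read_trials(trials_csv)
      } else {
        model <- config_model(config)
        cohort <- config_cohort(config)
        drawn <- draw_person_trajectories(model, cohort)
        write.csv(drawn$trajectories,
                  file.path(outdir, "ground_truth_trajectories.csv"),
                  row.names = FALSE)
        write.csv(drawn$latents,
                  file.path(outdir, "ground_truth_latents.csv"),
                  row.names = FALSE)
        tr <- generate_trials(drawn$trajectories, cohort)
        inj <- inject_artifacts(tr, config$fast_rate, config$slow_rate,
                                config$nonrecorded_rate)
        tr <- inj$trials
        jsonlite::write_json(as.list(inj$counts),
                             file.path(outdir, "artifact_counts.json"),
                             auto_unbox = TRUE)
        res$trajectories <- drawn
      }
      write_trials(tr, file.path(outdir, "trials.csv"))
      stage_msg(outdir, "simulate: ", nrow(tr), " trials, ",
                length(unique(tr$participant_id)), " participants")
      tr
    })
  }
  if ("preprocess" %in% stages) {
    res$pre <- run_stage("preprocess", {
      tr <- if (!is.null(res$trials)) res$trials else
        read_trials(file.path(outdir, "trials.csv"))
      pre <- preprocess_trials(tr, config$rt_low, config$rt_high,
                               config$iqr_multiplier,
                               config$accuracy_before_rt_filter)
      write_trials(pre$trials, file.path(outdir, "trials_preprocessed.csv"))
      write.csv(pre$log, file.path(outdir, "exclusion_log.csv"),
                row.names = FALSE)
      stage_msg(outdir, "preprocess: excluded fraction ",
                sprintf("%.4f", pre$excluded_fraction))
      pre
    })
  }
  if ("fit" %in% stages) {
    res$fits <- run_stage("fit", {
      tr <- if (!is.null(res$pre)) res$pre$trials else
        read_trials(file.path(outdir, "trials_preprocessed.csv"))
      spec <- ddm_model_spec(min_trials = config$min_trials)
      fits <- list()
      for (tp in sort(unique(tr$time_point))) {
        sub <- tr[tr$time_point == tp, , drop = FALSE]
        model <- build_model(sub, spec, config_priors(config))
        fit <- run_mcmc(model, config$fit_chains, config$fit_iter,
                        config$fit_burnin,
                        seed = config$seed + 17 * tp)
        fits[[as.character(tp)]] <- fit
        persist_fit_draws(fit, outdir, tp)
        stage_msg(outdir, "fit tp ", tp, ": ", length(fit$person_ids),
                  " participants")
      }
      fits
    })
  }
  if ("diagnose" %in% stages) {
    res$diag <- run_stage("diagnose", {
      set.seed(config$seed + 1000)
      all_ids <- sort(unique(read_trials(
        file.path(outdir, "trials.csv"))$participant_id))
      med_rows <- diag_rows <- ppc_rows <- list()
      for (tp in names(res$fits)) {
        fit <- res$fits[[tp]]
        dg <- fit_diagnostics(fit, config$rhat_threshold,
                              config$ess_threshold)
        med <- extract_person_medians(fit, all_ids = all_ids)
        ex <- apply_exclusion_rules(med, dg)
        dg$time_point <- as.integer(tp)
        med2 <- ex$medians
        med2$time_point <- as.integer(tp)
        diag_rows[[tp]] <- dg
        med_rows[[tp]] <- med2
        stage_msg(outdir, "diagnose tp ", tp, ": excluded fraction ",
                  sprintf("%.4f", ex$fraction))
      }
      diagnostics <- do.call(rbind, diag_rows)
      medians <- do.call(rbind, med_rows)
      rownames(medians) <- NULL
      write.csv(diagnostics, file.path(outdir, "diagnostics.csv"),
                row.names = FALSE)
      write.csv(medians, file.path(outdir, "person_medians.csv"),
                row.names = FALSE)
      if (config$ppc_draws > 0) {
        tr <- if (!is.null(res$pre)) res$pre$trials else
          read_trials(file.path(outdir, "trials_preprocessed.csv"))
        tp1 <- names(res$fits)[1]
        ppc <- posterior_predictive_check(
          res$fits[[tp1]], tr[tr$time_point == as.integer(tp1), ],
          n_draws = min(config$ppc_draws,
                        dim(res$fits[[tp1]]$draws)[1] *
                          res$fits[[tp1]]$n_chains))
        ppc$time_point <- as.integer(tp1)
        write.csv(ppc, file.path(outdir, "ppc.csv"), row.names = FALSE)
      }
      list(diagnostics = diagnostics, medians = medians)
    })
  }
  if ("analyze" %in% stages) {
    res$analysis <- run_stage("analyze", {
      set.seed(config$seed + 2000)
      medians <- if (!is.null(res$diag)) res$diag$medians else
        read.csv(file.path(outdir, "person_medians.csv"),
                 stringsAsFactors = FALSE)
      analysis <- analyze_stability(medians, res$fits, config)
      write_analysis(analysis, outdir)
      analysis
    })
  }
  if ("report" %in% stages) {
    run_stage("report", make_report(outdir))
  }
  stage_msg(outdir, "pipeline complete")
  invisible(res)
}

# columnar draw persistence (group-level and person main parameters)
persist_fit_draws <- function(fit, outdir, tp) {
  keep <- c("mu_nu", "sigma_nu", "mu_a", "sigma_a", "mu_tau_plus",
            "sigma_tau_plus", "mu_tau_minus", "sigma_tau_minus",
            as.vector(outer(c("nu[", "a[", "tau_plus[", "tau_minus["),
                            fit$person_ids,
                            function(a, b) paste0(a, b, "]"))))
  keep <- intersect(keep, fit$parameters)
  n_it <- dim(fit$draws)[1]
  out <- do.call(rbind, lapply(keep, function(par) {
    data.frame(parameter = par,
               chain = rep(seq_len(fit$n_chains), each = n_it),
               iteration = rep(seq_len(n_it), fit$n_chains),
               value = as.vector(fit$draws[, , par]))
  }))
  f <- file.path(outdir, sprintf("draws_tp%s.csv", tp))
  write.csv(out, f, row.names = FALSE)
  jsonlite::write_json(
    list(n_chains = fit$n_chains, n_iter = fit$n_iter,
         n_burnin = fit$n_burnin, seed = fit$seed,
         n_participants = length(fit$person_ids)),
    file.path(outdir, sprintf("draws_tp%s_meta.json", tp)),
    auto_unbox = TRUE)
  invisible(f)
}

# the four stability analyses + dropout t-tests on a medians table
analyze_stability <- function(medians, fits, config) {
  pars <- c("nu", "a", "tau_plus")
  rank_order <- do.call(rbind, lapply(pars, function(p) {
    m <- rank_order_matrix(medians, p)
    m$parameter <- p
    m
  }))
  mean_level <- NULL
  if (!is.null(fits)) {
    ml <- list()
    for (p in c("nu", "a", "tau_plus")) {
      gpar <- c(nu = "mu_nu", a = "mu_a", tau_plus = "mu_tau_plus")[[p]]
      draws <- lapply(fits, function(f) as.vector(draws_of(f, gpar)))
      cmp <- mean_level_comparison(draws, config$hdi_mass)
      cmp$parameter <- p
      ml[[p]] <- cmp
    }
    mean_level <- do.call(rbind, ml)
  }
  growth <- list()
  for (p in pars) {
    wide <- tapply(medians[[p]],
                   list(medians$participant_id, medians$time_point),
                   identity)
    if (sum(rowSums(!is.na(wide)) >= 2) < 50) {
      # growth curves need a cohort-sized sample; smaller runs carry the
      # other three analyses only
      message("analyze: skipping growth curve for ", p,
              " (fewer than 50 persons with >= 2 occasions)")
      next
    }
    growth[[p]] <- fit_growth_curve(
      wide, config$growth_chains, config$growth_iter,
      config$growth_burnin, seed = config$seed + 3000,
      missing = config$growth_missing)
  }
  z <- standardize_profiles(medians, scope = config$z_scope)
  qsum <- q_profile_summary(z)
  qrec <- do.call(rbind, lapply(seq_len(nrow(qsum)), function(i) {
    q_profile_correlations(z, qsum$t1[i], qsum$t2[i])$records
  }))
  # dropout: persons missing (unobserved or non-converged) at any later
  # occasion vs complete persons, on occasion-1 medians
  t1 <- medians[medians$time_point == 1, ]
  later <- medians[medians$time_point > 1, ]
  miss_ids <- unique(later$participant_id[!is.finite(later$nu)])
  dropout <- do.call(rbind, lapply(pars, function(p) {
    x <- t1[[p]][t1$participant_id %in% miss_ids]
    y <- t1[[p]][!t1$participant_id %in% miss_ids]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(parameter = p, bf10 = NA_real_, t = NA_real_,
                        n_missing = length(x), n_complete = length(y)))
    }
    bt <- dropout_bayes_t_test(x, y, config$cauchy_scale)
    data.frame(parameter = p, bf10 = bt$bf10, t = bt$t,
               n_missing = bt$n1, n_complete = bt$n2)
  }))
  list(rank_order = rank_order, mean_level = mean_level, growth = growth,
       q_summary = qsum, q_records = qrec, dropout = dropout)
}

write_analysis <- function(analysis, outdir) {
  write.csv(analysis$rank_order, file.path(outdir, "rank_order.csv"),
            row.names = FALSE)
  if (!is.null(analysis$mean_level)) {
    write.csv(analysis$mean_level, file.path(outdir, "mean_level.csv"),
              row.names = FALSE)
  }
  for (p in names(analysis$growth)) {
    g <- analysis$growth[[p]]
    out <- data.frame(parameter = rownames(g$summary),
                      round(g$summary, 6))
    out$fixed_cov_is <- g$fixed[["cov_is"]]
    out$fixed_var_s <- g$fixed[["var_s"]]
    out$bCFI <- round(g$fit_indices[["bCFI"]], 4)
    out$bGammaHat <- round(g$fit_indices[["bGammaHat"]], 4)
    write.csv(out, file.path(outdir, sprintf("growth_%s.csv", p)),
              row.names = FALSE)
  }
  write.csv(analysis$q_summary, file.path(outdir, "q_summary.csv"),
            row.names = FALSE)
  write.csv(analysis$q_records, file.path(outdir, "q_records.csv"),
            row.names = FALSE)
  write.csv(analysis$dropout, file.path(outdir, "dropout_tests.csv"),
            row.names = FALSE)
  invisible(outdir)
}

#' Generate the report tables for a completed run
#'
#' Reads a run directory's stage outputs and writes the report files:
#' per-parameter descriptives of the individual posterior medians (N,
#' mean, SD, min, max per occasion), correlation matrices with credible
#' interval strings (Bayes factors above 999 printed as ">999"), growth
#' tables with fixing flags, the q-correlation summary, and a q-density
#' figure. Regenerating from an unchanged run directory is
#' byte-identical.
#'
#' @param run_dir A \code{\link{run_pipeline}} output directory.
#' @param figures Also write the q-correlation density PNG.
#' @return Invisibly, the descriptives data.frame.
#' @export
make_report <- function(run_dir, figures = TRUE) {
  need <- file.path(run_dir, "person_medians.csv")
  if (!file.exists(need)) {
    stop("make_report: missing stage output: ", need, call. = FALSE)
  }
  medians <- read.csv(need, stringsAsFactors = FALSE)
  rows <- list(); k <- 0L
  for (p in c("nu", "a", "tau_plus")) {
    for (tp in sort(unique(medians$time_point))) {
      x <- medians[[p]][medians$time_point == tp]
      x <- x[is.finite(x)]
      k <- k + 1L
      rows[[k]] <- data.frame(parameter = p, time_point = tp,
                              n = length(x), mean = round(mean(x), 3),
                              sd = round(sd(x), 3),
                              min = round(min(x), 3),
                              max = round(max(x), 3))
    }
  }
  desc <- do.call(rbind, rows)
  write.csv(desc, file.path(run_dir, "report_descriptives.csv"),
            row.names = FALSE)

  ro_path <- file.path(run_dir, "rank_order.csv")
  if (file.exists(ro_path)) {
    ro <- read.csv(ro_path, stringsAsFactors = FALSE)
    ro$cell <- sprintf("%.2f [%.2f-%.2f]", ro$rho, ro$ci_lower, ro$ci_upper)
    ro$bf_text <- ifelse(ro$bf10 > 999, ">999", sprintf("%.2f", ro$bf10))
    write.csv(ro[, c("parameter", "t1", "t2", "cell", "bf_text", "n")],
              file.path(run_dir, "report_correlations.csv"),
              row.names = FALSE)
  }
  q_path <- file.path(run_dir, "q_records.csv")
  if (figures && file.exists(q_path)) {
    qr <- read.csv(q_path, stringsAsFactors = FALSE)
    qr <- qr[is.finite(qr$q), ]
    if (nrow(qr) >= 10) {
      grDevices::png(file.path(run_dir, "report_q_density.png"),
                     width = 900, height = 600)
      pairs <- unique(qr[, c("t1", "t2")])
      graphics::plot(NULL, xlim = c(-1, 1), ylim = c(0, 4),
                     xlab = "q correlation", ylab = "density",
                     main = "Profile stability across occasion pairs")
      for (i in seq_len(nrow(pairs))) {
        qi <- qr$q[qr$t1 == pairs$t1[i] & qr$t2 == pairs$t2[i]]
        if (length(qi) >= 10) graphics::lines(stats::density(qi), col = i)
      }
      graphics::legend("topleft",
                       legend = sprintf("T%d-T%d", pairs$t1, pairs$t2),
                       col = seq_len(nrow(pairs)), lty = 1, bty = "n")
      grDevices::dev.off()
    }
  }
  invisible(desc)
}
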