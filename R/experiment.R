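#' Execute one complete simulation run
#'
#' Founders are generated, infected, paired and bred; the offspring pool is
#' infected and added to the population; three capture-history sets are then
#' drawn from the same pooled population — control (bias 1), increased
#' (bias > 1) and decreased (bias < 1) — each fitted with the CJS model and
#' scored with the three outcome metrics, alongside the full-population
#' truth.  Stage seeds are spawned from `run_seed` with [child_seed()] so
#' every stage is independently replayable.
#'
#' @param cfg A [scenario_config()].
#' @param bias_increased Capture-bias multiplier > 1 for this run.
#' @param bias_decreased Capture-bias multiplier < 1 for this run.
#' @param run_seed Integer seed for this run.
#' @return A one-row data frame with the metric set per variant (`full`,
#'   `control`, `increased`, `decreased`), the CJS estimates per sampled
#'   variant, and bookkeeping columns.
#' @export
run_single <- function(cfg, bias_increased, bias_decreased, run_seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  stage <- function(name) set.seed(child_seed(run_seed, STAGES[[name]]))

  stage("founders")
  parents <- make_founders(cfg)
  stage("parent_infection")
  parents <- apply_infection(parents, cfg)
  stage("pairing")
  pairs <- pair_parents(parents)
  stage("reproduction")
  offspring <- reproduce(parents, pairs, cfg)
  stage("offspring_infection")
  offspring <- apply_infection(offspring, cfg)
  pooled <- rbind(parents, offspring)

  row <- list(
    penalty = effective_penalty(cfg),
    genotype_prediction_value = cfg$genotype_prediction_value,
    bias_increased = bias_increased,
    bias_decreased = bias_decreased,
    prevalence = mean(pooled$infected),
    n_offspring = nrow(offspring)
  )

  full <- compute_metrics(parents, offspring, cfg)
  for (nm in names(full)) row[[paste0(nm, "_full")]] <- full[[nm]]

  variants <- list(control = 1.0, increased = bias_increased,
                   decreased = bias_decreased)
  for (v in names(variants)) {
    stage(paste0("sampling_", v))
    ch <- build_capture_histories(pooled, cfg, variants[[v]])
    det <- detected_ids(ch)
    m <- compute_metrics(parents, offspring, cfg, detected = det)
    for (nm in names(m)) row[[paste0(nm, "_", v)]] <- m[[nm]]
    fit <- fit_cjs(ch)
    row[[paste0("p_infected_", v)]] <- fit$p_infected
    row[[paste0("p_uninfected_", v)]] <- fit$p_uninfected
    row[[paste0("delta_p_", v)]] <- fit$delta_p
    row[[paste0("phi_", v)]] <- fit$phi_hat
    row[[paste0("converged_", v)]] <- fit$converged
    row[[paste0("clamped_bouts_", v)]] <- ch$clamped_bouts
    row[[paste0("n_detected_", v)]] <- length(det)
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run a replicated simulation experiment
#'
#' Repeats [run_single()] `n_runs` times.  Fitness experiments perturb the
#' infection penalty uniformly on (0, 1) per run, holding the genotype
#' prediction value at its configured default; relative-risk and
#' allele-change experiments perturb the genotype prediction value, holding
#' the penalty at its default.  Each run also draws one decreased and one
#' increased capture-bias multiplier from the configured intervals.
#'
#' @param outcome `"fitness"`, `"relative_risk"`, or `"allele_change"`.
#' @param cfg A [scenario_config()] (its `scheme`, `n_runs` and `seed` drive
#'   the experiment).
#' @param verbose Print per-run progress to stderr.
#' @return A run table: `n_runs` rows, one per run, with columns from
#'   [run_single()] plus `run`, `outcome`, `scheme`.
#' @export
run_experiment <- function(outcome = c("fitness", "relative_risk",
                                       "allele_change"),
                           cfg = scenario_config(),
                           verbose = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_runs
  set.seed(cfg$seed)
  perturbed <- stats::runif(n)
  bias_dec <- stats::runif(n, cfg$bias_low_range[1], cfg$bias_low_range[2])
  bias_inc <- stats::runif(n, cfg$bias_high_range[1], cfg$bias_high_range[2])
  run_seeds <- vapply(seq_len(n), function(i) child_seed(cfg$seed, i),
                      integer(1))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    if (outcome == "fitness") {
      cfg_i$infection_penalty <- perturbed[i]
      cfg_i$penalty_is_loss <- FALSE
    } else {
      cfg_i$genotype_prediction_value <- perturbed[i]
    }
    rows[[i]] <- cbind(
      data.frame(run = i, outcome = outcome, scheme = cfg$scheme,
                 stringsAsFactors = FALSE),
      run_single(cfg_i, bias_inc[i], bias_dec[i], run_seeds[i])
    )
    if (verbose)
      message(sprintf("[%s/%s] run %d/%d done", outcome, cfg$scheme, i, n))
  }
  do.call(rbind, rows)
}

metric_columns <- function(outcome) {
  switch(outcome,
    fitness = c(raw = "repro_raw", corrected = "repro_corrected"),
    relative_risk = c(value = "relative_risk"),
    allele_change = c(value = "allele_freq_change"),
    stop("unknown outcome: ", outcome, call. = FALSE)
  )
}

#' Summarize an experiment table with the full statistical battery
#'
#' For each sampled variant (control, increased, decreased) and each metric
#' of the experiment's outcome: the SMA slope test against the 1:1 line
#' (sampled on full), the Fligner variance test against the full-population
#' values, and the residual-versus-|delta_p| diagnostic regression; plus
#' Welch t-tests of the CJS detection differences, control versus each
#' biased variant.  Raw p-values are reported; with the battery applied ten
#' times across the study, 0.005 is the Bonferroni-corrected significance
#' threshold.
#'
#' @param table A run table from [run_experiment()] or [read_run_table()].
#' @param outcome Outcome whose metrics to summarize; defaults to the
#'   table's own `outcome` column.
#' @return A data frame, one row per (metric, variant, test), with columns
#'   `estimate`, `ci_low`, `ci_high`, `statistic`, `df`, `r`, `p_value`,
#'   `n`.
#' @export
summarize_experiment <- function(table, outcome = NULL) {
  if (is.null(outcome)) outcome <- unique(table$outcome)[1]
  metrics <- metric_columns(outcome)
  variants <- c("control", "increased", "decreased")
  rows <- list()
  add <- function(metric, variant, test, estimate = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  statistic = NA_real_, df = NA_real_, r = NA_real_,
                  p_value = NA_real_, n = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      outcome = outcome, metric = metric, variant = variant, test = test,
      estimate = estimate, ci_low = ci_low, ci_high = ci_high,
      statistic = statistic, df = df, r = r, p_value = p_value, n = n,
      stringsAsFactors = FALSE)
  }
  for (mlab in names(metrics)) {
    base <- metrics[[mlab]]
    full <- table[[paste0(base, "_full")]]
    for (v in variants) {
      samp <- table[[paste0(base, "_", v)]]
      sma <- sma_slope_test(full, samp, test_slope = 1)
      add(base, v, "sma_slope_vs_1", estimate = sma$slope,
          ci_low = sma$ci_low, ci_high = sma$ci_high,
          statistic = sma$f_stat, df = sma$n - 2, r = sma$r,
          p_value = sma$p_value, n = sma$n)
      fl <- variance_test(samp, full)
      add(base, v, "fligner_vs_full", statistic = fl$statistic,
          df = fl$df, p_value = fl$p_value,
          n = sum(is.finite(samp)) + sum(is.finite(full)))
      rd <- residual_bias_diagnostic(full, samp,
                                     abs(table[[paste0("delta_p_", v)]]))
      add(base, v, "residual_vs_abs_delta_p", estimate = rd$slope,
          statistic = rd$f_stat, df = rd$df, r = rd$adj_r_squared,
          p_value = rd$p_value, n = rd$n)
    }
  }
  for (v in c("increased", "decreased")) {
    tt <- delta_p_group_test(table$delta_p_control,
                             table[[paste0("delta_p_", v)]])
    add("delta_p", v, "welch_t_vs_control", estimate = tt$mean_biased,
        statistic = tt$t, df = tt$df, p_value = tt$p_value,
        n = sum(is.finite(table$delta_p_control)) +
          sum(is.finite(table[[paste0("delta_p_", v)]])))
  }
  do.call(rbind, rows)
}

#' Human-readable experiment report
#'
#' @param summary_table Output of [summarize_experiment()].
#' @param file Connection or path passed to [base::cat()]; default stdout.
#' @return `summary_table`, invisibly.
#' @export
report_summary <- function(summary_table, file = "") {
  fmt <- function(x, d = 4) ifelse(is.na(x), "-", formatC(x, digits = d,
                                                          format = "g"))
  lines <- c(sprintf("Experiment summary: outcome %s",
                     unique(summary_table$outcome)[1]),
             "(Bonferroni-corrected significance threshold: 0.005)")
  for (i in seq_len(nrow(summary_table))) {
    s <- summary_table[i, ]
    lines <- c(lines, sprintf(
      "  %-18s %-9s %-24s est %-9s CI(%s, %s) stat %-9s p %s",
      s$metric, s$variant, s$test, fmt(s$estimate), fmt(s$ci_low),
      fmt(s$ci_high), fmt(s$statistic), fmt(s$p_value, 3)))
  }
  cat(paste(lines, collapse = "\n"), "\n", sep = "", file = file)
  invisible(summary_table)
}
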