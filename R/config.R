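#' Scenario configuration for a simulation run
#'
#' Bundles every tunable parameter of the host-parasite simulation into a
#' validated list.  Defaults are the headline study conditions: 5,000 diploid
#' founders, 2,500 breeding pairs, a base Poisson fecundity of 10 offspring
#' per pair, infection risks of 0.8 (susceptible genotype) and 0.2 (resistant
#' genotype), an individual noise component drawn from N(0.5, 0.2), and five
#' sampling bouts of 500 captures each.
#'
#' @param population_size Number of founders (even, >= 2).
#' @param sample_size Captures per sampling bout (<= pooled population is
#'   checked at sampling time; must not exceed `population_size`).
#' @param n_bouts Number of sampling bouts.
#' @param scheme Genotype-risk scheme: `"heterozygote_advantage"` (only the
#'   heterozygote is resistant) or `"resistance_allele"` (any carrier of the
#'   focal allele "a" is resistant).
#' @param high_risk_prob,low_risk_prob Infection risk assigned to the
#'   susceptible and resistant genotype classes; `high_risk_prob` must exceed
#'   `low_risk_prob`.
#' @param genotype_prediction_value Weight w in \[0,1\] mixing genotype risk
#'   with the individual random risk component.
#' @param noise_mean,noise_sd Mean and SD of the per-individual normal risk
#'   component.
#' @param base_lambda Expected offspring per uninfected pair.
#' @param infection_penalty Proportion of an infected parent's half of the
#'   pair fecundity that is retained (1 = no cost, 0 = total loss).  Set
#'   `penalty_is_loss = TRUE` to supply the lost proportion instead.
#' @param n_runs Replicate runs per experiment.
#' @param bias_low_range,bias_high_range Intervals from which the decreased
#'   and increased capture-bias multipliers are drawn, one draw per run.
#' @param seed Master integer seed.
#' @param penalty_is_loss If `TRUE`, `infection_penalty` is interpreted as
#'   the proportion of offspring lost and internally inverted.
#' @param rounding Rounding rule for the single-infected-parent fecundity
#'   term: `"half-up"` (default) or `"banker"` (IEC 60559, as `round()`).
#' @param require_parent_detected If `TRUE`, sampled reproductive-success
#'   metrics use only parents detected in at least one bout; by default all
#'   parents are treated as enumerable and only offspring detection is
#'   imperfect.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(population_size = 100, sample_size = 20)
#' cfg$base_lambda
#' @export
scenario_config <- function(population_size = 5000L,
                            sample_size = 500L,
                            n_bouts = 5L,
                            scheme = c("heterozygote_advantage",
                                       "resistance_allele"),
                            high_risk_prob = 0.8,
                            low_risk_prob = 0.2,
                            genotype_prediction_value = 0.5,
                            noise_mean = 0.5,
                            noise_sd = 0.2,
                            base_lambda = 10,
                            infection_penalty = 0.5,
                            n_runs = 200L,
                            bias_low_range = c(0.1, 0.9),
                            bias_high_range = c(1.1, 1.9),
                            seed = 1L,
                            penalty_is_loss = FALSE,
                            rounding = c("half-up", "banker"),
                            require_parent_detected = FALSE) {
  scheme <- match.arg(scheme)
  rounding <- match.arg(rounding)
  cfg <- list(
    population_size = as.integer(population_size),
    sample_size = as.integer(sample_size),
    n_bouts = as.integer(n_bouts),
    scheme = scheme,
    high_risk_prob = high_risk_prob,
    low_risk_prob = low_risk_prob,
    genotype_prediction_value = genotype_prediction_value,
    noise_mean = noise_mean,
    noise_sd = noise_sd,
    base_lambda = base_lambda,
    infection_penalty = infection_penalty,
    n_runs = as.integer(n_runs),
    bias_low_range = as.numeric(bias_low_range),
    bias_high_range = as.numeric(bias_high_range),
    seed = as.integer(seed),
    penalty_is_loss = isTRUE(penalty_is_loss),
    rounding = rounding,
    require_parent_detected = isTRUE(require_parent_detected)
  )
  class(cfg) <- "scenario_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid scenario_config: ", msg,
                                 call. = FALSE)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 0 && x <= 1
  if (is.na(cfg$population_size) || cfg$population_size < 2L)
    stop_cfg("population_size must be a positive count >= 2")
  if (cfg$population_size %% 2L != 0L)
    stop_cfg("population_size must be even (parents form exhaustive pairs)")
  if (is.na(cfg$sample_size) || cfg$sample_size < 1L)
    stop_cfg("sample_size must be a positive count")
  if (cfg$sample_size > cfg$population_size)
    stop_cfg("sample_size must not exceed population_size")
  if (is.na(cfg$n_bouts) || cfg$n_bouts < 1L)
    stop_cfg("n_bouts must be a positive count")
  for (nm in c("high_risk_prob", "low_risk_prob",
               "genotype_prediction_value", "infection_penalty")) {
    if (!in01(cfg[[nm]])) stop_cfg(paste(nm, "must lie in [0, 1]"))
  }
  if (cfg$high_risk_prob <= cfg$low_risk_prob)
    stop_cfg("high_risk_prob must exceed low_risk_prob")
  if (!is.numeric(cfg$noise_mean) || !is.numeric(cfg$noise_sd) ||
      cfg$noise_sd < 0)
    stop_cfg("noise_mean must be numeric and noise_sd non-negative")
  if (!is.numeric(cfg$base_lambda) || cfg$base_lambda <= 0)
    stop_cfg("base_lambda must be positive")
  if (is.na(cfg$n_runs) || cfg$n_runs < 1L)
    stop_cfg("n_runs must be a positive count")
  for (nm in c("bias_low_range", "bias_high_range")) {
    rg <- cfg[[nm]]
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1] <= 0 ||
        rg[1] >= rg[2])
      stop_cfg(paste(nm, "must be an increasing positive interval"))
  }
  if (is.na(cfg$seed)) stop_cfg("seed must be an integer")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration\n")
  cat(sprintf("  population %d, sample %d x %d bouts, scheme %s\n",
              x$population_size, x$sample_size, x$n_bouts, x$scheme))
  cat(sprintf("  risks %.2f / %.2f, w = %.2f, noise N(%.2f, %.2f)\n",
              x$high_risk_prob, x$low_risk_prob,
              x$genotype_prediction_value, x$noise_mean, x$noise_sd))
  cat(sprintf("  lambda %.1f, penalty %.2f (%s), %d runs, seed %d\n",
              x$base_lambda, x$infection_penalty,
              if (x$penalty_is_loss) "loss" else "retained",
              x$n_runs, x$seed))
  invisible(x)
}

# Retained proportion of an infected parent's fecundity share, after the
# optional loss/retained inversion.
effective_penalty <- function(cfg) {
  if (cfg$penalty_is_loss) 1 - cfg$infection_penalty else cfg$infection_penalty
}

# round-half-away-from-zero; base round() is banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

rounder_for <- function(cfg) {
  if (cfg$rounding == "half-up") round_half_up else round
}

#' Read a scenario configuration from a YAML file
#'
#' Absent keys take the package defaults; unknown keys are an error so typos
#' cannot silently change a run.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file of flat
#'   `key: value` pairs named as the arguments of [scenario_config()].
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, vals)
}

#' Write a scenario configuration to a YAML file
#'
#' @param cfg A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
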