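# shared fixtures, built in code

# a small, fast configuration for structural tests
small_config <- function(...) {
  defaults <- list(population_size = 200L, sample_size = 50L, n_bouts = 3L,
                   n_runs = 2L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# construct a population data frame from genotype codes
make_pop <- function(genotype, infected = FALSE, generation = "parent",
                     mother_id = NA_integer_, father_id = NA_integer_,
                     id = seq_along(genotype)) {
  data.frame(id = id, genotype = genotype,
             infected = rep_len(infected, length(genotype)),
             generation = rep_len(generation, length(genotype)),
             mother_id = rep_len(mother_id, length(genotype)),
             father_id = rep_len(father_id, length(genotype)),
             stringsAsFactors = FALSE)
}

# wrap a detection matrix + infection flags as a capture_history object
synthetic_history <- function(det, infected, bias_value = 1) {
  det <- as.matrix(det)
  structure(list(
    detections = det,
    individual_id = seq_len(nrow(det)),
    infected = rep_len(infected, nrow(det)),
    genotype = rep("Aa", nrow(det)),
    generation = rep("parent", nrow(det)),
    bias_value = bias_value,
    clamped_bouts = 0L
  ), class = "capture_history")
}

# Bernoulli detection histories for two infection groups at survival 1
simulate_group_histories <- function(n_inf, n_uninf, n_bouts, p_inf,
                                     p_uninf) {
  det <- rbind(
    matrix(stats::rbinom(n_inf * n_bouts, 1L, p_inf), ncol = n_bouts),
    matrix(stats::rbinom(n_uninf * n_bouts, 1L, p_uninf), ncol = n_bouts)
  )
  synthetic_history(det, infected = rep(c(TRUE, FALSE), c(n_inf, n_uninf)))
}

# Independent CJS likelihood oracle: probability of one history by
# exhaustive summation over the occasion after which the animal dies
# (a different decomposition from the chi recursion in the package).
oracle_history_logprob <- function(h, phi, p) {
  T <- length(h)
  f <- which(h == 1L)[1]
  l <- max(which(h == 1L))
  if (f == T) return(0)  # no post-release occasions: probability one
  total <- 0
  for (k in l:T) {
    surv <- if (k < T) phi^(k - f) * (1 - phi) else phi^(T - f)
    obs <- 1
    if (k > f) {
      y <- h[(f + 1L):k]
      obs <- prod(ifelse(y == 1L, p, 1 - p))
    }
    total <- total + surv * obs
  }
  log(total)
}

oracle_negloglik <- function(ch, phi, p_inf, p_uninf) {
  det <- ch$detections
  keep <- rowSums(det) > 0
  det <- det[keep, , drop = FALSE]
  grp <- ch$infected[keep]
  ll <- 0
  for (i in seq_len(nrow(det))) {
    p <- if (grp[i]) p_inf else p_uninf
    ll <- ll + oracle_history_logprob(det[i, ], phi, p)
  }
  -ll
}

# SMA acceptance helper: does the measured slope fall inside the printed
# interval widened by the artifact's own replication uncertainty (half the
# width of its 95% CI)?
expect_slope_in <- function(sma, paper_low, paper_high) {
  halfwidth <- (sma$ci_high - sma$ci_low) / 2
  expect_true(
    sma$slope >= paper_low - halfwidth && sma$slope <= paper_high + halfwidth,
    label = sprintf(
      "slope %.4f inside published interval (%.3f, %.3f) widened by %.4f",
      sma$slope, paper_low, paper_high, halfwidth))
}
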