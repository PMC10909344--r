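#' Offspring counts per parent
#'
#' Counts, for each parent, the number of its offspring — optionally only
#' offspring detected in at least one sampling bout.  Each offspring
#' increments the count of BOTH of its parents (parent-level, not
#' pair-level, reproductive success).
#'
#' @param parents Parent population data frame.
#' @param offspring Offspring population data frame with valid `mother_id`
#'   and `father_id` links.
#' @param detected The ids of detected individuals (e.g. from
#'   [detected_ids()]), or `NULL` to count all offspring.
#' @return Integer vector of counts aligned with `parents` rows.
#' @export
offspring_counts <- function(parents, offspring, detected = NULL) {
  if (!is.null(detected))
    offspring <- offspring[offspring$id %in% detected, , drop = FALSE]
  links <- c(offspring$mother_id, offspring$father_id)
  idx <- match(links, parents$id)
  if (anyNA(idx))
    stop("offspring reference parents absent from the parent table",
         call. = FALSE)
  tabulate(idx, nbins = nrow(parents))
}

#' Difference in reproductive success between infection classes
#'
#' Raw difference: mean offspring count of uninfected parents minus mean
#' offspring count of infected parents.  Corrected difference: the raw
#' difference divided by the mean offspring count of uninfected parents —
#' the normalization that makes the sampled value a proportional (thinning
#' invariant) measure.
#'
#' @param counts Per-parent offspring counts from [offspring_counts()].
#' @param infected Logical infection flags aligned with `counts`.
#' @return List with `raw` and `corrected`; `corrected` is `NA` (flagged via
#'   attribute `reason`) when no uninfected parents exist or their mean
#'   count is zero.
#' @export
reproductive_success_difference <- function(counts, infected) {
  stopifnot(length(counts) == length(infected))
  if (!any(infected) || !any(!infected)) {
    res <- list(raw = NA_real_, corrected = NA_real_)
    attr(res, "reason") <- "an infection class has no parents"
    return(res)
  }
  mean_u <- mean(counts[!infected])
  raw <- mean_u - mean(counts[infected])
  corrected <- if (mean_u > 0) raw / mean_u else NA_real_
  res <- list(raw = raw, corrected = corrected)
  if (is.na(corrected))
    attr(res, "reason") <- "mean uninfected offspring count is zero"
  res
}

# susceptible (high-risk) class indicator under a genotype-risk scheme
is_high_risk <- function(genotype, scheme) {
  n_focal <- focal_allele_count(genotype)
  switch(scheme,
    heterozygote_advantage = n_focal != 1L,
    resistance_allele = n_focal == 0L,
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

#' Relative risk of infection for the susceptible genotype class
#'
#' The proportion infected among the high-risk genotype class divided by the
#' proportion infected among the low-risk class.  Class membership follows
#' the risk scheme: under heterozygote advantage the homozygotes are
#' high-risk; under the resistance-allele scheme only AA (non-carriers) are.
#'
#' @param pop Population data frame (or any subset, e.g. the detected
#'   individuals) with `genotype` and `infected`.
#' @param scheme Genotype-risk scheme.
#' @return Relative risk (> 0), or `NA` flagged with attribute `reason` when
#'   a class is empty or the low-risk class has no infected members.
#' @export
relative_risk <- function(pop, scheme) {
  high <- is_high_risk(pop$genotype, scheme)
  n_high <- sum(high); n_low <- sum(!high)
  if (n_high == 0 || n_low == 0) {
    out <- NA_real_
    attr(out, "reason") <- "a genotype-risk class is empty"
    return(out)
  }
  p_high <- sum(pop$infected[high]) / n_high
  p_low <- sum(pop$infected[!high]) / n_low
  if (p_low == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no infected individuals in the low-risk class"
    return(out)
  }
  p_high / p_low
}

#' Intergenerational change in focal-allele frequency
#'
#' Focal-allele frequency of the offspring generation minus that of the
#' parent generation, computed on whatever individuals are supplied (the
#' full population, or the distinct detected individuals of a sample).
#'
#' @param pop Population data frame containing both generations.
#' @return Frequency change in \[-1, 1\], or `NA` flagged with attribute
#'   `reason` when a generation is absent.
#' @export
allele_frequency_change <- function(pop) {
  par_g <- pop$genotype[pop$generation == "parent"]
  off_g <- pop$genotype[pop$generation == "offspring"]
  if (length(par_g) == 0 || length(off_g) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "a generation is absent from the evaluated set"
    return(out)
  }
  allele_frequency(off_g) - allele_frequency(par_g)
}

#' Compute the three outcome metrics for one variant
#'
#' For the full population pass `detected = NULL`; for a sampled variant
#' pass the distinct detected ids, in which case reproductive success uses
#' detected offspring (all parents remain enumerable unless
#' `require_parent_detected` is set in the configuration) and relative risk
#' and allele-frequency change use only detected individuals.
#'
#' @param parents,offspring Generation data frames with infection assigned.
#' @param cfg A [scenario_config()].
#' @param detected Optional integer ids detected in >= 1 bout.
#' @return Named list: `repro_raw`, `repro_corrected`, `relative_risk`,
#'   `allele_freq_change`.
#' @export
compute_metrics <- function(parents, offspring, cfg, detected = NULL) {
  eval_parents <- parents
  if (!is.null(detected) && cfg$require_parent_detected)
    eval_parents <- parents[parents$id %in% detected, , drop = FALSE]
  counts <- offspring_counts(eval_parents, offspring, detected)
  rs <- reproductive_success_difference(counts, eval_parents$infected)
  pooled <- rbind(parents, offspring)
  if (!is.null(detected))
    pooled <- pooled[pooled$id %in% detected, , drop = FALSE]
  list(
    repro_raw = rs$raw,
    repro_corrected = rs$corrected,
    relative_risk = as.numeric(relative_risk(pooled, cfg$scheme)),
    allele_freq_change = as.numeric(allele_frequency_change(pooled))
  )
}
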