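GENOTYPES <- c("AA", "Aa", "aa")

# number of copies of the focal allele "a" carried by each genotype
focal_allele_count <- function(genotype) {
  cnt <- match(genotype, GENOTYPES) - 1L
  if (anyNA(cnt) && !anyNA(genotype))
    stop("unknown genotype code: ",
         paste(unique(genotype[is.na(cnt)]), collapse = ", "), call. = FALSE)
  cnt
}

#' Frequency of the focal allele in a set of genotypes
#'
#' @param genotype Character vector of `"AA"`, `"Aa"`, `"aa"` codes; allele
#'   "a" is the focal (resistance) allele.
#' @return Allele frequency in \[0, 1\].
#' @export
allele_frequency <- function(genotype) {
  if (length(genotype) == 0) stop("no genotypes supplied", call. = FALSE)
  mean(focal_allele_count(genotype)) / 2
}

#' Generate the founder population
#'
#' Each founder receives two independent fair allele draws at the single
#' diallelic locus, so expected genotype proportions are 0.25 / 0.50 / 0.25
#' and the expected focal-allele frequency is 0.5 (the realized frequency
#' varies binomially around it).  Founders start uninfected.
#'
#' @param cfg A [scenario_config()].
#' @return A population data frame with columns `id`, `genotype`, `infected`,
#'   `generation`, `mother_id`, `father_id`.
#' @export
make_founders <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$population_size
  n_focal <- stats::rbinom(n, 2L, 0.5)
  data.frame(
    id = seq_len(n),
    genotype = GENOTYPES[n_focal + 1L],
    infected = FALSE,
    generation = "parent",
    mother_id = NA_integer_,
    father_id = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Genotype-determined infection risk
#'
#' Under `heterozygote_advantage` only the heterozygote is resistant; under
#' `resistance_allele` any carrier of the focal allele "a" (Aa or aa) is
#' resistant.
#'
#' @param genotype Character vector of genotype codes.
#' @param scheme `"heterozygote_advantage"` or `"resistance_allele"`.
#' @param high_risk_prob,low_risk_prob Risk assigned to susceptible and
#'   resistant classes.
#' @return Numeric vector of genotype risks.
#' @export
genotype_risk <- function(genotype, scheme, high_risk_prob = 0.8,
                          low_risk_prob = 0.2) {
  n_focal <- focal_allele_count(genotype)
  low <- switch(scheme,
    heterozygote_advantage = n_focal == 1L,
    resistance_allele = n_focal >= 1L,
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
  ifelse(low, low_risk_prob, high_risk_prob)
}

#' Individual infection probability
#'
#' Mixes the genotype risk with an individual random component:
#' `clamp(w * g_risk + (1 - w) * r_i, 0, 1)`, where w is the genotype
#' prediction value and r_i the individual's normal noise draw.
#'
#' @param g_risk Genotype risk in \[0, 1\].
#' @param w Genotype prediction weight in \[0, 1\].
#' @param r_i Individual random risk component (any real; the tails are
#'   removed by the clamp).
#' @return Probability in \[0, 1\].
#' @export
infection_probability <- function(g_risk, w, r_i) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("genotype prediction value w must lie in [0, 1]", call. = FALSE)
  if (any(g_risk < 0 | g_risk > 1))
    stop("g_risk must lie in [0, 1]", call. = FALSE)
  pmin(pmax(w * g_risk + (1 - w) * r_i, 0), 1)
}

#' Assign infections to a population
#'
#' Draws one fresh noise value per individual, computes the clamped infection
#' probability, and sets each `infected` flag by an independent Bernoulli
#' trial.  Genotypes are untouched; infection is permanent within a run (the
#' parasite is sublethal and there is no recovery).
#'
#' @param pop Population data frame.
#' @param cfg A [scenario_config()].
#' @return `pop` with updated `infected` column.
#' @export
apply_infection <- function(pop, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (nrow(pop) == 0) stop("population is empty", call. = FALSE)
  g <- genotype_risk(pop$genotype, cfg$scheme, cfg$high_risk_prob,
                     cfg$low_risk_prob)
  r_i <- stats::rnorm(nrow(pop), cfg$noise_mean, cfg$noise_sd)
  p <- infection_probability(g, cfg$genotype_prediction_value, r_i)
  pop$infected <- stats::rbinom(nrow(pop), 1L, p) == 1L
  pop
}

#' Pair parents into breeding pairs
#'
#' A uniformly random perfect matching: every parent appears in exactly one
#' pair, giving `population_size / 2` monogamous pairs that exhaust the
#' founder generation.
#'
#' @param pop Parent population data frame (even row count).
#' @return Integer matrix with columns `mother_id`, `father_id`.
#' @export
pair_parents <- function(pop) {
  n <- nrow(pop)
  if (n < 2L || n %% 2L != 0L)
    stop("parent count must be even and >= 2 for exhaustive pairing",
         call. = FALSE)
  perm <- sample(pop$id)
  m <- matrix(perm, ncol = 2L)
  colnames(m) <- c("mother_id", "father_id")
  m
}

#' Expected offspring number for a pair
#'
#' With no infected parent the pair keeps the base fecundity.  With one
#' infected parent, that parent's half of the fecundity is multiplied by the
#' retained-proportion penalty and rounded before being added back to the
#' healthy half.  With two infected parents the whole base fecundity is
#' scaled by the penalty (unrounded; the Poisson rate need not be integer).
#'
#' @param infected_a,infected_b Logical infection states of the two parents
#'   (vectorized).
#' @param base_lambda Base expected offspring per pair.
#' @param penalty Retained proportion in \[0, 1\] of an infected parent's
#'   share.
#' @param rounder Rounding function for the single-infected case.
#' @return Numeric vector of Poisson rates.
#' @export
offspring_lambda <- function(infected_a, infected_b, base_lambda, penalty,
                             rounder = round_half_up) {
  if (any(penalty < 0 | penalty > 1))
    stop("infection penalty must lie in [0, 1]", call. = FALSE)
  if (any(base_lambda <= 0))
    stop("base_lambda must be positive", call. = FALSE)
  n_inf <- as.integer(infected_a) + as.integer(infected_b)
  half <- base_lambda / 2
  ifelse(n_inf == 0L, base_lambda,
         ifelse(n_inf == 1L, half + rounder(penalty * half),
                penalty * base_lambda))
}

#' Produce the offspring generation
#'
#' Each pair contributes a Poisson number of offspring at the
#' infection-penalized rate; every offspring receives one uniformly chosen
#' allele from each parent, independently per offspring (Mendelian
#' transmission).  Offspring are returned uninfected; infection is assigned
#' afterwards with [apply_infection()] on the offspring pool.
#'
#' @param pop Parent population data frame with infection flags assigned.
#' @param pairs Pair matrix from [pair_parents()].
#' @param cfg A [scenario_config()].
#' @return Offspring population data frame (`generation = "offspring"`,
#'   parent ids filled in, ids continuing after the parents').
#' @export
reproduce <- function(pop, pairs, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  idx_m <- match(pairs[, "mother_id"], pop$id)
  idx_f <- match(pairs[, "father_id"], pop$id)
  if (anyNA(idx_m) || anyNA(idx_f))
    stop("pair ids not found in population", call. = FALSE)
  lam <- offspring_lambda(pop$infected[idx_m], pop$infected[idx_f],
                          cfg$base_lambda, effective_penalty(cfg),
                          rounder_for(cfg))
  n_off <- stats::rpois(length(lam), lam)
  total <- sum(n_off)
  pair_of <- rep.int(seq_along(n_off), n_off)
  # transmitted allele is focal with probability (copies carried)/2
  gm <- focal_allele_count(pop$genotype[idx_m])[pair_of]
  gf <- focal_allele_count(pop$genotype[idx_f])[pair_of]
  allele_m <- stats::rbinom(total, 1L, gm / 2)
  allele_f <- stats::rbinom(total, 1L, gf / 2)
  data.frame(
    id = max(pop$id) + seq_len(total),
    genotype = GENOTYPES[allele_m + allele_f + 1L],
    infected = FALSE,
    generation = "offspring",
    mother_id = pairs[pair_of, "mother_id"],
    father_id = pairs[pair_of, "father_id"],
    stringsAsFactors = FALSE
  )
}

#' Write / read a population table
#'
#' Plain delimited text with header
#' `id, genotype, infected, generation, mother_id, father_id`.
#'
#' @param pop Population data frame.
#' @param path File path.
#' @return The population data frame (read) or `path` invisibly (write).
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "genotype", "infected", "generation",
              "mother_id", "father_id")
  if (!all(needed %in% names(pop)))
    stop("population file lacks columns: ",
         paste(setdiff(needed, names(pop)), collapse = ", "), call. = FALSE)
  pop$infected <- as.logical(pop$infected)
  pop
}
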