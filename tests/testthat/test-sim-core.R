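test_that("founders are uninfected with binomial genotypes at frequency 0.5", {
  cfg <- scenario_config(population_size = 10000L, sample_size = 500L)
  set.seed(11)
  pop <- make_founders(cfg)
  expect_equal(nrow(pop), 10000L)
  expect_false(any(pop$infected))
  expect_true(all(pop$generation == "parent"))
  expect_false(anyDuplicated(pop$id) > 0)
  expect_true(all(pop$genotype %in% c("AA", "Aa", "aa")))
  # focal-allele frequency within 3 binomial SE of 0.5 (2N draws)
  se <- sqrt(0.25 / (2 * 10000))
  expect_lt(abs(allele_frequency(pop$genotype) - 0.5), 3 * se)
  # genotype proportions near 0.25 / 0.50 / 0.25
  props <- table(factor(pop$genotype, c("AA", "Aa", "aa"))) / 10000
  expect_equal(as.numeric(props), c(0.25, 0.5, 0.25), tolerance = 0.05)

  tiny <- make_founders(small_config(population_size = 2L, sample_size = 2L))
  expect_equal(nrow(tiny), 2L)
})

test_that("genotype risk follows the scheme", {
  cases <- list(
    list("Aa", "heterozygote_advantage", 0.2),
    list("AA", "heterozygote_advantage", 0.8),
    list("aa", "heterozygote_advantage", 0.8),
    list("AA", "resistance_allele", 0.8),
    list("Aa", "resistance_allele", 0.2),
    list("aa", "resistance_allele", 0.2)
  )
  for (cs in cases) {
    expect_equal(genotype_risk(cs[[1]], cs[[2]], 0.8, 0.2), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
  }
  expect_error(genotype_risk("AB", "resistance_allele"), "genotype")
  expect_error(genotype_risk("Aa", "nonsense"), "scheme")
})

test_that("infection probability mixes genotype and noise with clamping", {
  expect_equal(infection_probability(0.8, 1.0, 123), 0.8)
  expect_equal(infection_probability(0.2, 0.0, 0.5), 0.5)
  expect_equal(infection_probability(0.2, 0.5, 1.4), 0.8)
  expect_equal(infection_probability(0.8, 0.5, 1.4), 1.0)   # clamp high
  expect_equal(infection_probability(0.2, 0.5, -1.0), 0.0)  # clamp low
  expect_error(infection_probability(0.5, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("infection assignment matches its binomial oracle", {
  # w = 1, all non-carriers, resistance scheme: risk is exactly 0.8
  cfg <- scenario_config(population_size = 10000L,
                         scheme = "resistance_allele",
                         genotype_prediction_value = 1)
  pop <- make_pop(rep("AA", 10000L))
  set.seed(21)
  pop <- apply_infection(pop, cfg)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(mean(pop$infected) - 0.8), 3 * se)

  # degenerate: no genotype risk, no noise -> nobody infected
  cfg0 <- scenario_config(population_size = 1000L, sample_size = 100L,
                          high_risk_prob = 1e-12, low_risk_prob = 0,
                          noise_mean = 0, noise_sd = 0,
                          genotype_prediction_value = 1)
  pop0 <- apply_infection(make_pop(rep(c("AA", "aa"), 500L)), cfg0)
  expect_false(any(pop0$infected))

  # w = 0: infection decoupled from genotype, rate set by the noise mean
  cfgn <- scenario_config(population_size = 10000L,
                          genotype_prediction_value = 0, noise_sd = 0)
  set.seed(22)
  popn <- apply_infection(make_pop(rep(c("AA", "Aa"), 5000L)), cfgn)
  by_g <- tapply(popn$infected, popn$genotype, mean)
  expect_equal(unname(by_g[["AA"]]), 0.5, tolerance = 3 * sqrt(0.25 / 5000))
  expect_equal(unname(by_g[["Aa"]]), 0.5, tolerance = 3 * sqrt(0.25 / 5000))
})

test_that("pairing is a perfect matching over the parents", {
  cfg <- scenario_config()
  set.seed(31)
  pop <- make_founders(cfg)
  pairs <- pair_parents(pop)
  expect_equal(nrow(pairs), 2500L)
  expect_setequal(c(pairs), pop$id)           # conservation, each exactly once
  expect_equal(anyDuplicated(c(pairs)), 0L)

  expect_equal(nrow(pair_parents(make_pop(c("AA", "aa")))), 1L)
  expect_error(pair_parents(make_pop(c("AA", "aa", "Aa"))), "even")
})

test_that("pair fecundity applies the infection penalty as described", {
  expect_equal(offspring_lambda(FALSE, FALSE, 10, 0.3), 10)
  expect_equal(offspring_lambda(TRUE, FALSE, 10, 0.6), 8)   # 5 + round(3)
  expect_equal(offspring_lambda(FALSE, TRUE, 10, 0.6), 8)   # symmetric
  expect_equal(offspring_lambda(TRUE, TRUE, 10, 0), 0)
  expect_equal(offspring_lambda(TRUE, TRUE, 10, 0.37), 3.7) # unrounded
  expect_error(offspring_lambda(TRUE, TRUE, 10, 1.2), "penalty")
  # rounding rule only matters at the half-integer boundary
  expect_equal(offspring_lambda(TRUE, FALSE, 10, 0.1,
                                rounder = round_half_up), 6)  # 5 + ceil(0.5)
  expect_equal(offspring_lambda(TRUE, FALSE, 10, 0.1, rounder = round), 5)
  # loss interpretation switch inverts the retained proportion
  cfg_loss <- small_config(infection_penalty = 0.3, penalty_is_loss = TRUE)
  expect_equal(capturebias:::effective_penalty(cfg_loss), 0.7)
})

test_that("reproduction is Mendelian with Poisson family sizes", {
  cfg <- scenario_config(infection_penalty = 1)
  # certainty cross: AA x aa -> all heterozygotes
  pop <- make_pop(c("AA", "aa"))
  set.seed(41)
  off <- reproduce(pop, pair_parents(pop), cfg)
  expect_true(all(off$genotype == "Aa"))
  expect_true(all(off$generation == "offspring"))
  expect_true(all(off$mother_id %in% pop$id & off$father_id %in% pop$id))

  # Aa x Aa at a large family count: 0.25 / 0.5 / 0.25
  big <- scenario_config(population_size = 2000L, sample_size = 100L,
                         infection_penalty = 1, base_lambda = 10)
  pop2 <- make_pop(rep("Aa", 2000L))
  set.seed(42)
  off2 <- reproduce(pop2, pair_parents(pop2), big)
  props <- table(factor(off2$genotype, c("AA", "Aa", "aa"))) / nrow(off2)
  expect_equal(as.numeric(props), c(0.25, 0.5, 0.25), tolerance = 0.02)

  # no-penalty Poisson oracle: mean offspring per pair ~ base lambda
  set.seed(43)
  founders <- make_founders(cfg)
  founders <- apply_infection(founders, cfg)
  off3 <- reproduce(founders, pair_parents(founders), cfg)
  se <- sqrt(10 / 2500)
  expect_lt(abs(nrow(off3) / 2500 - 10), 3 * se)
})

test_that("offspring alleles are consistent with their parents' genotypes", {
  cfg <- small_config()
  set.seed(44)
  pop <- make_founders(cfg)
  off <- reproduce(pop, pair_parents(pop), cfg)
  gm <- match(off$genotype, c("AA", "Aa", "aa")) - 1L
  pm <- match(pop$genotype[match(off$mother_id, pop$id)],
              c("AA", "Aa", "aa")) - 1L
  pf <- match(pop$genotype[match(off$father_id, pop$id)],
              c("AA", "Aa", "aa")) - 1L
  # each transmitted allele must exist in the corresponding parent
  expect_true(all(gm <= (pm > 0) + (pf > 0)))
  expect_true(all(2L - gm <= (pm < 2) + (pf < 2)))
})

test_that("no selection leaves allele frequency unchanged in expectation", {
  cfg <- scenario_config(population_size = 2000L, sample_size = 100L,
                         infection_penalty = 1)
  set.seed(51)
  pop <- apply_infection(make_founders(cfg), cfg)
  off <- reproduce(pop, pair_parents(pop), cfg)
  p0 <- allele_frequency(pop$genotype)
  # binomial transmission noise over ~2N_off allele draws, family-size
  # variance inflates it; 4 SE bound on a single seeded replicate
  se <- sqrt(p0 * (1 - p0) / (2 * nrow(off))) * 2
  expect_lt(abs(allele_frequency(off$genotype) - p0), 4 * se)
})

test_that("parasite-driven selection raises the resistance allele frequency", {
  cfg <- scenario_config(population_size = 400L, sample_size = 100L,
                         scheme = "resistance_allele",
                         genotype_prediction_value = 0.9,
                         infection_penalty = 0.1)
  set.seed(52)
  gains <- vapply(1:50, function(i) {
    pop <- apply_infection(make_founders(cfg), cfg)
    off <- reproduce(pop, pair_parents(pop), cfg)
    allele_frequency(off$genotype) - allele_frequency(pop$genotype)
  }, numeric(1))
  # sign test over 50 replicated runs
  expect_gte(sum(gains > 0), qbinom(0.999, 50, 0.5))
  expect_gt(mean(gains), 0)
})

test_that("infection probability is monotone in risk and in weight", {
  g_grid <- seq(0, 1, by = 0.1)
  for (w in c(0, 0.3, 0.7, 1)) {
    p <- infection_probability(g_grid, w, 0.5)
    expect_true(all(diff(p) >= 0))
  }
  w_grid <- seq(0, 1, by = 0.1)
  for (g in c(0.6, 0.8, 1)) {  # g above the noise mean
    p <- infection_probability(g, w_grid, 0.5)
    expect_true(all(diff(p) >= -1e-12))
  }
  expect_true(all(infection_probability(runif(100), runif(100),
                                        rnorm(100, 0.5, 0.2)) >= 0))
})
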