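test_that("offspring counts credit both parents and honor detection", {
  parents <- make_pop(c("AA", "aa", "Aa", "Aa"))
  off <- make_pop(rep("Aa", 7), generation = "offspring",
                  mother_id = 1L, father_id = 2L, id = 5:11)
  counts <- offspring_counts(parents, off)
  expect_equal(counts, c(7L, 7L, 0L, 0L))

  # detection union: an offspring detected in any bout counts exactly once
  counts_det <- offspring_counts(parents, off, detected = c(5L, 6L))
  expect_equal(counts_det, c(2L, 2L, 0L, 0L))
  expect_equal(offspring_counts(parents, off, detected = integer(0)),
               rep(0L, 4))

  orphan <- make_pop("Aa", generation = "offspring",
                     mother_id = 99L, father_id = 1L, id = 12L)
  expect_error(offspring_counts(parents, orphan, NULL), "absent")
})

test_that("reproductive-success difference and its correction", {
  counts <- c(10, 10, 6, 6)
  infected <- c(FALSE, FALSE, TRUE, TRUE)
  rs <- reproductive_success_difference(counts, infected)
  expect_equal(rs$raw, 4)
  expect_equal(rs$corrected, 0.4)

  all_inf <- reproductive_success_difference(c(1, 2), c(TRUE, TRUE))
  expect_true(is.na(all_inf$raw))
  expect_match(attr(all_inf, "reason"), "class")
  zero_u <- reproductive_success_difference(c(0, 3), c(FALSE, TRUE))
  expect_true(is.na(zero_u$corrected))
})

test_that("no infection cost means no reproductive-success difference", {
  cfg <- scenario_config(infection_penalty = 1)
  set.seed(81)
  pop <- apply_infection(make_founders(cfg), cfg)
  off <- reproduce(pop, pair_parents(pop), cfg)
  rs <- reproductive_success_difference(offspring_counts(pop, off),
                                        pop$infected)
  # Poisson noise over 2,500 pairs: se of a class-mean difference
  se <- 2 * sqrt(10 / 2500)
  expect_lt(abs(rs$raw), 4 * se)
})

test_that("uniform offspring thinning preserves the corrected difference", {
  cfg <- scenario_config(infection_penalty = 0.3)
  set.seed(82)
  pop <- apply_infection(make_founders(cfg), cfg)
  off <- reproduce(pop, pair_parents(pop), cfg)
  full <- reproductive_success_difference(offspring_counts(pop, off),
                                          pop$infected)
  rate <- 0.1
  thinned_ids <- off$id[runif(nrow(off)) < rate]
  thin <- reproductive_success_difference(
    offspring_counts(pop, off, detected = thinned_ids), pop$infected)
  # raw difference scales with the thinning rate; corrected is invariant
  expect_equal(thin$raw / full$raw, rate, tolerance = 0.35)
  expect_equal(thin$corrected, full$corrected, tolerance = 0.12)
})

test_that("relative risk matches its contingency-table definition", {
  pop <- make_pop(rep(c("AA", "Aa"), c(100L, 100L)),
                  infected = c(rep(c(TRUE, FALSE), c(80L, 20L)),
                               rep(c(TRUE, FALSE), c(20L, 80L))))
  expect_equal(relative_risk(pop, "resistance_allele"), 4)

  equal <- make_pop(rep(c("AA", "Aa"), each = 50L),
                    infected = rep(rep(c(TRUE, FALSE), each = 25L), 2L))
  expect_equal(relative_risk(equal, "resistance_allele"), 1)

  # heterozygote advantage pools both homozygotes as high-risk
  het <- make_pop(rep(c("AA", "aa", "Aa"), c(30L, 30L, 40L)),
                  infected = c(rep(TRUE, 45), rep(FALSE, 15),
                               rep(TRUE, 10), rep(FALSE, 30)))
  expect_equal(relative_risk(het, "heterozygote_advantage"),
               (45 / 60) / (10 / 40))

  rr <- relative_risk(make_pop(c("AA", "Aa"), infected = c(TRUE, FALSE)),
                      "resistance_allele")
  expect_true(is.na(rr))
  expect_match(attr(rr, "reason"), "low-risk")
})

test_that("relative risk agrees with brute-force enumeration on 20 hosts", {
  set.seed(83)
  for (rep in 1:20) {
    pop <- make_pop(sample(c("AA", "Aa", "aa"), 20, replace = TRUE),
                    infected = runif(20) < 0.5)
    for (scheme in c("heterozygote_advantage", "resistance_allele")) {
      high <- if (scheme == "heterozygote_advantage")
        pop$genotype != "Aa" else pop$genotype == "AA"
      # direct 2x2 tabulation, computed independently
      tab <- table(factor(high, c(FALSE, TRUE)),
                   factor(pop$infected, c(FALSE, TRUE)))
      n_high <- sum(tab["TRUE", ]); n_low <- sum(tab["FALSE", ])
      expected <- if (n_high == 0 || n_low == 0 ||
                      tab["FALSE", "TRUE"] == 0) NA_real_ else
        (tab["TRUE", "TRUE"] / n_high) / (tab["FALSE", "TRUE"] / n_low)
      expect_equal(as.numeric(relative_risk(pop, scheme)), expected)
    }
  }
})

test_that("allele-frequency change is offspring minus parent frequency", {
  both_het <- rbind(make_pop(rep("Aa", 10)),
                    make_pop(rep("Aa", 10), generation = "offspring",
                             id = 11:20))
  expect_equal(allele_frequency_change(both_het), 0)

  pop <- rbind(make_pop(rep(c("AA", "aa"), 50L)),
               make_pop(rep(c("aa", "AA"), c(60L, 40L)),
                        generation = "offspring", id = 101:200))
  expect_equal(allele_frequency_change(pop), 0.1)

  only_parents <- make_pop(rep("Aa", 5))
  afc <- allele_frequency_change(only_parents)
  expect_true(is.na(afc))
  expect_match(attr(afc, "reason"), "generation")
})

test_that("null configuration centres both selection metrics", {
  cfg <- scenario_config(population_size = 1000L, sample_size = 100L,
                         infection_penalty = 1,
                         genotype_prediction_value = 0)
  set.seed(84)
  res <- t(vapply(1:40, function(i) {
    pop <- apply_infection(make_founders(cfg), cfg)
    off <- reproduce(pop, pair_parents(pop), cfg)
    off <- apply_infection(off, cfg)
    m <- compute_metrics(pop, off, cfg)
    c(m$repro_raw, m$allele_freq_change, m$relative_risk)
  }, numeric(3)))
  expect_lt(abs(mean(res[, 1])), 3 * sd(res[, 1]) / sqrt(40))
  expect_lt(abs(mean(res[, 2])), 3 * sd(res[, 2]) / sqrt(40))
  expect_equal(mean(res[, 3]), 1, tolerance = 0.05)
})
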