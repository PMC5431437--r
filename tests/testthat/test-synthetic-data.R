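test_that("generators are fully deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123)
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a, b)
  sa <- generate_scores(a$library, config = cfg)
  sb <- generate_scores(b$library, config = cfg)
  expect_identical(sa, sb)
  expect_identical(generate_formula_pair(cfg), generate_formula_pair(cfg))
  # a different seed changes the draw
  expect_false(identical(
    a$library$ob, generate_library(simulation_config(seed = 124))$library$ob))
})

test_that("library generator honors its mixture design", {
  all_pass <- simulation_config(
    seed = 5, n_compounds = 200,
    ob_distribution = list(p_high = 1, low = c(2, 28), high = c(40, 90)),
    dl_distribution = list(p_high = 1, low = c(0.01, 0.1),
                           high = c(0.3, 0.9)))
  gl <- generate_library(all_pass)
  expect_true(all(gl$truth$strict_pass))
  expect_true(all(screen_library(gl$library)$strict_pass ==
                    gl$library$compound_id))

  # strict-pass rate within 3 binomial standard errors of the design rate
  cfg <- simulation_config(seed = 99, n_compounds = 10000)
  gl2 <- generate_library(cfg)
  p_design <- formulanet:::mixture_pass_prob(cfg$ob_distribution, 30) *
    formulanet:::mixture_pass_prob(cfg$dl_distribution, 0.18)
  p_hat <- mean(gl2$truth$strict_pass)
  se <- sqrt(p_design * (1 - p_design) / 10000)
  expect_lt(abs(p_hat - p_design), 3 * se)

  # truth labels agree with the screen itself
  expect_setequal(screen_library(gl2$library)$strict_pass,
                  gl2$truth$compound_id[gl2$truth$strict_pass])

  # herb attribution stays within the configured herbs, never empty
  expect_true(all(unlist(gl2$library$herbs) %in% names(cfg$herbs)))
})

test_that("score generator plants a truth set the consensus filter recovers exactly", {
  cfg <- simulation_config(seed = 21, n_compounds = 25, n_targets = 20,
                           planted_shared_fraction = 0.8, n_b_specific = 2)
  gl <- generate_library(cfg)
  sc <- generate_scores(gl$library, config = cfg)
  expect_true(all(sc$scores$rf_score >= 0 & sc$scores$rf_score <= 1))
  expect_true(all(sc$scores$svm_score >= 0 & sc$scores$svm_score <= 1))
  kept <- consensus_filter(sc$scores)
  key <- function(d) paste(d$compound_id, d$target_id)
  expect_setequal(key(kept), key(sc$truth[sc$truth$is_true, ]))

  # independent per-row scan agrees with the planted count
  n_kept <- sum(sc$scores$rf_score > 0.7 & sc$scores$svm_score > 0.8 &
                  sc$scores$rf_score > 0.5 & sc$scores$svm_score > 0.5)
  expect_equal(n_kept, sum(sc$truth$is_true))

  # zero interaction rate: nothing survives
  cfg0 <- simulation_config(seed = 21, n_compounds = 10, n_targets = 10,
                            true_interaction_rate = 0,
                            planted_shared_fraction = 0.8, n_b_specific = 1)
  sc0 <- generate_scores(generate_library(cfg0)$library, config = cfg0)
  expect_equal(nrow(consensus_filter(sc0$scores)), 0)
})

test_that("formula pair recovers planted shared fractions exactly in noise-free mode", {
  for (f in c(0.5, 0.75, 0.9, 0.97)) {
    cfg <- simulation_config(seed = 17, n_targets = 100,
                             planted_shared_fraction = f, n_b_specific = 2)
    pair <- generate_formula_pair(cfg)
    cmp <- compare_formulae(pair$net_a, pair$net_b, pair$annotations)
    expect_equal(cmp$shared_fraction, round(f * 100) / 100,
                 tolerance = 1e-12)
    expect_setequal(cmp$shared_targets, pair$truth$shared)
    expect_setequal(cmp$b_specific, pair$truth$b_specific)
  }

  # planted fraction 1: identical target sets
  cfg1 <- simulation_config(seed = 2, n_targets = 30,
                            planted_shared_fraction = 1, n_b_specific = 0)
  pair1 <- generate_formula_pair(cfg1)
  expect_setequal(pair1$net_a$targets, pair1$net_b$targets)

  # one disease-linked removed-specific target flips the verdict
  cfg2 <- simulation_config(seed = 3, n_targets = 50, n_b_specific = 3,
                            planted_shared_fraction = 0.9,
                            n_disease_linked_b_specific = 1)
  pair2 <- generate_formula_pair(cfg2)
  cmp2 <- compare_formulae(pair2$net_a, pair2$net_b, pair2$annotations)
  expect_false(removal_verdict(cmp2)$removable)
})

test_that("verdicts match the generating truth over a parameter grid", {
  for (f in c(0.5, 0.95)) {
    for (n_bad in 0:1) {
      cfg <- simulation_config(seed = 31, n_targets = 60,
                               planted_shared_fraction = f,
                               n_b_specific = 2,
                               n_disease_linked_b_specific = n_bad)
      pair <- generate_formula_pair(cfg)
      cmp <- compare_formulae(pair$net_a, pair$net_b, pair$annotations)
      v <- removal_verdict(cmp, shared_fraction_threshold = 0.90)
      expect_equal(isTRUE(v$removable),
                   cmp$shared_fraction >= 0.90 && n_bad == 0)
    }
  }
})

test_that("config validation catches inconsistent plans", {
  expect_error(simulation_config(seed = 1, planted_shared_fraction = 0.99,
                                 n_targets = 100, n_b_specific = 5),
               "inconsistent")
  expect_error(simulation_config(seed = 1, n_b_specific = 1,
                                 n_disease_linked_b_specific = 2),
               "exceeds")
  expect_error(simulation_config(seed = 1, ob_distribution = list(
    p_high = 0.5, low = c(30, 30), high = c(40, 90))),
    "zero spread")
  expect_error(simulation_config(seed = 1, true_interaction_rate = 1.5),
               "\\[0, 1\\]")
  expect_error(simulation_config(seed = 2^31), "seed")
})
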