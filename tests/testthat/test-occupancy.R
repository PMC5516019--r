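test_that("state counting is the product of per-site level counts", {
  expect_identical(count_states(integer(0)), 1)
  expect_identical(count_states(c(2L, 1L, 0L)), 6)
  expect_identical(count_states(rep(2L, 12)), 531441)
  expect_identical(count_states(kv12_affinity_table()),
                   3^8 * 2^4) # 8 saturable + 4 single-occupancy sites
})

test_that("state constants factorize over sites", {
  cst <- toy_constants()
  expect_identical(state_constant(cst, c(0, 0, 0)), 1)
  expect_equal(state_constant(cst, c(t2 = 1)), 3)
  expect_equal(state_constant(cst, c(2, 1, 1)), 1 * 3 * 0.5)
  # the printed single-site constants multiply into two-site state constants
  kv <- binding_constants(kv12_affinity_table(), ref_reservoir())
  expect_equal(state_constant(kv, c(S10 = 1, S11 = 1)),
               2.51e1 * 4.19e1, tolerance = 0.05)
  expect_error(state_constant(cst, c(3, 0, 0)), "0..n_max")
  expect_error(state_constant(cst, c(bogus = 1)), "unknown site")
})

test_that("enumerated probabilities follow the weight definition", {
  cst <- toy_constants()
  # zero concentration: all mass on the empty state
  d0 <- state_probabilities(cst, 0)
  empty <- rowSums(d0$states) == 0
  expect_equal(d0$prob[empty], 1)
  expect_equal(sum(d0$prob), 1, tolerance = 1e-9)
  # brute-force oracle straight from the definition
  K <- list(c(2, 1), 3, c(0.5, 0.25))
  for (conc in c(0.1, 1, 7)) {
    bf <- brute_force_probs(K, conc)
    d <- state_probabilities(cst, conc)
    expect_equal(d$prob[order(apply(d$states, 1, paste, collapse = ""))],
                 bf$prob[order(apply(bf$states, 1, paste, collapse = ""))],
                 tolerance = 1e-12)
  }
  # two one-ligand sites with K = 2 and 3 at 1 mM: rho(both) = 6/12
  two <- toy_constants(list(2, 3))
  d <- state_probabilities(two, 1)
  both <- rowSums(d$states) == 2
  expect_equal(d$prob[both], 6 / 12, tolerance = 1e-12)
})

test_that("factorized and enumerated modes agree everywhere they overlap", {
  kv <- binding_constants(kv12_affinity_table(), ref_reservoir())
  sub <- kv[kv$site_id %in% sprintf("S%02d", c(1, 2, 9, 10, 5)), ]
  class(sub) <- class(kv)
  attr(sub, "ctx") <- attr(kv, "ctx")
  for (conc in c(0.01, 1, 50)) {
    enum <- state_probabilities(sub, conc)
    fact <- factorized_distribution(sub, conc)
    me <- marginal_occupancy(enum)
    mf <- marginal_occupancy(fact)
    for (s in names(me)) expect_equal(me[[s]], mf[[s]], tolerance = 1e-10)
    expect_equal(macrostate_probabilities(enum),
                 macrostate_probabilities(fact), tolerance = 1e-10)
    expect_equal(mean_occupancy(enum), mean_occupancy(fact),
                 tolerance = 1e-10)
  }
})

test_that("marginals are normalized and respond to concentration limits", {
  cst <- toy_constants()
  m0 <- marginal_occupancy(cst, concentration = 0)
  expect_equal(m0$t1, c(`0` = 1, `1` = 0, `2` = 0))
  m <- marginal_occupancy(cst, concentration = 2)
  expect_true(all(abs(vapply(m, sum, numeric(1)) - 1) < 1e-12))
  # closed form for one site: rho(n) ~ c^n K_n
  w <- c(1, 2 * 2, 2^2 * 1)
  expect_equal(unname(m$t1), w / sum(w), tolerance = 1e-12)
  expect_error(marginal_occupancy(cst, concentration = 1, sites = "zz"),
               "unknown site")
  expect_error(marginal_occupancy(cst), "concentration")
})

test_that("macrostate probabilities from convolution match enumeration", {
  cst <- toy_constants(list(c(2, 1), 3, c(0.5, 0.25), 0.1))
  for (conc in c(0.5, 3)) {
    enum <- macrostate_probabilities(state_probabilities(cst, conc))
    conv <- macrostate_probabilities(cst, conc)
    expect_equal(enum, conv, tolerance = 1e-12)
    expect_equal(sum(conv), 1, tolerance = 1e-12)
  }
  # one site, closed form rho(2) = b/(1+a+b) with weights (1, a, b)
  one <- toy_constants(list(c(4, 2.5)))
  p <- macrostate_probabilities(one, 1)
  expect_equal(unname(p["2"]), 2.5 / (1 + 4 + 2.5), tolerance = 1e-12)
})

test_that("ensemble averages are probability-weighted means", {
  cst <- toy_constants()
  d <- state_probabilities(cst, 1)
  expect_equal(ensemble_average(d, function(st) 1), 1, tolerance = 1e-12)
  expect_equal(ensemble_average(d, rowSums(d$states)), mean_occupancy(d),
               tolerance = 1e-12)
  # one site with weights (1, a): <n> = a/(1+a)
  one <- toy_constants(list(5))
  d1 <- state_probabilities(one, 1)
  expect_equal(ensemble_average(d1, function(st) sum(st)), 5 / 6,
               tolerance = 1e-12)
  expect_error(ensemble_average(d, c(1, 2)), "per state")
})

test_that("titration curves are monotone with the dilute slope sum(K1)", {
  kv <- binding_constants(kv12_affinity_table(), ref_reservoir())
  conc <- c(0, 10^seq(-3, 3, by = 0.5))
  curve <- suppressWarnings(titration_curve(kv, conc))
  expect_equal(curve$n_mean[1], 0)
  expect_true(all(diff(curve$n_mean) >= 0))
  for (col in grep("^n_S", names(curve))) {
    expect_true(all(diff(curve[[col]]) >= -1e-12))
  }
  # saturation: <n> -> sum(n_max) = 20 at very high concentration
  sat <- suppressWarnings(mean_occupancy(kv, 1e9))
  expect_equal(sat, sum(max_occupancy(kv)), tolerance = 1e-3)
  # dilute limit slope
  eps <- 1e-9
  slope <- mean_occupancy(kv, eps) / eps
  expect_equal(slope, dilute_limit_slope(kv), tolerance = 1e-5)
  # empty-state probability is non-increasing in concentration
  p_empty <- vapply(c(0.1, 1, 10, 100), function(cc) {
    marginal_occupancy(kv, cc)$S10[["0"]]
  }, numeric(1))
  expect_true(all(diff(p_empty) <= 0))
})

test_that("oversized systems are pushed to the factorized path and 1 M warns", {
  kv <- binding_constants(kv12_affinity_table(), ref_reservoir())
  expect_error(state_probabilities(kv, 1, enumeration_cap = 1000),
               "factorized_distribution")
  expect_warning(factorized_distribution(kv, 1000), "1 M")
  expect_warning(state_probabilities(toy_constants(), 2000), "1 M")
})

test_that("ranked state tables sort by probability with lexicographic ties", {
  cst <- toy_constants(list(1, 1))
  d <- state_probabilities(cst, 1) # all four states equally probable
  tab <- sorted_states(d)
  expect_identical(tab$state, c("00", "01", "10", "11"))
  kv <- toy_constants()
  tab2 <- sorted_states(state_probabilities(kv, 1), top = 3)
  expect_identical(nrow(tab2), 3L)
  expect_true(all(diff(tab2$prob) <= 0))
})
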