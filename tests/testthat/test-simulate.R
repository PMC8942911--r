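test_that("2HTM simulation is seed-reproducible and sums to the design", {
  sp <- scenario_spec("null", seed = 8)
  a <- simulate_2htm(sp, replicate = 1)
  b <- simulate_2htm(sp, replicate = 1)
  expect_identical(a, b)
  c2 <- simulate_2htm(sp, replicate = 2)
  expect_false(identical(a$counts, c2$counts))
  d <- sp$design
  tot <- a$counts$r1 + a$counts$r2 + a$counts$r3 + a$counts$r4
  expect_equal(tot, unname(mapply(
    function(cond, cl) pooled_total(d, cond, cl),
    a$counts$condition, a$counts$item_class)))
})

test_that("certain detection with certain confidence rates every target 4", {
  d <- experiment_design(c(g = 3), c(target = 50, lure = 10))
  p <- list(g = list(Do = 1 - 1e-12, s = 1 - 1e-12,
                     Dn = c(lure = 0.5), n = c(lure = 0.5),
                     g = 0.5, a_o = 0.5, a_n = 0.5))
  sim <- simulate_2htm(generator_spec("2htm", p, d, seed = 1))
  expect_true(all(sim$trials$rating[sim$trials$item_class == "target"] == 4))
})

test_that("simulated frequencies converge to the enumerated probabilities", {
  d <- experiment_design(c(c1 = 1),
                         c(target = 200000, category_lure = 200000,
                           colour_lure = 200000, critical_lure = 200000))
  base <- scenario_spec("null")$params$colour
  sim <- simulate_2htm(generator_spec("2htm", list(c1 = base), d, seed = 21))
  m <- build_2htm_model()  # single unlabelled condition
  flat <- mptsdt:::flatten_htm_params(base)
  pr <- category_probabilities(m, flat[m$slots])
  k <- sim$counts
  for (cl in names(d$trials_per_class)) {
    obs <- as.numeric(k[k$item_class == cl, c("r1", "r2", "r3", "r4")])
    expect_lt(max(abs(obs / sum(obs) - pr[[cl]])), 0.005)
  }
})

test_that("UVSDT simulation: null parameters make classes indistinguishable", {
  d <- experiment_design(c(g = 1), c(target = 50000, lure = 50000))
  sp <- generator_spec("uvsdt",
                       list(g = list(criteria = c(-0.5, 0.3, 1),
                                     classes = list(target = c(0, 1),
                                                    lure = c(0, 1)))),
                       d, seed = 5)
  k <- simulate_uvsdt(sp)$counts
  po <- as.numeric(k[k$item_class == "target", c("r1", "r2", "r3", "r4")])
  pn <- as.numeric(k[k$item_class == "lure", c("r1", "r2", "r3", "r4")])
  expect_lt(max(abs(po / sum(po) - pn / sum(pn))), 0.01)
})

test_that("infinite criteria collapse ratings to a single category", {
  d <- experiment_design(c(g = 1), c(target = 100))
  mk <- function(cr) generator_spec(
    "uvsdt", list(g = list(criteria = cr, classes = list(target = c(1, 1.2)))),
    d, seed = 2)
  lo <- simulate_uvsdt(mk(c(-Inf, -Inf, -Inf)))
  expect_true(all(lo$trials$rating == 4))
  hi <- simulate_uvsdt(mk(c(Inf, Inf, Inf)))
  expect_true(all(hi$trials$rating == 1))
})

test_that("scenario presets encode the intended condition differences", {
  w <- scenario_spec("word_like")
  expect_equal(unname(w$params$category$Dn["colour_lure"]), 0.75)
  expect_equal(unname(w$params$colour$Dn["colour_lure"]), 0.35)
  p <- scenario_spec("picture_like")
  expect_equal(unname(p$params$colour$Dn["category_lure"]), 0.75)
  expect_gt(p$design$conditions[["category"]], 30)  # picture design sizes
  n <- scenario_spec("null")
  expect_identical(n$params$colour, n$params$category)
  expect_error(scenario_spec("bogus"))
})

test_that("participant heterogeneity widens the pooled rating spread", {
  d <- experiment_design(c(g = 60), c(target = 40, lure = 40))
  p <- list(g = list(Do = 0.6, s = 0.85, Dn = c(lure = 0.5),
                     n = c(lure = 0.8), g = 0.4, a_o = 0.6, a_n = 0.6))
  hom <- simulate_2htm(generator_spec("2htm", p, d, seed = 9))
  het <- simulate_2htm(generator_spec("2htm", p, d, seed = 9,
                                      heterogeneity = 4))
  # per-participant hit counts vary more under heterogeneity
  hits <- function(sim) tapply(
    sim$trials$rating >= 3, sim$trials$participant, sum)
  expect_gt(stats::var(hits(het)[1:60]), stats::var(hits(hom)[1:60]))
})

test_that("word-like effect size gives high power for the condition test", {
  sp <- scenario_spec("word_like", seed = 17)
  reps <- 30
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    k <- simulate_2htm(sp, replicate = r)$counts
    f <- fit_2htm_joint(k, "word_like", starts = 2, seed = r)
    tst <- test_parameter_across_conditions(f, "Dn.colour_lure", starts = 2)
    rej[r] <- tst$delta_G2 > stats::qchisq(0.95, 1)
  }
  expect_gt(mean(rej), 0.9)
})
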