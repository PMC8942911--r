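test_that("category probabilities match the branch-path enumerator", {
  models <- list(single = build_2htm_model(),
                 joint = build_2htm_model(c("colour", "category")),
                 combined = build_combined_2htm())
  set.seed(2)
  for (m in models) {
    for (i in 1:25) {
      pars <- random_slot_values(m)
      got <- category_probabilities(m, pars)
      want <- oracle_probs(m, as.list(pars))
      expect_equal(got, want[names(got)], tolerance = 1e-12)
      expect_true(all(abs(vapply(got, sum, 0) - 1) < 1e-12))
    }
  }
})

test_that("hand-enumerated lure-tree probabilities are reproduced", {
  m <- build_2htm_model(lure_types = "lure")
  p <- c("Do" = 0.5, "s" = 0.5, "Dn.lure" = 0.6, "n.lure" = 0.8,
         "g" = 0.2, "a_o" = 0.5, "a_n" = 0.9)
  pr <- category_probabilities(m, p)$lure
  expect_equal(unname(pr[c("1", "2", "3", "4")]),
               c(0.768, 0.152, 0.04, 0.04), tolerance = 1e-12)
  # certain detection and confident responding puts all target mass on 4
  p2 <- replace(p, c("Do", "s"), c(1 - 1e-12, 1 - 1e-12))
  pt <- category_probabilities(m, p2)$target
  expect_equal(unname(pt["4"]), 1, tolerance = 1e-9)
  # pure symmetric guessing spreads target mass uniformly
  p3 <- replace(p, c("Do", "g", "a_o", "a_n"), c(1e-12, 0.5, 0.5, 0.5))
  expect_equal(unname(category_probabilities(m, p3)$target),
               rep(0.25, 4), tolerance = 1e-9)
  expect_error(category_probabilities(m, p[-1]), "unbound")
})

test_that("ML estimate on a one-parameter tree matches a fine grid search", {
  m <- toy_one_param()
  f <- fit_mpt(m, list(t = c(a = 30, b = 70)), starts = 3)
  grid <- seq(1e-6, 1 - 1e-6, by = 1e-6)
  ll <- 30 * log(grid) + 70 * log(1 - grid)
  expect_equal(unname(f$estimates["theta"]), grid[which.max(ll)],
               tolerance = 2e-6)
  expect_equal(f$df, 0L)
})

test_that("data generated at the model's expected counts fit perfectly", {
  m <- build_2htm_model(lure_types = c("category_lure", "colour_lure"))
  truth <- c("Do" = 0.6, "s" = 0.8, "g" = 0.45, "a_o" = 0.6, "a_n" = 0.7,
             "Dn.category_lure" = 0.5, "n.category_lure" = 0.75,
             "Dn.colour_lure" = 0.3, "n.colour_lure" = 0.65)
  pr <- category_probabilities(m, truth)
  dat <- lapply(pr, function(p) p * 4000)
  f <- fit_mpt(m, dat, starts = 5)
  expect_lt(f$G2, 1e-6)
  # raw parameters are only recoverable once the guessing ridge is pinned
  f_id <- fit_mpt(m, dat, mpt_constraints(fixed = c(g = truth[["g"]])),
                  starts = 5)
  expect_lt(f_id$G2, 1e-6)
  nm <- setdiff(names(truth), "g")
  expect_equal(f_id$estimates[nm], truth[nm], tolerance = 1e-3)
})

test_that("fits are invariant to branch and tree permutation", {
  m <- build_2htm_model(c("colour", "category"))
  cts <- lop_counts()
  dat <- mptsdt:::htm_tree_data(cts[cts$experiment == "e1", ])
  f1 <- fit_mpt(m, dat, starts = 4)
  set.seed(9)
  b <- m$branches[sample(nrow(m$branches)), ]
  m2 <- mpt_model(b)
  f2 <- fit_mpt(m2, dat[sample(names(dat))], starts = 4)
  expect_equal(f2$G2, f1$G2, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  # fitted cell probabilities (identified) are permutation-invariant;
  # raw estimates need not be, since the guessing ridge is flat
  key1 <- paste(f1$model$cells$tree, f1$model$cells$category)
  key2 <- paste(f2$model$cells$tree, f2$model$cells$category)
  expect_equal(f2$expected[order(key2)], f1$expected[order(key1)],
               tolerance = 1e-4)
})

test_that("equality constraints never improve the likelihood", {
  set.seed(31)
  cts <- sim_null_counts(seed = 31)
  f <- fit_2htm_joint(cts, "null", starts = 4)
  for (par in c("Do", "s", "Dn.critical_lure")) {
    tst <- test_parameter_across_conditions(f, par, starts = 4)
    expect_gte(tst$delta_G2, -0.01)
    expect_equal(tst$df, 1L)
  }
  # constraining a parameter at its unconstrained ML value changes nothing
  con <- mpt_constraints(fixed = stats::setNames(
    f$estimates["Do[colour]"], "Do[colour]"))
  f0 <- fit_mpt(f$model, f$data, con, starts = 4)
  expect_lt(f0$G2 - f$G2, 1e-4)
})

test_that("identifiability check ranks shipped and pathological models", {
  # the joint rating 2HTM with fully shared guessing has a flat ridge: the
  # guessing rate g trades off exactly against detection and confidence, so
  # the Jacobian rank is 18, one short of the 19 free parameters
  joint <- build_2htm_model(c("colour", "category"))
  chk <- check_identifiability(joint, n_points = 3)
  expect_equal(chk$n_free, 19L)
  expect_equal(chk$ranks, rep(18L, 3))
  expect_false(chk$identified)
  # fixing g removes the ridge
  chk_g <- check_identifiability(
    joint, mpt_constraints(fixed = c(g = 0.4)), n_points = 3)
  expect_equal(chk_g$n_free, 18L)
  expect_true(chk_g$identified)

  # two parameters appearing only as a product are not identified
  bad <- mpt_model(data.frame(
    tree = "t", category = c("x", "y", "y"),
    path = c("a*b", "a*(1-b)", "(1-a)")))
  expect_false(check_identifiability(bad, n_points = 3)$identified)

  # saturated tree: rank equals the free categories
  sat <- mpt_model(data.frame(
    tree = "t", category = c("1", "2", "3", "4"),
    path = c("p1", "(1-p1)*p2", "(1-p1)*(1-p2)*p3",
             "(1-p1)*(1-p2)*(1-p3)")))
  expect_equal(check_identifiability(sat, n_points = 2)$ranks, c(3L, 3L))
})

test_that("eqn files round-trip the model", {
  m <- build_2htm_model(c("colour", "category"))
  f <- tempfile(fileext = ".eqn")
  write_eqn(m, f)
  m2 <- read_eqn(f)
  set.seed(5)
  pars <- random_slot_values(m)
  expect_equal(category_probabilities(m2, pars),
               category_probabilities(m, pars))
  writeLines(c("t a", "too many fields here x"), f)
  expect_error(read_eqn(f), "malformed")
})

test_that("bootstrap requires resamples and flags failures sensibly", {
  m <- toy_one_param()
  f <- fit_mpt(m, list(t = c(a = 30, b = 70)), starts = 2)
  expect_error(bootstrap_parameters(f, B = 0), "positive")
  b <- bootstrap_parameters(f, B = 50, seed = 4)
  expect_equal(b$n_failed, 0)
  # binomial sampling theory: SD of theta-hat ~ sqrt(p(1-p)/n)
  expect_equal(unname(b$sd["theta"]), sqrt(0.3 * 0.7 / 100),
               tolerance = 0.35)
  # reproducible under the same seed
  b2 <- bootstrap_parameters(f, B = 50, seed = 4)
  expect_identical(b$draws, b2$draws)
})
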