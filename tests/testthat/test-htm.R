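test_that("2HTM trees have the canonical structure", {
  m <- build_2htm_model(lure_types = c("category_lure", "colour_lure",
                                       "critical_lure"))
  b <- m$branches
  for (tr in m$trees) {
    expect_equal(sum(b$tree == tr), 6L)
    expect_setequal(unique(b$category[b$tree == tr]), c("1", "2", "3", "4"))
  }
  # lure detection off: lure tree equals the target tree's guessing subtree
  p <- c("Do" = 1e-12, "s" = 0.7, "g" = 0.3, "a_o" = 0.55, "a_n" = 0.8,
         "Dn.category_lure" = 1e-12, "n.category_lure" = 0.5,
         "Dn.colour_lure" = 1e-12, "n.colour_lure" = 0.5,
         "Dn.critical_lure" = 1e-12, "n.critical_lure" = 0.5)
  pr <- category_probabilities(m, p)
  for (tr in m$trees[-1])
    expect_equal(pr[[tr]], pr$target, tolerance = 1e-9)
})

test_that("degrees of freedom match the published bookkeeping", {
  cts <- lop_counts()
  f1 <- fit_2htm_joint(cts, "e1", starts = 2)
  expect_equal(length(f1$estimates), 19L)
  expect_equal(f1$df, 5L)
  fc <- fit_2htm_combined(cts, starts = 2)
  expect_equal(length(fc$estimates), 38L)
  expect_equal(fc$df, 10L)
  # one guessing ridge per experiment: rank 36 of 38
  expect_equal(check_identifiability(fc$model, n_points = 2)$ranks,
               rep(36L, 2))
  # without shared guessing the joint model is saturated
  m <- build_2htm_model(c("colour", "category"), share_guessing = FALSE)
  expect_equal(length(mptsdt:::compile_binding(m)$free$name), 22L)
})

test_that("expected counts preserve tree totals", {
  cts <- lop_counts()
  f <- fit_2htm_joint(cts, "e2", starts = 2)
  obs_tot <- rowsum(f$observed, f$model$cell_tree)
  exp_tot <- rowsum(f$expected, f$model$cell_tree)
  expect_equal(exp_tot, obs_tot, tolerance = 1e-6)
  expect_gte(f$G2, 0)
})

test_that("free-ratio reparametrization preserves the combined likelihood", {
  cts <- lop_counts()
  fc <- fit_2htm_combined(cts, starts = 5)
  ti <- interaction_test(fc, "Dn.colour_lure", starts = 8)
  expect_lt(abs(ti$fit_free$G2 - fc$G2), 0.01)
  expect_gte(ti$delta_G2, 0)
  # the free shrinkage factors reproduce the unconstrained parameter ratios
  est <- fc$estimates
  for (e in c("e1", "e2")) {
    r <- est[paste0("Dn.colour_lure[colour,", e, "]")] /
      est[paste0("Dn.colour_lure[category,", e, "]")]
    expect_equal(unname(ti$lambda[paste0("lambda[", e, "]")]), unname(r),
                 tolerance = 0.02)
  }
})

test_that("a ratio shared by construction yields a null interaction", {
  # both "experiments" simulated from identical parameters: ratio = 1 in both
  sp <- scenario_spec("null", seed = 12)
  c1 <- simulate_2htm(sp, replicate = 1)$counts; c1$experiment <- "s1"
  c2 <- simulate_2htm(sp, replicate = 2)$counts; c2$experiment <- "s2"
  fc <- fit_2htm_combined(rbind(c1, c2), experiments = c("s1", "s2"),
                          starts = 3)
  ti <- interaction_test(fc, "Dn.colour_lure", starts = 5)
  expect_lt(ti$delta_G2, stats::qchisq(0.995, 1))
})

test_that("identified parameter combinations are recovered without bias", {
  # raw detection parameters sit on the guessing ridge and cannot be
  # recovered individually; the identified combinations (1-Do)(1-g) and
  # (1-Dn_k)g, plus a_o and a_n, are estimable and should be unbiased
  sp <- scenario_spec("word_like", seed = 100)
  tp <- sp$params
  truth <- c(K_col = (1 - tp$colour$Do) * (1 - tp$colour$g),
             K_cat = (1 - tp$category$Do) * (1 - tp$category$g),
             c_col = (1 - tp$colour$Dn[["colour_lure"]]) * tp$colour$g,
             c_cat = (1 - tp$category$Dn[["colour_lure"]]) * tp$category$g,
             a_o = tp$colour$a_o, a_n = tp$colour$a_n)
  reps <- 40
  est <- matrix(NA_real_, reps, length(truth))
  for (r in seq_len(reps)) {
    k <- simulate_2htm(sp, replicate = r)$counts
    f <- fit_2htm_joint(k, "word_like", starts = 2, seed = r)
    e <- f$estimates
    est[r, ] <- c(
      (1 - e[["Do[colour]"]]) * (1 - e[["g"]]),
      (1 - e[["Do[category]"]]) * (1 - e[["g"]]),
      (1 - e[["Dn.colour_lure[colour]"]]) * e[["g"]],
      (1 - e[["Dn.colour_lure[category]"]]) * e[["g"]],
      e[["a_o"]], e[["a_n"]])
  }
  bias <- colMeans(est) - truth
  expect_true(all(abs(bias) < 0.03))
})

test_that("parameter tables expose condition and experiment tags", {
  cts <- lop_counts()
  f <- fit_2htm_joint(cts, "e1", starts = 2)
  tab <- htm_parameter_table(f)
  expect_equal(nrow(tab), 19L)
  expect_setequal(unique(tab$condition[tab$parameter == "Do"]),
                  c("colour", "category"))
  expect_equal(tab$condition[tab$parameter == "g"], "")
})
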