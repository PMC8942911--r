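#' Specify a multinomial processing tree model
#'
#' An MPT model is a set of trees; each tree is a set of branches; each
#' branch is a product of parameters theta or complements (1 - theta)
#' ending in a response category.  The probability of a category is the sum
#' over its branches of the product of the branch's factors, so category
#' probabilities within a tree are non-negative and sum to 1 for any
#' parameter vector in (0, 1).
#'
#' @param branches data frame with columns `tree`, `category` and `path`,
#'   where `path` is a product such as `"(1-Do)*g*a_o"`.  Parameter names
#'   appearing in several trees denote the same parameter slot.
#' @return An object of class `mpt_model`.
#' @export
#' @examples
#' m <- mpt_model(data.frame(
#'   tree = "t", category = c("a", "b"), path = c("theta", "(1-theta)")))
#' category_probabilities(m, c(theta = 0.3))
mpt_model <- function(branches) {
  need <- c("tree", "category", "path")
  if (!all(need %in% names(branches)))
    stop("'branches' needs columns tree, category, path")
  branches <- as.data.frame(branches, stringsAsFactors = FALSE)
  branches$tree <- as.character(branches$tree)
  branches$category <- as.character(branches$category)

  parse_path <- function(p) {
    toks <- strsplit(gsub("[[:space:]]", "", p), "*", fixed = TRUE)[[1]]
    if (!length(toks)) stop("empty branch path")
    lapply(toks, function(tk) {
      comp <- grepl("^\\(1-.+\\)$", tk)
      nm <- if (comp) sub("^\\(1-(.+)\\)$", "\\1", tk) else tk
      if (!nzchar(nm) || grepl("[()*]", nm))
        stop("cannot parse term '", tk, "'")
      list(slot = nm, comp = comp)
    })
  }
  terms <- lapply(branches$path, parse_path)

  trees <- unique(branches$tree)
  cats <- lapply(stats::setNames(trees, trees), function(tr)
    sort(unique(branches$category[branches$tree == tr])))
  cells <- do.call(rbind, lapply(trees, function(tr)
    data.frame(tree = tr, category = cats[[tr]], stringsAsFactors = FALSE)))
  cells$cell <- seq_len(nrow(cells))

  slots <- unique(unlist(lapply(terms, vapply, function(t) t$slot, "")))

  nb <- nrow(branches)
  branch_cell <- vapply(seq_len(nb), function(i)
    cells$cell[cells$tree == branches$tree[i] &
               cells$category == branches$category[i]], 0L)
  # position-wise factor layout for fast product evaluation
  maxk <- max(vapply(terms, length, 0L))
  pos <- lapply(seq_len(maxk), function(k) {
    has <- which(vapply(terms, length, 0L) >= k)
    list(branch = has,
         slot = vapply(has, function(i) match(terms[[i]][[k]]$slot, slots), 0L),
         comp = vapply(has, function(i) terms[[i]][[k]]$comp, TRUE))
  })

  structure(list(branches = branches, trees = trees, categories = cats,
                 cells = cells, slots = slots, branch_cell = branch_cell,
                 cell_tree = match(cells$tree, trees), pos = pos,
                 used_cells = sort(unique(branch_cell))),
            class = "mpt_model")
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", length(x$trees), "tree(s),", nrow(x$branches),
      "branches,", nrow(x$cells), "response categories,",
      length(x$slots), "parameter slot(s)\n")
  invisible(x)
}

# branch and cell probabilities from a full vector of slot values
mpt_cell_probs <- function(model, sv) {
  bp <- rep(1, nrow(model$branches))
  for (p in model$pos) {
    v <- sv[p$slot]
    v[p$comp] <- 1 - v[p$comp]
    bp[p$branch] <- bp[p$branch] * v
  }
  cellp <- numeric(nrow(model$cells))
  cp <- rowsum(bp, model$branch_cell)
  cellp[model$used_cells] <- cp
  cellp
}

#' Category probabilities of an MPT model
#'
#' @param model an [mpt_model()].
#' @param params named numeric vector giving a value in (0, 1) for every
#'   parameter slot of the model.
#' @return Named list (one element per tree) of named category-probability
#'   vectors.
#' @export
category_probabilities <- function(model, params) {
  stopifnot(inherits(model, "mpt_model"))
  miss <- setdiff(model$slots, names(params))
  if (length(miss))
    stop("unbound parameter(s): ", paste(miss, collapse = ", "))
  sv <- unname(params[model$slots])
  if (any(sv <= 0) || any(sv >= 1))
    stop("parameter values must lie strictly in (0, 1)")
  cellp <- mpt_cell_probs(model, sv)
  lapply(stats::setNames(model$trees, model$trees), function(tr) {
    i <- model$cells$tree == tr
    stats::setNames(cellp[i], model$cells$category[i])
  })
}

#' Equality, fixing and ratio constraints for MPT fitting
#'
#' @param equal list of character vectors; the slots (or scale-parameter
#'   names) in each vector are bound to a single shared free parameter.
#' @param fixed named numeric vector of slots pinned to constants.
#' @param ratio list of `list(slot =, base =, scale =)` entries that
#'   reparametrize `slot = scale * base`, where `base` is another parameter
#'   slot and `scale` names a new positive free parameter (a shrinkage
#'   factor, unbounded above; the product is constrained to (0, 1) during
#'   optimization).
#' @return An object of class `mpt_constraints`.
#' @export
mpt_constraints <- function(equal = list(), fixed = numeric(), ratio = list()) {
  structure(list(equal = equal, fixed = fixed, ratio = ratio),
            class = "mpt_constraints")
}

# Resolve constraints into a free-parameter table and per-slot definitions.
compile_binding <- function(model, constraints = NULL) {
  if (is.null(constraints)) constraints <- mpt_constraints()
  stopifnot(inherits(constraints, "mpt_constraints"))
  slots <- model$slots
  known <- function(s) {
    bad <- setdiff(s, slots)
    if (length(bad)) stop("unknown parameter slot(s): ",
                          paste(bad, collapse = ", "))
  }

  fixed <- constraints$fixed
  known(names(fixed))
  ratio_slots <- vapply(constraints$ratio, `[[`, "", "slot")
  ratio_base <- vapply(constraints$ratio, `[[`, "", "base")
  ratio_scale <- vapply(constraints$ratio, `[[`, "", "scale")
  known(ratio_slots); known(ratio_base)
  if (anyDuplicated(ratio_slots)) stop("duplicate ratio slot")

  # representative free name per slot (union of equality groups)
  rep_of <- stats::setNames(slots, slots)
  scale_rep <- stats::setNames(unique(ratio_scale), unique(ratio_scale))
  find <- function(map, x) { while (map[[x]] != x) x <- map[[x]]; x }
  for (grp in constraints$equal) {
    grp <- as.character(grp)
    is_scale <- grp %in% names(scale_rep)
    if (any(is_scale) && !all(is_scale))
      stop("cannot equate probability slots with scale parameters")
    map <- if (all(is_scale)) scale_rep else { known(grp); rep_of }
    r <- find(map, grp[1])
    for (g in grp[-1]) map[find(map, g)] <- r
    if (all(is_scale)) scale_rep <- map else rep_of <- map
  }
  rep_of <- vapply(slots, function(s) find(rep_of, s), "")
  scale_rep <- vapply(names(scale_rep), function(s) find(scale_rep, s), "")

  plain <- setdiff(slots, union(names(fixed), ratio_slots))
  if (length(intersect(names(fixed), ratio_slots)))
    stop("a slot cannot be both fixed and ratio-reparametrized")
  if (any(ratio_base %in% c(names(fixed), ratio_slots)))
    stop("ratio base must be an unconstrained probability slot")

  free_prob <- unique(unname(rep_of[plain]))
  free_pos <- unique(unname(scale_rep))
  free <- data.frame(name = c(free_prob, free_pos),
                     kind = c(rep("prob", length(free_prob)),
                              rep("pos", length(free_pos))),
                     stringsAsFactors = FALSE)
  fidx <- stats::setNames(seq_len(nrow(free)), free$name)

  slot_def <- vector("list", length(slots))
  names(slot_def) <- slots
  for (s in plain) slot_def[[s]] <- list(type = "free", idx = fidx[[rep_of[[s]]]])
  for (s in names(fixed)) slot_def[[s]] <- list(type = "fixed",
                                                value = unname(fixed[[s]]))
  for (i in seq_along(ratio_slots)) {
    b <- ratio_base[i]
    slot_def[[ratio_slots[i]]] <- list(
      type = "ratio",
      scale_idx = fidx[[scale_rep[[ratio_scale[i]]]]],
      base_idx = fidx[[rep_of[[b]]]])
  }
  list(free = free, slot_def = slot_def)
}

binding_slot_values <- function(binding, vf) {
  vapply(binding$slot_def, function(d)
    switch(d$type,
           free = vf[d$idx],
           fixed = d$value,
           ratio = vf[d$scale_idx] * vf[d$base_idx]), 0)
}

theta_to_free <- function(binding, theta) {
  ifelse(binding$free$kind == "prob", stats::plogis(theta), exp(theta))
}

# align a data list (tree -> named counts) with the model's cell order
align_observed <- function(model, data) {
  miss <- setdiff(model$trees, names(data))
  if (length(miss)) stop("no data for tree(s): ", paste(miss, collapse = ", "))
  obs <- numeric(nrow(model$cells))
  for (tr in model$trees) {
    v <- data[[tr]]
    i <- which(model$cells$tree == tr)
    if (is.null(names(v))) {
      if (length(v) != length(i))
        stop("counts for tree '", tr, "' have wrong length")
      obs[i] <- v
    } else {
      miss <- setdiff(model$cells$category[i], names(v))
      if (length(miss)) stop("tree '", tr, "' lacks categories: ",
                             paste(miss, collapse = ", "))
      obs[i] <- v[model$cells$category[i]]
    }
  }
  # non-integer "counts" are allowed: fitting expected counts is legitimate
  if (any(!is.finite(obs)) || any(obs < 0))
    stop("counts must be non-negative")
  obs
}

mpt_negloglik <- function(model, binding, obs, theta) {
  vf <- theta_to_free(binding, theta)
  sv <- binding_slot_values(binding, vf)
  if (any(sv <= 0) || any(sv >= 1)) {
    viol <- sum(pmax(sv - 1, 0)) + sum(pmax(-sv, 0))
    return(1e10 * (1 + viol))
  }
  cellp <- mpt_cell_probs(model, sv)
  -sum(obs * log(pmax(cellp, 1e-12)))
}

g2_statistic <- function(obs, expected) {
  i <- obs > 0
  2 * sum(obs[i] * log(obs[i] / pmax(expected[i], 1e-12)))
}

#' Fit an MPT model by maximum likelihood
#'
#' Maximizes the product-multinomial likelihood over the model's free
#' parameters.  Optimization runs on logit-transformed probabilities (and
#' log-transformed positive scale parameters), so ordering and range
#' constraints hold by construction.  A deterministic multi-start scheme is
#' used: one central start (all probabilities 0.5, scales 1) plus
#' `starts - 1` seeded random interior points; the best solution is polished
#' with [stats::nlminb()].  Among starts whose likelihoods tie within 1e-8,
#' the lexicographically smallest estimate vector is kept, so refits are
#' exactly reproducible.
#'
#' @param model an [mpt_model()].
#' @param data named list mapping each tree name to its observed category
#'   counts (named numeric vector, or unnamed in the tree's category order).
#' @param constraints optional [mpt_constraints()].
#' @param starts number of optimization starts (default 20).
#' @param seed integer seed for the random starts.
#' @return An object of class `mpt_fit` with elements `estimates` (free
#'   parameters), `slot_values`, `loglik`, `G2`, `df`, `p_value`,
#'   `expected`, `observed`, `convergence`, `boundary` (names of estimates
#'   within 1e-4 of 0 or 1) and the inputs needed for refitting.
#' @export
fit_mpt <- function(model, data, constraints = NULL, starts = 20, seed = 1) {
  stopifnot(inherits(model, "mpt_model"), starts >= 1)
  binding <- compile_binding(model, constraints)
  obs <- align_observed(model, data)
  nfree <- nrow(binding$free)

  rng <- local_rng(seed)
  on.exit(rng$restore())

  theta0 <- matrix(stats::rnorm(nfree * starts), nfree, starts)
  theta0[, 1] <- 0
  cands <- list()
  for (k in seq_len(starts)) {
    f <- stats::optim(theta0[, k], mpt_negloglik, model = model,
                      binding = binding, obs = obs, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
    cands[[k]] <- f
  }
  vals <- vapply(cands, `[[`, 0, "value")
  best <- cands[[which.min(vals)]]
  pol <- stats::nlminb(best$par, mpt_negloglik, model = model,
                       binding = binding, obs = obs,
                       control = list(iter.max = 2000, eval.max = 5000))
  if (pol$objective < best$value)
    best <- list(par = pol$par, value = pol$objective, convergence = 0)
  # deterministic tie-break: lexicographically smallest estimates
  tied <- which(vals <= best$value + 1e-8)
  for (k in tied) {
    a <- theta_to_free(binding, cands[[k]]$par)
    b <- theta_to_free(binding, best$par)
    d <- a - b
    j <- which(abs(d) > 1e-10)
    if (length(j) && d[j[1]] < 0)
      best <- cands[[k]]
  }
  if (best$value >= 1e10)
    stop("optimization failed: no admissible parameter vector found")

  vf <- theta_to_free(binding, best$par)
  names(vf) <- binding$free$name
  sv <- binding_slot_values(binding, vf)
  cellp <- mpt_cell_probs(model, sv)
  tree_n <- as.vector(rowsum(obs, model$cell_tree))
  expected <- cellp * tree_n[model$cell_tree]
  g2 <- g2_statistic(obs, expected)
  df <- nrow(model$cells) - length(model$trees) - nfree
  boundary <- binding$free$name[vf < 1e-4 | (binding$free$kind == "prob" & vf > 1 - 1e-4)]

  structure(list(estimates = vf, slot_values = sv, loglik = -best$value,
                 G2 = g2, df = df,
                 p_value = stats::pchisq(g2, df, lower.tail = FALSE),
                 expected = expected, observed = obs,
                 convergence = best$convergence, boundary = boundary,
                 model = model, data = data, constraints = constraints,
                 binding = binding, starts = starts, seed = seed,
                 theta = best$par),
            class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("MPT fit:", length(x$estimates), "free parameter(s)\n")
  cat(sprintf("  G2(%d) = %.*f, p = %.*f, logLik = %.*f\n",
              x$df, digits, x$G2, digits, x$p_value, digits, x$loglik))
  print(round(x$estimates, digits))
  if (length(x$boundary))
    cat("  near-boundary estimate(s):", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of nested MPT models
#'
#' Computes `dG2 = G2_constrained - G2_general` with degrees of freedom
#' equal to the difference in free parameters, referred to the chi-squared
#' distribution.  A negative difference beyond `tolerance` indicates that
#' the constrained optimization found a better optimum than the general one
#' — an optimization failure; the general model should be refit with more
#' starts.
#'
#' @param fit_general,fit_constrained [fit_mpt()] results, with
#'   `fit_constrained` nested in `fit_general`.
#' @param tolerance slack for small negative differences due to numerical
#'   convergence (default 0.01).
#' @return Object of class `mpt_test`: list with `delta_G2`, `df`,
#'   `p_value`.
#' @export
delta_g2 <- function(fit_general, fit_constrained, tolerance = 0.01) {
  stopifnot(inherits(fit_general, "mpt_fit"), inherits(fit_constrained, "mpt_fit"))
  ddf <- fit_constrained$df - fit_general$df
  if (ddf < 1) stop("constrained model must have fewer free parameters")
  dg2 <- fit_constrained$G2 - fit_general$G2
  if (dg2 < -tolerance)
    warning("negative delta-G2 (", format(dg2), "): refit with more starts")
  structure(list(delta_G2 = dg2, df = ddf,
                 p_value = stats::pchisq(max(dg2, 0), ddf, lower.tail = FALSE)),
            class = "mpt_test")
}

#' @export
print.mpt_test <- function(x, digits = 3, ...) {
  cat(sprintf("delta-G2(%d) = %.*f, p = %.*g\n",
              x$df, digits, x$delta_G2, digits, x$p_value))
  invisible(x)
}

#' Parametric bootstrap of MPT parameter estimates
#'
#' Draws `B` parametric resamples — per-tree multinomial counts at the
#' fitted category probabilities and the observed per-tree totals — refits
#' each, and summarizes the resampled free-parameter estimates.
#'
#' @param fit an [fit_mpt()] result.
#' @param B number of bootstrap resamples (must be positive).
#' @param seed integer seed; the r-th resample uses a seed derived from it
#'   by a fixed counter scheme, so any replicate is reproducible in
#'   isolation.
#' @param starts optimization starts per refit (refits also start from the
#'   original solution, so few random starts are needed).
#' @return List with `sd` and `ci` (2.5/97.5 percentile) per free
#'   parameter, the resample `draws` matrix, and `n_failed`.  More than 5
#'   percent failed refits triggers a warning.
#' @export
bootstrap_parameters <- function(fit, B = 1000, seed = 1, starts = 2) {
  stopifnot(inherits(fit, "mpt_fit"))
  if (B < 1) stop("B must be a positive integer")
  model <- fit$model
  cellp <- fit$expected / pmax(rowsum(fit$observed, model$cell_tree)[model$cell_tree], 1)
  draws <- matrix(NA_real_, B, length(fit$estimates),
                  dimnames = list(NULL, names(fit$estimates)))
  n_failed <- 0
  for (r in seq_len(B)) {
    rng <- local_rng(replicate_seed(seed, r))
    sim <- fit$observed
    for (ti in seq_along(model$trees)) {
      i <- which(model$cell_tree == ti)
      n <- sum(fit$observed[i])
      sim[i] <- as.vector(stats::rmultinom(1, n, cellp[i]))
    }
    rng$restore()
    dat <- split(sim, model$cells$tree)[model$trees]
    for (tr in model$trees) {
      i <- model$cells$tree == tr
      names(dat[[tr]]) <- model$cells$category[i]
    }
    rf <- tryCatch(
      refit_warm(fit, dat, starts = starts, seed = replicate_seed(seed, r)),
      error = function(e) NULL)
    if (is.null(rf) || rf$convergence != 0 && rf$convergence != 1) {
      n_failed <- n_failed + 1
    } else {
      draws[r, ] <- rf$estimates
    }
  }
  if (n_failed / B > 0.05)
    warning(n_failed, " of ", B, " bootstrap refits failed")
  ok <- stats::complete.cases(draws)
  list(sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
       ci = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(0.025, 0.975)),
       draws = draws, n_failed = n_failed)
}

# refit starting from an existing solution plus a few random starts
refit_warm <- function(fit, data, starts = 2, seed = 1) {
  binding <- fit$binding
  obs <- align_observed(fit$model, data)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  best <- NULL
  for (k in seq_len(starts)) {
    th0 <- if (k == 1) fit$theta else stats::rnorm(length(fit$theta))
    f <- stats::optim(th0, mpt_negloglik, model = fit$model, binding = binding,
                      obs = obs, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || f$value < best$value) best <- f
  }
  vf <- theta_to_free(binding, best$par)
  names(vf) <- binding$free$name
  list(estimates = vf, value = best$value, convergence = best$convergence)
}

#' Numerical identifiability check of an MPT model
#'
#' Evaluates the Jacobian of the stacked category probabilities with
#' respect to the free parameters (on the unconstrained optimization scale)
#' at random interior points.  Full column rank at every point indicates
#' local identifiability, which justifies the degrees-of-freedom bookkeeping
#' `df = (categories - trees) - free parameters`.
#'
#' @param model an [mpt_model()].
#' @param constraints optional [mpt_constraints()].
#' @param n_points number of random interior points.
#' @param seed integer seed.
#' @return List with `n_free`, per-point `ranks`, and logical `identified`.
#' @export
check_identifiability <- function(model, constraints = NULL, n_points = 5,
                                  seed = 1) {
  binding <- compile_binding(model, constraints)
  nfree <- nrow(binding$free)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  ranks <- integer(n_points)
  for (pt in seq_len(n_points)) {
    theta <- ifelse(binding$free$kind == "prob",
                    stats::qlogis(stats::runif(nfree, 0.15, 0.85)),
                    log(stats::runif(nfree, 0.6, 1.4)))
    probs_at <- function(th) {
      sv <- binding_slot_values(binding, theta_to_free(binding, th))
      mpt_cell_probs(model, sv)
    }
    h <- 1e-5
    J <- vapply(seq_len(nfree), function(j) {
      e <- numeric(nfree); e[j] <- h
      (probs_at(theta + e) - probs_at(theta - e)) / (2 * h)
    }, numeric(nrow(model$cells)))
    ranks[pt] <- qr(J)$rank
  }
  list(n_free = nfree, ranks = ranks, identified = all(ranks == nfree))
}

#' Read and write MPT model files (.eqn convention)
#'
#' One line per branch: `tree category path`, with the path a
#' `*`-separated product of parameter names and `(1-name)` complements.  An
#' optional first line holding a single integer (the branch count used by
#' some programs) is skipped on reading.
#'
#' @param path file path.
#' @return `read_eqn` returns an [mpt_model()].
#' @export
read_eqn <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) && grepl("^[0-9]+$", ln[1])) ln <- ln[-1]
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- vapply(parts, length, 0L) != 3
  if (any(bad)) stop("malformed .eqn line(s): ", paste(which(bad), collapse = ", "))
  mpt_model(data.frame(tree = vapply(parts, `[[`, "", 1),
                       category = vapply(parts, `[[`, "", 2),
                       path = vapply(parts, `[[`, "", 3),
                       stringsAsFactors = FALSE))
}

#' @rdname read_eqn
#' @param model an [mpt_model()].
#' @export
write_eqn <- function(model, path) {
  stopifnot(inherits(model, "mpt_model"))
  b <- model$branches
  writeLines(c(as.character(nrow(b)),
               paste(b$tree, b$category, gsub(" ", "", b$path))), path)
  invisible(path)
}
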