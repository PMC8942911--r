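#' Generator specification for synthetic confidence-rating experiments
#'
#' Bundles a generating model (`"2htm"` or `"uvsdt"`), true parameter
#' values per encoding condition, an [experiment_design()], a replicate
#' count and a base seed.  Replicate `r` of a spec is generated under a
#' seed derived from the base seed by a fixed counter scheme, so any single
#' replicate is reproducible in isolation.
#'
#' @param model `"2htm"` or `"uvsdt"`.
#' @param params named list (one element per condition) of true parameter
#'   values; see [simulate_2htm()] / [simulate_uvsdt()] for the layout.
#' @param design an [experiment_design()].
#' @param experiment experiment label written into the output counts.
#' @param replicates number of replicates the spec stands for.
#' @param seed base seed.
#' @param heterogeneity optional beta-precision `kappa` for participant
#'   heterogeneity in the 2HTM generator (`NULL`, the default, simulates
#'   homogeneous participants — the assumption under which pooled fitting
#'   is exact).
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(model = c("2htm", "uvsdt"), params, design,
                           experiment = "sim", replicates = 1, seed = 1,
                           heterogeneity = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "experiment_design"),
            all(names(design$conditions) %in% names(params)))
  structure(list(model = model, params = params, design = design,
                 experiment = experiment, replicates = replicates,
                 seed = seed, heterogeneity = heterogeneity),
            class = "generator_spec")
}

# participant-level parameter draw: Beta with mean p and precision kappa
draw_hetero <- function(p, kappa, n) {
  if (is.null(kappa)) return(matrix(p, n, length(p), byrow = TRUE,
                                    dimnames = list(NULL, names(p))))
  m <- vapply(p, function(pp)
    stats::rbeta(n, pp * kappa, (1 - pp) * kappa), numeric(n))
  pmin(pmax(m, 1e-4), 1 - 1e-4)
}

sim_2htm_class <- function(n, item_class, th) {
  # literal branch traversal: each split sampled independently
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  rating <- integer(n)
  if (item_class == "target") {
    det <- u1 < th[["Do"]]
    rating[det] <- ifelse(u2[det] < th[["s"]], 4L, 3L)
  } else {
    det <- u1 < th[[paste0("Dn.", item_class)]]
    rating[det] <- ifelse(u2[det] < th[[paste0("n.", item_class)]], 1L, 2L)
  }
  g <- u2[!det] < th[["g"]]
  r <- integer(sum(!det))
  r[g] <- ifelse(u3[!det][g] < th[["a_o"]], 4L, 3L)
  r[!g] <- ifelse(u3[!det][!g] < th[["a_n"]], 1L, 2L)
  rating[!det] <- r
  rating
}

flatten_htm_params <- function(p) {
  out <- c(Do = p$Do, s = p$s, g = p$g, a_o = p$a_o, a_n = p$a_n)
  c(out, stats::setNames(p$Dn, paste0("Dn.", names(p$Dn))),
    stats::setNames(p$n, paste0("n.", names(p$n))))
}

#' Simulate a confidence-rating experiment from the 2HTM
#'
#' For every participant and test trial the item-class processing tree is
#' traversed, sampling each split independently, and the resulting rating
#' is recorded.  Pooled counts aggregate the trial table exactly.
#'
#' @param spec a [generator_spec()] with `model = "2htm"`.  Per-condition
#'   parameters: `list(Do =, s =, Dn = c(<lure> = ...), n = c(<lure> = ...),
#'   g =, a_o =, a_n =)`, with one `Dn`/`n` entry per lure class in the
#'   design.
#' @param replicate replicate index (selects the per-replicate seed).
#' @return List with `trials` (data frame: condition, participant,
#'   item_class, rating) and `counts` (a [rating_counts()] table).
#' @export
simulate_2htm <- function(spec, replicate = 1) {
  stopifnot(inherits(spec, "generator_spec"), spec$model == "2htm")
  rng <- local_rng(replicate_seed(spec$seed, replicate))
  on.exit(rng$restore())
  design <- spec$design
  rows <- list()
  for (cond in names(design$conditions)) {
    th0 <- flatten_htm_params(spec$params[[cond]])
    np <- design$conditions[[cond]]
    thp <- draw_hetero(th0, spec$heterogeneity, np)
    for (pid in seq_len(np)) {
      for (cl in names(design$trials_per_class)) {
        nt <- design$trials_per_class[[cl]]
        rating <- sim_2htm_class(nt, cl, thp[pid, ])
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, participant = pid, item_class = cl,
          rating = rating, stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows)
  list(trials = trials, counts = pool_trials(trials, spec$experiment))
}

#' Simulate a confidence-rating experiment from the UVSDT model
#'
#' Each trial draws a memory strength from the item class's normal
#' distribution and bins it by the shared response criteria.  Per-condition
#' parameters: `list(criteria = c(c1, c2, c3), classes = list(<class> =
#' c(mu, sigma), ...))` with one entry per item class in the design
#' (targets typically `c(mu, sigma)`, lures `c(0, 1)`).  Infinite criteria
#' are allowed and collapse the corresponding ratings.
#'
#' @inheritParams simulate_2htm
#' @return As [simulate_2htm()].
#' @export
simulate_uvsdt <- function(spec, replicate = 1) {
  stopifnot(inherits(spec, "generator_spec"), spec$model == "uvsdt")
  rng <- local_rng(replicate_seed(spec$seed, replicate))
  on.exit(rng$restore())
  design <- spec$design
  rows <- list()
  for (cond in names(design$conditions)) {
    pc <- spec$params[[cond]]
    np <- design$conditions[[cond]]
    for (pid in seq_len(np)) {
      for (cl in names(design$trials_per_class)) {
        nt <- design$trials_per_class[[cl]]
        ms <- pc$classes[[cl]]
        if (is.null(ms)) stop("no strength distribution for class '", cl, "'")
        strength <- stats::rnorm(nt, ms[1], ms[2])
        rating <- findInterval(strength, pc$criteria) + 1L
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, participant = pid, item_class = cl,
          rating = rating, stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows)
  list(trials = trials, counts = pool_trials(trials, spec$experiment))
}

# aggregate a trial table into a rating_counts data frame
pool_trials <- function(trials, experiment) {
  cells <- unique(trials[, c("condition", "item_class")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- trials$rating[trials$condition == cells$condition[i] &
                       trials$item_class == cells$item_class[i]]
    k <- tabulate(r, nbins = 4)
    data.frame(experiment = experiment, condition = cells$condition[i],
               item_class = cells$item_class[i],
               r1 = k[1], r2 = k[2], r3 = k[3], r4 = k[4],
               stringsAsFactors = FALSE)
  }))
  validate_rating_counts(out)
}

#' Simulate from a generator spec
#'
#' @param spec a [generator_spec()].
#' @param replicate replicate index.
#' @return As [simulate_2htm()] / [simulate_uvsdt()].
#' @export
simulate_spec <- function(spec, replicate = 1) {
  switch(spec$model,
         "2htm" = simulate_2htm(spec, replicate),
         "uvsdt" = simulate_uvsdt(spec, replicate))
}

#' Named 2HTM generating scenarios
#'
#' Presets for calibration studies at the bundled experiment designs:
#' `"null"` — both encoding conditions share every parameter (for type-I
#' error calibration of the condition-difference tests); `"word_like"` —
#' colour-lure detection is much higher under category encoding
#' (`Dn.colour_lure` 0.75 vs 0.35), echoing the verbal-materials pattern,
#' at the word-experiment design; `"picture_like"` — category-lure
#' detection is higher under colour encoding (0.75 vs 0.35) at the
#' picture-experiment design.  All other parameters are shared across
#' conditions at field-typical values.
#'
#' @param name preset name.
#' @param replicates,seed stored in the returned spec.
#' @return A [generator_spec()].
#' @export
scenario_spec <- function(name = c("null", "word_like", "picture_like"),
                          replicates = 200, seed = 1) {
  name <- match.arg(name)
  base <- list(Do = 0.65, s = 0.85,
               Dn = c(category_lure = 0.45, colour_lure = 0.45,
                      critical_lure = 0.25),
               n = c(category_lure = 0.8, colour_lure = 0.8,
                     critical_lure = 0.8),
               g = 0.4, a_o = 0.6, a_n = 0.6)
  designs <- lop_designs()
  p <- list(colour = base, category = base)
  design <- designs$e1
  if (name == "word_like") {
    p$category$Dn[["colour_lure"]] <- 0.75
    p$colour$Dn[["colour_lure"]] <- 0.35
  } else if (name == "picture_like") {
    p$colour$Dn[["category_lure"]] <- 0.75
    p$category$Dn[["category_lure"]] <- 0.35
    design <- designs$e2
  }
  generator_spec("2htm", p, design, experiment = name,
                 replicates = replicates, seed = seed)
}
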