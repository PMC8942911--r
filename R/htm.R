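#' Two-high-threshold recognition models for 4-point confidence ratings
#'
#' Builders for the 2HTM as a multinomial processing tree over the rating
#' categories 1 (definitely new) ... 4 (definitely old).  An old (target)
#' item is detected with probability `Do` and then rated 4 with probability
#' `s` (else 3).  A lure of type k is detected as new with probability
#' `Dn.<k>` and then rated 1 with probability `n.<k>` (else 2).  Undetected
#' items of any class enter a common guessing state: guess "old" with
#' probability `g`, then rate 4 with probability `a_o` (else 3); guess
#' "new" with probability `1 - g`, then rate 1 with probability `a_n`
#' (else 2).  Detection and confidence parameters are condition-specific;
#' by default the guessing parameters `g`, `a_o`, `a_n` are shared across
#' the encoding conditions of an experiment (the guessing state does not
#' depend on the study task), giving the joint two-condition model 19 free
#' parameters and 5 degrees of freedom.
#'
#' Parameter slots are named `base[condition]` or `base[condition,experiment]`,
#' e.g. `"Dn.colour_lure[category,e1]"`; shared guessing slots drop the
#' condition tag.
#'
#' @param conditions character vector of condition labels, or `NULL` for a
#'   single unlabelled condition.
#' @param lure_types lure class labels (each gets its own detection `Dn`
#'   and high-confidence `n` parameter).
#' @param experiment optional experiment tag appended to slot and tree
#'   names (used by the combined cross-experiment model).
#' @param share_guessing share `g`, `a_o`, `a_n` across conditions
#'   (default TRUE).
#' @return An [mpt_model()]; tree names are
#'   `[experiment.]condition.item_class`.
#' @export
#' @examples
#' m <- build_2htm_model(conditions = c("colour", "category"))
#' m  # 8 trees, 19 parameter slots
build_2htm_model <- function(conditions = NULL,
                             lure_types = c("category_lure", "colour_lure",
                                            "critical_lure"),
                             experiment = NULL, share_guessing = TRUE) {
  tag <- function(base, cond) {
    keep <- c(if (!is.null(cond)) cond, experiment)
    if (length(keep)) paste0(base, "[", paste(keep, collapse = ","), "]")
    else base
  }
  one_condition <- function(cond) {
    pre <- paste(c(experiment, cond), collapse = ".")
    gcond <- if (share_guessing) NULL else cond
    g <- tag("g", gcond); ao <- tag("a_o", gcond); an <- tag("a_n", gcond)
    guess <- function(tree, det) data.frame(
      tree = tree, category = c("4", "3", "1", "2"),
      path = paste0("(1-", det, ")*", c(paste0(g, "*", ao),
                                        paste0(g, "*(1-", ao, ")"),
                                        paste0("(1-", g, ")*", an),
                                        paste0("(1-", g, ")*(1-", an, ")"))))
    Do <- tag("Do", cond); s <- tag("s", cond)
    tt <- paste0(pre, if (nzchar(pre)) ".", "target")
    target <- rbind(
      data.frame(tree = tt, category = c("4", "3"),
                 path = c(paste0(Do, "*", s), paste0(Do, "*(1-", s, ")"))),
      guess(tt, Do))
    lures <- lapply(lure_types, function(lt) {
      Dn <- tag(paste0("Dn.", lt), cond); n <- tag(paste0("n.", lt), cond)
      tl <- paste0(pre, if (nzchar(pre)) ".", lt)
      rbind(data.frame(tree = tl, category = c("1", "2"),
                       path = c(paste0(Dn, "*", n),
                                paste0(Dn, "*(1-", n, ")"))),
            guess(tl, Dn))
    })
    do.call(rbind, c(list(target), lures))
  }
  conds <- if (is.null(conditions)) list(NULL) else as.list(conditions)
  branches <- do.call(rbind, lapply(conds, one_condition))
  m <- mpt_model(branches)
  m$meta <- list(conditions = conditions, lure_types = lure_types,
                 experiment = experiment, share_guessing = share_guessing)
  m
}

#' Combined cross-experiment 2HTM
#'
#' Concatenates the per-experiment joint models into one model with no
#' parameter sharing across experiments (the combined two-experiment model
#' has 38 free parameters and 10 degrees of freedom).
#'
#' @param experiments experiment labels.
#' @inheritParams build_2htm_model
#' @return An [mpt_model()].
#' @export
build_combined_2htm <- function(experiments = c("e1", "e2"),
                                conditions = c("colour", "category"),
                                lure_types = c("category_lure", "colour_lure",
                                               "critical_lure"),
                                share_guessing = TRUE) {
  ms <- lapply(experiments, function(e)
    build_2htm_model(conditions, lure_types, experiment = e,
                     share_guessing = share_guessing))
  m <- mpt_model(do.call(rbind, lapply(ms, function(x) x$branches)))
  m$meta <- list(conditions = conditions, lure_types = lure_types,
                 experiments = experiments, share_guessing = share_guessing)
  m
}

# rating_counts rows -> named tree data list matching builder tree names
htm_tree_data <- function(counts, with_experiment = FALSE) {
  counts <- validate_rating_counts(as.data.frame(counts))
  nm <- if (with_experiment)
    paste(counts$experiment, counts$condition, counts$item_class, sep = ".")
  else paste(counts$condition, counts$item_class, sep = ".")
  if (anyDuplicated(nm)) stop("duplicate (condition, item class) rows")
  out <- lapply(seq_len(nrow(counts)), function(i)
    stats::setNames(as.numeric(counts[i, c("r1", "r2", "r3", "r4")]),
                    c("1", "2", "3", "4")))
  stats::setNames(out, nm)
}

#' Fit the joint two-condition 2HTM to one experiment
#'
#' @param counts a [rating_counts()] data frame.
#' @param experiment experiment label selecting rows of `counts`.
#' @param constraints optional extra [mpt_constraints()].
#' @inheritParams fit_mpt
#' @inheritParams build_2htm_model
#' @return An `mpt_fit` (see [fit_mpt()]).
#' @export
#' @examples
#' fit <- fit_2htm_joint(lop_counts(), "e1", starts = 5)
#' fit$G2  # approximately 5.22 on 5 df
fit_2htm_joint <- function(counts, experiment, constraints = NULL,
                           starts = 20, seed = 1, share_guessing = TRUE) {
  counts <- counts[counts$experiment == experiment, , drop = FALSE]
  if (!nrow(counts)) stop("no rows for experiment '", experiment, "'")
  conds <- unique(counts$condition)
  lts <- setdiff(unique(counts$item_class), "target")
  model <- build_2htm_model(conds, lts, share_guessing = share_guessing)
  fit_mpt(model, htm_tree_data(counts), constraints, starts = starts,
          seed = seed)
}

#' Fit the combined cross-experiment 2HTM
#'
#' @inheritParams fit_2htm_joint
#' @param experiments experiment labels selecting rows of `counts`.
#' @return An `mpt_fit`.
#' @export
fit_2htm_combined <- function(counts, experiments = c("e1", "e2"),
                              constraints = NULL, starts = 20, seed = 1,
                              share_guessing = TRUE) {
  counts <- counts[counts$experiment %in% experiments, , drop = FALSE]
  conds <- unique(counts$condition)
  lts <- setdiff(unique(counts$item_class), "target")
  model <- build_combined_2htm(experiments, conds, lts,
                               share_guessing = share_guessing)
  fit_mpt(model, htm_tree_data(counts, with_experiment = TRUE), constraints,
          starts = starts, seed = seed)
}

htm_slot <- function(base, condition, experiment = NULL) {
  keep <- c(condition, experiment)
  if (length(keep)) paste0(base, "[", paste(keep, collapse = ","), "]")
  else base
}

merge_equal <- function(constraints, group) {
  if (is.null(constraints)) constraints <- mpt_constraints()
  constraints$equal <- c(constraints$equal, list(group))
  constraints
}

#' Test equality of a 2HTM parameter across encoding conditions
#'
#' Refits the joint model with the named parameter constrained equal across
#' the two conditions and returns the 1-df likelihood-ratio test.
#'
#' @param fit a fit from [fit_2htm_joint()].
#' @param param parameter base name: `"Do"`, `"s"`, `"Dn.<lure_type>"` or
#'   `"n.<lure_type>"`.
#' @param starts,seed passed to the constrained refit (defaults taken from
#'   `fit`).
#' @return An `mpt_test` (see [delta_g2()]) with the constrained fit
#'   attached as attribute `"fit"`.
#' @export
test_parameter_across_conditions <- function(fit, param, starts = fit$starts,
                                             seed = fit$seed) {
  stopifnot(inherits(fit, "mpt_fit"))
  meta <- fit$model$meta
  if (is.null(meta) || length(meta$conditions) < 2)
    stop("'fit' must be a joint multi-condition 2HTM fit")
  grp <- vapply(meta$conditions, function(cn)
    htm_slot(param, cn, meta$experiment), "")
  if (!all(grp %in% fit$model$slots))
    stop("unknown parameter '", param, "'")
  con <- merge_equal(fit$constraints, grp)
  f0 <- fit_mpt(fit$model, fit$data, con, starts = starts, seed = seed)
  out <- delta_g2(fit, f0)
  attr(out, "fit") <- f0
  out
}

#' Test equality of lure detection (or confidence) across lure types
#'
#' Within one encoding condition, refits with the parameter equated between
#' two lure types, e.g. `Dn.category_lure = Dn.colour_lure`.
#'
#' @inheritParams test_parameter_across_conditions
#' @param condition the encoding condition in which to equate.
#' @param type_a,type_b lure type labels.
#' @param param parameter family, `"Dn"` (detection, default) or `"n"`
#'   (high-confidence "new").
#' @return An `mpt_test`.
#' @export
test_parameter_across_lure_types <- function(fit, condition, type_a, type_b,
                                             param = "Dn",
                                             starts = fit$starts,
                                             seed = fit$seed) {
  stopifnot(inherits(fit, "mpt_fit"))
  meta <- fit$model$meta
  grp <- c(htm_slot(paste0(param, ".", type_a), condition, meta$experiment),
           htm_slot(paste0(param, ".", type_b), condition, meta$experiment))
  if (identical(grp[1], grp[2]))
    return(structure(list(delta_G2 = 0, df = 1, p_value = 1),
                     class = "mpt_test"))
  if (!all(grp %in% fit$model$slots))
    stop("unknown lure type or parameter")
  con <- merge_equal(fit$constraints, grp)
  f0 <- fit_mpt(fit$model, fit$data, con, starts = starts, seed = seed)
  out <- delta_g2(fit, f0)
  attr(out, "fit") <- f0
  out
}

#' Ratio-invariance interaction test across experiments
#'
#' Tests whether the ratio of a parameter between two encoding conditions
#' differs across experiments (materials), following the log-linear
#' reading of an interaction: the parameter in the `numerator` condition is
#' reparametrized as a shrinkage factor `lambda` times its value in the
#' `denominator` condition, separately per experiment.  With `lambda_e`
#' free, the model is a likelihood-preserving reparametrization of the
#' combined model; constraining `lambda_1 = lambda_2` gives the 1-df
#' interaction test.  `lambda` is unbounded above (the ratio may exceed 1);
#' only the product `lambda * base` is constrained to (0, 1).
#'
#' @param fit a fit from [fit_2htm_combined()].
#' @param param parameter base name, e.g. `"Dn.colour_lure"`.
#' @param numerator,denominator condition labels defining the ratio
#'   `param[numerator] = lambda * param[denominator]`.
#' @param starts,seed optimization settings for the two reparametrized fits.
#' @return List of class `htm_interaction`: `lambda` (per experiment, from
#'   the free-ratio fit), `lambda_shared`, `delta_G2`, `df`, `p_value`,
#'   plus both reparametrized fits.
#' @export
interaction_test <- function(fit, param, numerator = "colour",
                             denominator = "category", starts = fit$starts,
                             seed = fit$seed) {
  stopifnot(inherits(fit, "mpt_fit"))
  meta <- fit$model$meta
  if (is.null(meta$experiments) || length(meta$experiments) < 2)
    stop("'fit' must be a combined cross-experiment 2HTM fit")
  exps <- meta$experiments
  ratio <- lapply(exps, function(e) list(
    slot = htm_slot(param, numerator, e),
    base = htm_slot(param, denominator, e),
    scale = paste0("lambda[", e, "]")))
  for (r in ratio)
    if (!all(c(r$slot, r$base) %in% fit$model$slots))
      stop("unknown parameter '", param, "' or condition")
  base_con <- if (is.null(fit$constraints)) mpt_constraints() else fit$constraints
  con_free <- base_con; con_free$ratio <- c(con_free$ratio, ratio)
  con_shared <- merge_equal(con_free, vapply(ratio, `[[`, "", "scale"))

  f_free <- fit_mpt(fit$model, fit$data, con_free, starts = starts, seed = seed)
  if (abs(f_free$G2 - fit$G2) > 0.01)
    warning("free-ratio reparametrization did not reproduce the combined ",
            "likelihood (G2 difference ", format(f_free$G2 - fit$G2),
            "); increase 'starts'")
  f_shared <- fit_mpt(fit$model, fit$data, con_shared, starts = starts,
                      seed = seed)
  dg2 <- f_shared$G2 - fit$G2
  structure(list(
    lambda = f_free$estimates[vapply(ratio, `[[`, "", "scale")],
    lambda_shared = unname(f_shared$estimates[ratio[[1]]$scale]),
    delta_G2 = dg2, df = 1L,
    p_value = stats::pchisq(max(dg2, 0), 1, lower.tail = FALSE),
    fit_free = f_free, fit_shared = f_shared),
    class = "htm_interaction")
}

#' @export
print.htm_interaction <- function(x, digits = 3, ...) {
  cat("Ratio-invariance interaction test\n")
  cat("  lambda:", paste(names(x$lambda), round(x$lambda, digits),
                         sep = " = ", collapse = ", "),
      "| shared:", round(x$lambda_shared, digits), "\n")
  cat(sprintf("  delta-G2(%d) = %.*f, p = %.*g\n", x$df, digits, x$delta_G2,
              digits, x$p_value))
  invisible(x)
}

#' Tidy parameter table of a 2HTM fit
#'
#' @param fit an `mpt_fit` from one of the 2HTM fitters.
#' @return Data frame with columns `parameter`, `condition`, `experiment`
#'   (if tagged) and `estimate`, one row per free parameter.
#' @export
htm_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  nm <- names(fit$estimates)
  base <- sub("\\[.*$", "", nm)
  tags <- ifelse(grepl("\\[", nm), sub("^.*\\[(.*)\\]$", "\\1", nm), "")
  parts <- strsplit(tags, ",", fixed = TRUE)
  cond <- vapply(parts, function(p) if (length(p) >= 1) p[1] else "", "")
  expt <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  data.frame(parameter = base, condition = cond, experiment = expt,
             estimate = unname(fit$estimates), stringsAsFactors = FALSE)
}
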