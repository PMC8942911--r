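#' Recompute the full measurement-model analysis of the bundled experiments
#'
#' Runs the whole pipeline on the bundled data: reconstruct pooled counts
#' from the published proportion tables, compute the descriptive targets,
#' fit the UVSDT model and the joint, combined and constrained 2HTM
#' variants, and compare twelve computed quantities against the reference
#' values reported with the original experiments
#' ([lop_reference_values()]).  The run is deterministic for a fixed
#' `seed` and `starts`.
#'
#' Tolerances (bundled with the reference values): 0.3 for G-squared and
#' 0.5 for delta-G-squared (covering the rounding of the published
#' proportions to four decimals), 0.03 for `d_a` and `x_c`, 0.02 for the
#' Wald z, and printed precision for the descriptives.
#'
#' @param seed integer seed for the optimizer's random starts.
#' @param starts optimization starts per fit.
#' @param bootstrap_B if positive, additionally bootstrap the two joint
#'   fits with this many resamples and attach parameter SDs.
#' @param quiet suppress progress messages.
#' @return Object of class `reproduction_report`: a data frame with columns
#'   `quantity`, `computed`, `reference`, `difference`, `tolerance`,
#'   `pass`, with the fitted objects in `attr(, "fits")`.
#' @export
reproduce_study <- function(seed = 1, starts = 10, bootstrap_B = 0,
                            quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]

  say("reconstructing pooled counts from the proportion tables")
  counts <- lop_counts()
  prop <- lop_proportions()

  say("descriptives")
  mr <- descriptives(as.numeric(
    prop[prop$experiment == "e1" & prop$condition == "colour" &
         prop$item_class == "target", c("p1", "p2", "p3", "p4")]))$mean_rating
  crit2 <- counts[counts$experiment == "e2" &
                  counts$item_class == "critical_lure", ]
  fa_crit <- sum(crit2$r3 + crit2$r4) / sum(crit2$r1 + crit2$r2 +
                                            crit2$r3 + crit2$r4)

  say("UVSDT fits (targets vs colour lures, experiment e1)")
  uv_cat <- fit_uvsdt_cell(counts, "e1", "category", "colour_lure")
  uv_col <- fit_uvsdt_cell(counts, "e1", "colour", "colour_lure")
  z_da <- wald_z(uv_cat$d_a, uv_cat$se_d_a, uv_col$d_a, uv_col$se_d_a)$z

  say("joint 2HTM fits")
  f1 <- fit_2htm_joint(counts, "e1", starts = starts, seed = seed)
  f2 <- fit_2htm_joint(counts, "e2", starts = starts, seed = seed)
  fc <- fit_2htm_combined(counts, starts = starts, seed = seed)

  say("condition-equality tests")
  t_do <- test_parameter_across_conditions(f1, "Do")
  t_dncol <- test_parameter_across_conditions(f1, "Dn.colour_lure")
  t_dncat <- test_parameter_across_conditions(f2, "Dn.category_lure")

  say("cross-experiment ratio-invariance interaction")
  t_int <- interaction_test(fc, "Dn.colour_lure")

  computed <- c(
    g2_joint_e1 = f1$G2,
    g2_joint_e2 = f2$G2,
    g2_combined = fc$G2,
    dg2_Do_conditions_e1 = t_do$delta_G2,
    dg2_Dncol_conditions_e1 = t_dncol$delta_G2,
    dg2_Dncat_conditions_e2 = t_dncat$delta_G2,
    dg2_interaction_Dncol = t_int$delta_G2,
    uvsdt_da_e1_category_colour_lure = uv_cat$d_a,
    uvsdt_xc_e1_category_colour_lure = uv_cat$x_c,
    wald_z_da_colour_lure_e1 = z_da,
    mean_rating_e1_colour_target = mr,
    fa_rate_e2_critical = fa_crit)

  ref <- lop_reference_values()
  stopifnot(identical(sort(ref$quantity), sort(names(computed))))
  out <- data.frame(quantity = ref$quantity,
                    computed = unname(computed[ref$quantity]),
                    reference = ref$reference,
                    tolerance = ref$tolerance,
                    stringsAsFactors = FALSE)
  out$difference <- out$computed - out$reference
  out$pass <- abs(out$difference) <= out$tolerance
  out <- out[, c("quantity", "computed", "reference", "difference",
                 "tolerance", "pass")]

  fits <- list(uvsdt_category = uv_cat, uvsdt_colour = uv_col,
               joint_e1 = f1, joint_e2 = f2, combined = fc,
               interaction = t_int)
  if (bootstrap_B > 0) {
    say("parametric bootstrap of the joint fits")
    fits$bootstrap_e1 <- bootstrap_parameters(f1, B = bootstrap_B, seed = seed)
    fits$bootstrap_e2 <- bootstrap_parameters(f2, B = bootstrap_B, seed = seed)
  }
  structure(out, class = c("reproduction_report", "data.frame"),
            fits = fits, seed = seed, starts = starts,
            runtime = proc.time()[["elapsed"]] - t0)
}

#' @export
print.reproduction_report <- function(x, digits = 3, ...) {
  cat("Reproduction report (seed ", attr(x, "seed"), ", ",
      sprintf("%.1f", attr(x, "runtime")), " s)\n", sep = "")
  df <- as.data.frame(x)
  df$computed <- round(df$computed, digits)
  df$difference <- round(df$difference, digits)
  print(df, row.names = FALSE)
  cat(sum(x$pass), "of", nrow(x), "comparisons within tolerance\n")
  invisible(x)
}

#' Export a reproduction report as JSON
#'
#' @param report a [reproduce_study()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "reproduction_report"))
  jsonlite::write_json(
    list(seed = attr(report, "seed"), starts = attr(report, "starts"),
         comparisons = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
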