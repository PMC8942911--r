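#' Unequal-variance signal-detection model for pooled rating data
#'
#' The UVSDT model places the new-item strength distribution at N(0, 1) and
#' the old-item distribution at N(mu, sigma^2); three ordered criteria
#' c1 < c2 < c3 partition the strength axis into the four confidence
#' ratings.  Sensitivity is summarized by `d_a = mu * sqrt(2 / (1 + sigma^2))`
#' (equal to d-prime when sigma = 1) and response bias by the middle
#' criterion `x_c = c2`, which separates "new" (ratings 1-2) from "old"
#' (ratings 3-4) responses on the new-distribution axis.
#'
#' @name uvsdt
NULL

#' UVSDT parameter container
#'
#' @param mu old-distribution mean.
#' @param sigma old-distribution standard deviation (> 0).
#' @param criteria increasing numeric vector `c1 < c2 < c3`.
#' @return List of class `uvsdt_params`.
#' @export
uvsdt_params <- function(mu, sigma, criteria) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(criteria) != 3 || any(diff(criteria) <= 0))
    stop("criteria must be three strictly increasing values")
  structure(list(mu = mu, sigma = sigma, criteria = criteria),
            class = "uvsdt_params")
}

# 2 x 4 matrix of rating-cell probabilities (rows: new, old)
uvsdt_cell_probs <- function(params) {
  cr <- params$criteria
  rbind(new = diff(c(0, stats::pnorm(cr), 1)),
        old = diff(c(0, stats::pnorm(cr, params$mu, params$sigma), 1)))
}

#' Negative log-likelihood of the UVSDT model
#'
#' Product-multinomial negative log-likelihood of old- and new-item rating
#' counts; cell probabilities below 1e-12 are floored to keep the value
#' finite when a near-impossible cell holds a positive count.
#'
#' @param params an [uvsdt_params()].
#' @param old,new integer rating counts (length 4, rating 1 to 4).
#' @return Scalar negative log-likelihood.
#' @export
uvsdt_negloglik <- function(params, old, new) {
  stopifnot(inherits(params, "uvsdt_params"),
            length(old) == 4, length(new) == 4)
  p <- pmax(uvsdt_cell_probs(params), 1e-12)
  -(sum(new * log(p["new", ])) + sum(old * log(p["old", ])))
}

#' Sensitivity index d_a
#'
#' @param mu old-distribution mean.
#' @param sigma old-distribution standard deviation (> 0).
#' @return `mu * sqrt(2 / (1 + sigma^2))`.
#' @export
da_from_params <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  mu * sqrt(2 / (1 + sigma^2))
}

#' Fit the UVSDT model to pooled rating counts by maximum likelihood
#'
#' Optimization runs in an unconstrained space (free `mu`, `log sigma`,
#' `c1` plus log-increments for `c2` and `c3`, so the criterion ordering
#' holds by construction) from a deterministic grid of starts
#' (mu in 0.5/1.5/2.5 by sigma in 1/1.5, criteria from the new-class
#' empirical quantiles); the best solution is kept.  Standard errors come
#' from the inverse observed-information matrix (numerical Hessian of the
#' negative log-likelihood at the MLE in natural parameters), with the SE
#' of `d_a` by the delta method.
#'
#' @param old,new rating counts (length 4) for the old (target) and new
#'   (lure) item class.
#' @return Object of class `uvsdt_fit`: the [uvsdt_params()] estimates plus
#'   `d_a`, `x_c`, `se_d_a`, `se_x_c`, `vcov`, `loglik` and `convergence`.
#' @export
#' @examples
#' cts <- lop_counts()
#' tgt <- subset(cts, experiment == "e1" & condition == "category" &
#'               item_class == "target")
#' lur <- subset(cts, experiment == "e1" & condition == "category" &
#'               item_class == "colour_lure")
#' f <- fit_uvsdt(as.numeric(tgt[, 4:7]), as.numeric(lur[, 4:7]))
#' c(f$d_a, f$x_c)  # approximately 2.716, 1.640
fit_uvsdt <- function(old, new) {
  old <- as.numeric(old); new <- as.numeric(new)
  stopifnot(length(old) == 4, length(new) == 4, all(old >= 0), all(new >= 0))
  if (sum(old > 0) < 2 || sum(new > 0) < 2)
    stop("each item class needs responses in at least two rating categories")

  nll_t <- function(th) {
    inc <- pmax(exp(th[4:5]), 1e-9)
    cr <- cumsum(c(th[3], inc))
    sig <- exp(th[2])
    if (!all(is.finite(c(cr, sig))) || sig <= 0 || any(diff(cr) <= 0))
      return(1e10)
    uvsdt_negloglik(uvsdt_params(th[1], sig, cr), old, new)
  }
  cum <- pmin(pmax(cumsum(new)[1:3] / sum(new), 0.01), 0.99)
  cr0 <- stats::qnorm(cum)
  cr0 <- cummax(cr0 + c(0, 1e-3, 2e-3))  # guard equal empirical quantiles
  best <- NULL
  for (mu0 in c(0.5, 1.5, 2.5)) for (s0 in c(1, 1.5)) {
    th0 <- c(mu0, log(s0), cr0[1],
             log(max(cr0[2] - cr0[1], 1e-3)), log(max(cr0[3] - cr0[2], 1e-3)))
    f <- stats::optim(th0, nll_t, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || f$value < best$value) best <- f
  }
  th <- best$par
  mu <- th[1]; sigma <- exp(th[2])
  criteria <- cumsum(c(th[3], exp(th[4]), exp(th[5])))
  params <- uvsdt_params(mu, sigma, criteria)

  nll_nat <- function(p) {
    if (p[2] <= 0 || any(diff(p[3:5]) <= 0)) return(Inf)
    uvsdt_negloglik(uvsdt_params(p[1], p[2], p[3:5]), old, new)
  }
  V <- tryCatch({
    H <- stats::optimHess(c(mu, sigma, criteria), nll_nat)
    solve(H)
  }, error = function(e) NULL)
  if (is.null(V)) {
    warning("observed information not invertible; SEs unavailable")
    se_da <- se_xc <- NA_real_
  } else {
    grad_da <- c(sqrt(2 / (1 + sigma^2)),
                 -mu * sqrt(2) * sigma * (1 + sigma^2)^-1.5, 0, 0, 0)
    se_da <- sqrt(drop(grad_da %*% V %*% grad_da))
    se_xc <- sqrt(V[4, 4])
  }
  structure(c(params,
              list(d_a = da_from_params(mu, sigma), x_c = criteria[2],
                   se_d_a = se_da, se_x_c = se_xc, vcov = V,
                   loglik = -best$value, convergence = best$convergence)),
            class = c("uvsdt_fit", "uvsdt_params"))
}

#' @export
print.uvsdt_fit <- function(x, digits = 3, ...) {
  cat("UVSDT fit (ML, pooled counts)\n")
  cat(sprintf("  mu = %.*f, sigma = %.*f, criteria = %s\n", digits, x$mu,
              digits, x$sigma,
              paste(round(x$criteria, digits), collapse = ", ")))
  cat(sprintf("  d_a = %.*f (SE %.*f), x_c = %.*f (SE %.*f)\n",
              digits, x$d_a, digits, x$se_d_a, digits, x$x_c, digits, x$se_x_c))
  invisible(x)
}

#' Fit the UVSDT model to one cell of a rating-count table
#'
#' Convenience wrapper selecting the old- and new-class rows of a
#' [rating_counts()] table for one experiment and condition.
#'
#' @param counts a [rating_counts()] data frame.
#' @param experiment,condition row selectors.
#' @param old_class,new_class item-class labels (default: targets vs a
#'   lure class given in `new_class`).
#' @return An `uvsdt_fit`.
#' @export
fit_uvsdt_cell <- function(counts, experiment, condition, new_class,
                           old_class = "target") {
  pick <- function(cl) {
    r <- counts[counts$experiment == experiment &
                counts$condition == condition &
                counts$item_class == cl, c("r1", "r2", "r3", "r4")]
    if (nrow(r) != 1) stop("no unique row for item class '", cl, "'")
    as.numeric(r)
  }
  fit_uvsdt(pick(old_class), pick(new_class))
}

#' Two-sample Wald z test for independent parameter estimates
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)`, with a two-sided normal
#' p-value; the standard recipe for comparing detection-theory parameters
#' estimated from independent groups.
#'
#' @param est1,se1,est2,se2 estimates and standard errors.
#' @return List with `z` and `p_value`.
#' @export
#' @examples
#' wald_z(2.716, 0.1314, 1.422, 0.0811)$z  # 8.38
wald_z <- function(est1, se1, est2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
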