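#' Experiment design: group sizes and per-participant trial counts
#'
#' Describes a between-subjects recognition experiment with a 4-point
#' confidence scale: how many participants were run in each encoding
#' condition and how many test trials of each item class (targets and the
#' three lure types) every participant received.  The pooled trial total for
#' a (condition, item class) cell is `n_participants * trials_per_class`,
#' which is the multinomial sample size used by all pooled model fits.
#'
#' @param conditions named integer vector of participants per condition,
#'   e.g. `c(colour = 27, category = 26)`.
#' @param trials_per_class named integer vector of test trials per
#'   participant for each item class, e.g.
#'   `c(target = 27, category_lure = 9, colour_lure = 9, critical_lure = 9)`.
#' @param label optional experiment label.
#'
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(c(colour = 27, category = 26),
#'                   c(target = 27, category_lure = 9,
#'                     colour_lure = 9, critical_lure = 9))
experiment_design <- function(conditions, trials_per_class, label = NULL) {
  stopifnot(length(conditions) >= 1, length(trials_per_class) >= 1)
  if (is.null(names(conditions)) || is.null(names(trials_per_class)))
    stop("'conditions' and 'trials_per_class' must be named")
  if (any(conditions != round(conditions)) || any(conditions <= 0))
    stop("participant counts must be strictly positive integers")
  if (any(trials_per_class != round(trials_per_class)) || any(trials_per_class <= 0))
    stop("trial counts must be strictly positive integers")
  structure(list(conditions = conditions,
                 trials_per_class = trials_per_class,
                 n_rating_levels = 4L,
                 label = label),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  participants:", paste(names(x$conditions), x$conditions,
                               sep = "=", collapse = ", "), "\n")
  cat("  trials/participant:", paste(names(x$trials_per_class),
                                     x$trials_per_class,
                                     sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pooled trial total for one design cell
#'
#' @param design an [experiment_design()].
#' @param condition condition label.
#' @param item_class item class label.
#' @return Integer pooled number of trials.
#' @export
pooled_total <- function(design, condition, item_class) {
  stopifnot(inherits(design, "experiment_design"))
  n <- design$conditions[[condition]]
  t <- design$trials_per_class[[item_class]]
  if (is.null(n) || is.null(t)) stop("unknown condition or item class")
  as.integer(n * t)
}

#' Rating-count table constructor
#'
#' A `rating_counts` object is a data frame with one row per
#' (experiment, condition, item class) cell and integer response counts
#' `r1`..`r4` over the 4-point confidence scale
#' (1 = definitely new ... 4 = definitely old).
#'
#' @param experiment,condition,item_class character vectors (recycled).
#' @param r1,r2,r3,r4 non-negative integer counts.
#' @return A `rating_counts` data frame.
#' @export
rating_counts <- function(experiment, condition, item_class, r1, r2, r3, r4) {
  df <- data.frame(experiment = experiment, condition = condition,
                   item_class = item_class,
                   r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                   stringsAsFactors = FALSE)
  validate_rating_counts(df)
}

validate_rating_counts <- function(df) {
  need <- c("experiment", "condition", "item_class", "r1", "r2", "r3", "r4")
  if (!all(need %in% names(df)))
    stop("rating counts need columns: ", paste(need, collapse = ", "))
  cts <- as.matrix(df[, c("r1", "r2", "r3", "r4")])
  if (any(!is.finite(cts)) || any(cts < 0))
    stop("counts must be non-negative")
  if (any(cts != round(cts)))
    stop("counts must be integers")
  df[, c("r1", "r2", "r3", "r4")] <- lapply(df[, c("r1", "r2", "r3", "r4")],
                                            as.integer)
  class(df) <- c("rating_counts", "data.frame")
  df
}

# Largest-remainder (Hamilton) apportionment of `total` over proportions `p`.
# Ties in the fractional remainders are broken towards the lower index.
largest_remainder <- function(p, total) {
  stopifnot(all(p >= 0), total >= 0, total == round(total))
  if (sum(p) == 0) stop("proportions sum to zero")
  q <- p / sum(p) * total
  f <- floor(q)
  r <- as.integer(round(total - sum(f)))
  if (r > 0) {
    ord <- order(-(q - f), seq_along(q))
    f[ord[seq_len(r)]] <- f[ord[seq_len(r)]] + 1
  }
  as.integer(f)
}

#' Reconstruct pooled integer counts from a printed proportion table
#'
#' Published summary tables usually report the participant-mean proportion of
#' responses in each rating category.  When every participant contributes the
#' same number of trials per item class, the participant mean equals the
#' pooled proportion, so the pooled integer counts can be recovered as
#' `proportion * pooled total`, rounded by largest-remainder apportionment so
#' that each row sums exactly to its design total.  A cell whose rounded
#' count moves more than one unit away from `p * total` indicates
#' proportions inconsistent with the stated design and is rejected.
#'
#' @param proportions data frame with columns `experiment`, `condition`,
#'   `item_class`, `p1`..`p4` (each row summing to 1 within printing
#'   precision, +-0.003).
#' @param design an [experiment_design()] for the rows' experiment, or a
#'   named list of designs keyed by experiment label when `proportions`
#'   spans several experiments.
#' @return A [rating_counts()] data frame.
#' @export
#' @examples
#' d <- experiment_design(c(colour = 27, category = 26),
#'                        c(target = 27, category_lure = 9,
#'                          colour_lure = 9, critical_lure = 9))
#' pr <- data.frame(experiment = "e1", condition = "colour",
#'                  item_class = "category_lure",
#'                  p1 = 0.568, p2 = 0.309, p3 = 0.074, p4 = 0.049)
#' reconstruct_counts(pr, d)  # 138 75 18 12
reconstruct_counts <- function(proportions, design) {
  need <- c("experiment", "condition", "item_class", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(proportions)))
    stop("proportion table needs columns: ", paste(need, collapse = ", "))
  pm <- as.matrix(proportions[, c("p1", "p2", "p3", "p4")])
  if (any(pm < 0) || any(pm > 1)) stop("proportions must lie in [0, 1]")
  bad <- abs(rowSums(pm) - 1) > 0.003
  if (any(bad))
    stop("proportion rows do not sum to 1 within printing precision: row(s) ",
         paste(which(bad), collapse = ", "))
  get_design <- function(exp) {
    if (inherits(design, "experiment_design")) return(design)
    d <- design[[exp]]
    if (is.null(d)) stop("no design supplied for experiment '", exp, "'")
    d
  }
  out <- proportions[, c("experiment", "condition", "item_class")]
  cts <- matrix(0L, nrow(proportions), 4)
  for (i in seq_len(nrow(proportions))) {
    d <- get_design(proportions$experiment[i])
    total <- pooled_total(d, proportions$condition[i], proportions$item_class[i])
    k <- largest_remainder(pm[i, ], total)
    if (any(abs(k - pm[i, ] * total) > 1 + 1e-9))
      stop("proportions inconsistent with design in row ", i,
           " (adjustment beyond +-1 per cell)")
    cts[i, ] <- k
  }
  out$r1 <- cts[, 1]; out$r2 <- cts[, 2]; out$r3 <- cts[, 3]; out$r4 <- cts[, 4]
  validate_rating_counts(out)
}

#' Descriptive statistics of one rating distribution
#'
#' The acceptance ("old") rate is the proportion of rating-3 and rating-4
#' responses — the hit rate for targets, the false-alarm rate for lures.
#' The mean rating is the expectation of the 4-point confidence scale.
#'
#' @param x numeric vector of length 4: either proportions `p1..p4` or
#'   counts `r1..r4` (any non-negative vector is normalised).
#' @return List with elements `rate` (in `[0, 1]`) and `mean_rating`
#'   (in `[1, 4]`).
#' @export
#' @examples
#' descriptives(c(0.089, 0.165, 0.199, 0.547))  # rate 0.746, mean 3.204
descriptives <- function(x) {
  stopifnot(length(x) == 4, all(x >= 0), sum(x) > 0)
  p <- x / sum(x)
  list(rate = unname(p[3] + p[4]),
       mean_rating = unname(sum(p * 1:4)))
}

#' Read / write rating-count tables as CSV
#'
#' Plain CSV with header `experiment,condition,item_class,r1,r2,r3,r4`.
#' The round trip is lossless.
#'
#' @param path file path.
#' @return `read_counts_csv` returns a [rating_counts()] data frame.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "condition", "item_class", "r1", "r2", "r3", "r4")
  if (!identical(names(df), need))
    stop("malformed header: expected ", paste(need, collapse = ","))
  validate_rating_counts(df)
}

#' @rdname read_counts_csv
#' @param counts a [rating_counts()] data frame.
#' @export
write_counts_csv <- function(counts, path) {
  counts <- validate_rating_counts(as.data.frame(counts))
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
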