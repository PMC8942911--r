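#' Bundled levels-of-processing false-memory dataset
#'
#' The package ships the pooled summary data of two between-subjects
#' recognition-memory experiments on levels of processing and false memory.
#' Experiment "e1" used concrete words printed in coloured fonts
#' (colour-naming N = 27, category-naming N = 26; 27 targets and 9 lures of
#' each type per participant at test); experiment "e2" used door-scene
#' photographs (colour N = 35, category N = 36; 18 targets, 6 category
#' lures, 6 colour lures, 9 critical lures).  Test items were judged on a
#' 4-point confidence scale (1 = definitely new ... 4 = definitely old).
#' Lures matched the targets in semantic category only ("category lures"),
#' in colour only ("colour lures"), or in both ("critical lures").
#'
#' `lop_proportions()` returns the published participant-mean rating
#' proportions per cell; `lop_designs()` the two experiment designs;
#' `lop_counts()` the pooled integer counts obtained by
#' [reconstruct_counts()] (exact because every participant contributed the
#' same number of trials per item class); `lop_reference_values()` the
#' summary-model estimates reported with the original experiments, used by
#' [reproduce_study()] as comparison values.
#'
#' @return `lop_proportions()`: data frame with `p1..p4` and `mean_rating`;
#'   `lop_designs()`: named list of [experiment_design()] objects;
#'   `lop_counts()`: a [rating_counts()] data frame (16 rows);
#'   `lop_reference_values()`: data frame `quantity, reference, tolerance`.
#' @name lop_data
NULL

lop_file <- function(f) system.file("extdata", f, package = "mptsdt",
                                    mustWork = TRUE)

#' @rdname lop_data
#' @export
lop_proportions <- function() {
  utils::read.csv(lop_file("lop_rating_proportions.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname lop_data
#' @export
lop_designs <- function() {
  raw <- yaml::read_yaml(lop_file("lop_designs.yaml"))
  lapply(raw, function(d)
    experiment_design(unlist(d$conditions), unlist(d$trials_per_class),
                      label = d$label))
}

#' @rdname lop_data
#' @export
lop_counts <- function() {
  reconstruct_counts(lop_proportions(), lop_designs())
}

#' @rdname lop_data
#' @export
lop_reference_values <- function() {
  utils::read.csv(lop_file("lop_reference_values.csv"),
                  stringsAsFactors = FALSE)
}
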