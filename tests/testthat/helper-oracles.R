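# Independent branch-path enumerator: evaluates each branch's path string
# term by term and sums products per (tree, category).  Deliberately avoids
# the package's compiled position-wise evaluation.
oracle_probs <- function(model, params) {
  b <- model$branches
  bp <- vapply(seq_len(nrow(b)), function(i) {
    terms <- strsplit(gsub(" ", "", b$path[i]), "*", fixed = TRUE)[[1]]
    prod(vapply(terms, function(tk) {
      if (grepl("^\\(1-", tk)) 1 - params[[sub("^\\(1-(.+)\\)$", "\\1", tk)]]
      else params[[tk]]
    }, 0))
  }, 0)
  agg <- tapply(bp, list(paste(b$tree, b$category, sep = "\r")), sum)
  out <- lapply(unique(b$tree), function(tr) {
    cats <- sort(unique(b$category[b$tree == tr]))
    stats::setNames(as.numeric(agg[paste(tr, cats, sep = "\r")]), cats)
  })
  stats::setNames(out, unique(b$tree))
}

# random interior parameter vector for every slot of a model
random_slot_values <- function(model, lo = 0.05, hi = 0.95) {
  stats::setNames(stats::runif(length(model$slots), lo, hi), model$slots)
}

# a tiny one-parameter model: theta -> "a", (1-theta) -> "b"
toy_one_param <- function() {
  mpt_model(data.frame(tree = "t", category = c("a", "b"),
                       path = c("theta", "(1-theta)")))
}

# single-condition 2HTM data simulated at given seed, pooled counts only
sim_null_counts <- function(seed, scale = 1) {
  sp <- scenario_spec("null", seed = seed)
  if (scale != 1) {
    d <- sp$design
    sp$design <- experiment_design(d$conditions * scale, d$trials_per_class)
  }
  simulate_2htm(sp, replicate = 1)$counts
}
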