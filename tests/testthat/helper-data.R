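# Build a deterministic person-level dataset from per-cell outcome counts.
# `yes` and `no` are K x K matrices of outcome-positive / -negative counts
# indexed (origin, destination).
cell_count_data <- function(yes, no, levels = education_levels()) {
  rows <- list()
  for (i in seq_along(levels)) {
    for (j in seq_along(levels)) {
      n1 <- yes[i, j]; n0 <- no[i, j]
      if (n1 + n0 == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        origin = levels[i], destination = levels[j],
        outcome = rep(c(1L, 0L), c(n1, n0)))
    }
  }
  out <- do.call(rbind, rows)
  out$origin <- as_education(out$origin)
  out$destination <- as_education(out$destination)
  out$age <- 30
  out
}

# Small synthetic cohort at the male defaults with overridable size/seed.
quick_cohort <- function(n = 2000, seed = 1, sex = "male", ...) {
  simulate_cohort(default_sim_config(sex, n = n, ...), seed = seed)
}
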