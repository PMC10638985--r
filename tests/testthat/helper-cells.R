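# Heavy simulation cells shared by the acceptance tests, computed once per
# test run and memoised.  Study conditions: 500 x 20 binary data, population
# loading 0.35, median split, shared-row planned missingness; 100
# replications per cell with B = 100 bootstrap resamples for Gamma.

.cell_cache <- new.env(parent = emptyenv())

acceptance_cell <- function(columns, rate, model, reps = 100, B = 100) {
  key <- paste(columns, rate, model, reps, B, sep = "_")
  if (is.null(.cell_cache[[key]])) {
    cell <- design_cell(columns, rate, model, "fixed", reps = reps,
                        master_seed = 20260921L)
    .cell_cache[[key]] <- run_cell(cell, B = B)
  }
  .cell_cache[[key]]
}

cell_mean <- function(summary, index) {
  summary$stats$mean[summary$stats$index == index]
}
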