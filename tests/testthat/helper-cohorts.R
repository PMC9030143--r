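# Small cohorts shared across test files, built once per test run.
# Sizes are deliberately tiny: the unit suite exercises correctness, not
# statistical power (the acceptance tests use the desk-scale designs).

tinyCohort <- function(groups = c(NC = 8, AD = 8), roiCount = 10,
                       framesPerScan = 60, edgeEffect = 0.8,
                       seed = 101, ...) {
  simulateCohort(cohortSpec(roiCount = roiCount,
                            framesPerScan = framesPerScan, groups = groups,
                            edgeEffect = edgeEffect, seed = seed, ...))
}

tinyHyper <- function(epochs = 15, valFraction = 0.25, ...) {
  modelHyper(epochs = epochs, hidden = 8L, featureDim = 8L,
             cnnBlocks = list(c(4L, 5L, 2L), c(8L, 5L, 2L), c(8L, 5L, 2L)),
             valFraction = valFraction, ...)
}

randomFC <- function(R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(5 * R * R), 5 * R, R)
  pearsonFC(roiTimeSeries(x))
}
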