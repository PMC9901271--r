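# Shared fixtures: the worked example and small simulated datasets.

exampleFixture <- ssramExample()

# random pedigree with scrambled row order, for label-determinism checks
scrambleRows <- function(df, seed = 1) {
  set.seed(seed)
  df[sample(nrow(df)), , drop = FALSE]
}

# simulated dataset small enough for dense oracles
smallSim <- function(seed, ...) {
  args <- utils::modifyList(
    list(nFounders = 14, nGenerations = 3, nMatingsPerGen = 8,
         progenyPerMating = 2, nMarkers = 60,
         genotypedFraction = 0.3, phenotypedFraction = 0.6, seed = seed),
    list(...))
  do.call(simulateDataset, args)
}

# marker data centered at the true founder frequencies (observed-frequency
# centering leaves G singular by construction)
simMarkers <- function(sim, ...) markerData(sim$geno, alleleFreq = sim$freq, ...)

# absolute-difference comparison of named vectors / labelled matrices
expectNamedEqual <- function(got, want, tol) {
  expect_true(all(names(want) %in% names(got)))
  expect_lt(max(abs(unname(got[names(want)]) - unname(want))), tol)
}

expectMatrixEqual <- function(got, want, tol) {
  got <- as.matrix(got)[rownames(want), colnames(want), drop = FALSE]
  expect_lt(max(abs(got - want)), tol)
}
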