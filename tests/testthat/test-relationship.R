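test_that("tabular A reproduces known relationship values", {
  ex <- exampleFixture
  A <- tabularA(ex$ped)
  ## genotyped pair: half-sib parents make animal 10 inbred
  expect_equal(A["5", "10"], 0.625)
  expect_equal(A["10", "10"], 1.125)
  ## slice route agrees with the full computation
  A22 <- tabularA(ex$ped, c("5", "10"))
  expect_equal(A22, A[c("5", "10"), c("5", "10")])

  founders <- Pedigree(letters[1:4])
  expect_equal(tabularA(founders), diag(4) + 0,
               ignore_attr = TRUE)

  fs <- Pedigree(c("s", "d", "x", "y"), sire = c(0, 0, "s", "s"),
                 dam = c(0, 0, "d", "d"))
  Afs <- tabularA(fs)
  expect_equal(Afs["x", "x"], 1)
  expect_equal(Afs["x", "y"], 0.5)
})

test_that("inbreeding and Mendelian-sampling variances follow the D rules", {
  ex <- exampleFixture
  mv <- inbreeding(ex$ped)
  F <- setNames(mv$F, mv$id)
  D <- setNames(mv$D, mv$id)
  expect_equal(unname(F["10"]), 0.125)   # parents are paternal half-sibs
  expect_equal(unname(F[as.character(1:9)]), rep(0, 9))
  expect_equal(unname(D[c("9", "11", "12")]), c(0.5, 0.5, 0.5))
  expect_equal(unname(D["8"]), 0.75)     # single known, non-inbred parent
  expect_equal(unname(D["1"]), 1)        # founder

  ## F agrees with the tabular diagonal on random pedigrees, and D never
  ## increases when a parent becomes known
  for (seed in 1:3) {
    set.seed(seed)
    sim <- simulatePedigree(nFounders = 10, nGenerations = 4,
                            nMatingsPerGen = 6, progenyPerMating = 2)
    mv <- inbreeding(sim$ped)
    expect_equal(mv$F, diag(tabularA(sim$ped)) - 1,
                 ignore_attr = TRUE, tolerance = 1e-12)
    ## drop each animal's dam: D must not decrease
    ped2 <- Pedigree(animalIds(sim$ped), sireIds(sim$ped), NA)
    mv2 <- inbreeding(ped2)
    expect_true(all(mv2$D >= mv$D - 1e-12))
  }
})

test_that("Henderson's rules reproduce the printed sparse inverse entries", {
  ex <- exampleFixture
  Ai6 <- 6 * as.matrix(aInverse(ex$ped))
  expect_equal(Ai6["4", "4"], 16)
  expect_equal(Ai6["4", "5"], 3)
  expect_equal(Ai6["4", "8"], -4)
  expect_equal(Ai6["2", "2"], 10)
  expect_equal(6 * as.matrix(aInverse(Pedigree(letters[1:3]))), 6 * diag(3),
               ignore_attr = TRUE)
})

test_that("sparse A-inverse inverts the tabular A on random pedigrees", {
  set.seed(99)
  sim <- simulatePedigree(nFounders = 30, nGenerations = 4,
                          nMatingsPerGen = 30, progenyPerMating = 3,
                          pMissingSire = 0.1, pMissingDam = 0.1)
  expect_gt(nAnimals(sim$ped), 250)
  A <- tabularA(sim$ped)
  Ai <- aInverse(sim$ped)
  I <- as.matrix(Ai %*% A)
  expect_lt(max(abs(I - diag(nrow(A)))), 1e-10)
})

test_that("subset inverse equals the inverse of the tabular slice", {
  ex <- exampleFixture
  Ai <- aInverse(ex$ped)
  for (keep in list(c("5", "10"), as.character(c(1:7, 10)),
                    as.character(c(4:7, 10)),
                    as.character(c(4, 5, 9, 10, 11, 12)))) {
    S <- as.matrix(subsetInverse(Ai, keep))
    Aslice <- tabularA(ex$ped, keep)
    expect_lt(max(abs(S %*% Aslice - diag(length(keep)))), 1e-9)
  }
  ## keep-all is a no-op
  expect_equal(as.matrix(subsetInverse(Ai, rownames(Ai))), as.matrix(Ai),
               tolerance = 1e-14)

  ## random pedigrees and random subsets
  for (seed in 1:3) {
    set.seed(seed)
    sim <- simulatePedigree(nFounders = 12, nGenerations = 3,
                            nMatingsPerGen = 8, progenyPerMating = 2)
    ids <- animalIds(sim$ped)
    keep <- sample(ids, max(3, length(ids) %/% 3))
    S <- as.matrix(subsetInverse(aInverse(sim$ped), keep))
    expect_lt(max(abs(S %*% tabularA(sim$ped, keep) - diag(length(keep)))),
              1e-9)
  }
})

test_that("general subsets need the Schur route, not pruned Henderson rules", {
  ex <- exampleFixture
  ## {5,10} is not ancestor-closed: Henderson rules on the restricted
  ## pedigree give the wrong inverse, the Schur complement the right one
  keep <- c("5", "10")
  henderson <- as.matrix(aInverse(Pedigree(keep)))  # restricted: founders
  schur <- as.matrix(subsetInverse(aInverse(ex$ped), keep))
  expect_gt(max(abs(henderson - schur)), 0.3)
  ## but on an ancestor-closed subset the two routes coincide
  closed <- c("2", "5", "6", "1", "4", "3", "7")
  sub <- Pedigree(closed,
                  sire = sireIds(ex$ped)[match(closed, animalIds(ex$ped))],
                  dam = damIds(ex$ped)[match(closed, animalIds(ex$ped))])
  h2 <- as.matrix(aInverse(sub))[closed, closed]
  s2 <- as.matrix(subsetInverse(aInverse(ex$ped), closed))[closed, closed]
  expect_lt(max(abs(h2 - s2)), 1e-10)
})
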