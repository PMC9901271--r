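ramSetup <- function() {
  ex <- exampleFixture
  sets <- classifyAnimals(ex$ped, ex$genotyped, ex$records$animal)
  mv <- inbreeding(ex$ped)
  list(ex = ex, sets = sets, mv = mv)
}

test_that("reduced design has parent-average rows and inflated residuals", {
  s <- ramSetup()
  rd <- buildReducedDesign(s$ex$records, s$ex$ped, s$sets, s$mv, s$ex$vc, 1)
  W <- as.matrix(rd$W)
  rownames(W) <- s$ex$records$animal
  expectMatrixEqual(W, s$ex$expected$W, 1e-12)
  ## absorbed records of 9, 11, 12: (sigmaE2 + D sigmaA2)^-1 = 0.4
  names(rd$RtildeInv) <- s$ex$records$animal
  expectNamedEqual(rd$RtildeInv, s$ex$expected$RtildeNn, 1e-12)
  expect_equal(unname(rd$RtildeInv[c("4", "5", "10")]), rep(0.5, 3))
  ## row sums: 1 for kept records, number-of-known-parents/2 for absorbed
  expect_equal(unname(rowSums(W)), c(1, 1, 1, 1, 1, 1))

  rdq <- buildReducedDesign(s$ex$records, s$ex$ped, s$sets, s$mv, s$ex$vc, 3)
  Wq <- as.matrix(rdq$W)
  rownames(Wq) <- s$ex$records$animal
  expectMatrixEqual(Wq, s$ex$expected$Wq, 1e-12)

  ## method 2 never inflates (no absorbed records by construction)
  rd2 <- buildReducedDesign(s$ex$records, s$ex$ped, s$sets, s$mv, s$ex$vc, 2)
  expect_equal(unname(rd2$RtildeInv), rep(0.5, 6))
  expect_equal(unname(Matrix::rowSums(rd2$W)), rep(1, 6))
})

test_that("absorbed record with both parents unknown gets D = 1 inflation", {
  ped <- Pedigree(c("g1", "g2", "x"), sire = c(0, 0, 0))
  recs <- data.frame(animal = "x", value = 3)
  vc <- varianceComponents(sigmaA2 = 1, sigmaE2 = 2)
  sets <- classifyAnimals(ped, c("g1", "g2"), "x")
  rd <- buildReducedDesign(recs, ped, sets, inbreeding(ped), vc, 1)
  expect_equal(sum(abs(rd$W)), 0)               # no known parents
  expect_equal(rd$RtildeInv, 1 / (2 + 1))       # (sigmaE2 + sigmaA2)^-1
})

test_that("Mendelian-sampling regression uses B = D sA2 / (R + D sA2)", {
  expect_equal(mendelianB(0.5, 1, 2), 0.2)
  expect_equal(mendelianB(0.75, 1, 2), 3 / 11)
  ## B in (0,1), vanishing with sigmaA2
  expect_true(all(mendelianB(c(0.5, 0.75, 1), 1e-12, 2) < 1e-11))
  set.seed(1)
  Bs <- mendelianB(runif(20, 0.25, 1), runif(20, 0.1, 5), runif(20, 0.1, 5))
  expect_true(all(Bs > 0 & Bs < 1))
})

test_that("method 1 reproduces the reduced solutions and back-solves", {
  ex <- exampleFixture
  sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                fixed = ex$fixed, method = 1, details = TRUE)
  expect_equal(systemOrder(attr(sol, "system")), 10)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatP1, 5e-5)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatN1, 5e-5)
  prov <- solutionProvenance(sol)
  expect_setequal(names(prov)[prov == "backsolved"], ex$expected$m1n)
  ## the adjusted records driving the back-solve
  d <- buildDesign(ex$records, ex$ped, ex$fixed, ex$vc)
  adj <- setNames(ex$records$value - as.numeric(d$X %*% fixedSolutions(sol)),
                  ex$records$animal)
  expectNamedEqual(adj, ex$expected$adjustedRecords1, 5e-5)
  ## nonphenotyped absorbed animal 8 = half its sire's solution
  expect_equal(unname(animalSolutions(sol)["8"]),
               unname(animalSolutions(sol)["4"]) / 2)
})

test_that("method 2 solves the kept set and back-solves through A-inverse", {
  ex <- exampleFixture
  sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                fixed = ex$fixed, method = 2, details = TRUE)
  expect_equal(systemOrder(attr(sol, "system")), 8)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatP2, 5e-5)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatN2, 5e-5)
})

test_that("method 3 solves q and back-solves r then n", {
  ex <- exampleFixture
  sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                fixed = ex$fixed, method = 3, details = TRUE)
  expect_equal(systemOrder(attr(sol, "system")), 7)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatQ3, 5e-5)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatR3, 5e-5)
  expectNamedEqual(animalSolutions(sol), ex$expected$aHatN1, 5e-5)
})

test_that("back-solving r uses only pedigree blocks of the p-subset inverse", {
  ex <- exampleFixture
  sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                fixed = ex$fixed, method = 3)
  sets <- classifyAnimals(ex$ped, ex$genotyped, ex$records$animal)
  AppInv <- subsetInverse(aInverse(ex$ped), sets@m1p)   # no genomic terms
  a <- animalSolutions(sol)
  manual <- -as.numeric(Matrix::solve(
    AppInv[sets@m3r, sets@m3r],
    AppInv[sets@m3r, sets@m3q] %*% a[sets@m3q]))
  expect_equal(unname(a[sets@m3r]), manual, tolerance = 1e-12)
  ## same for method 2 with full A-inverse blocks
  sol2 <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                 fixed = ex$fixed, method = 2)
  Ai <- aInverse(ex$ped)
  a2 <- animalSolutions(sol2)
  manual2 <- -as.numeric(Matrix::solve(
    Ai[sets@m2n, sets@m2n], Ai[sets@m2n, sets@m2p] %*% a2[sets@m2p]))
  expect_equal(unname(a2[sets@m2n]), manual2, tolerance = 1e-12)
})

test_that("all three reduced models equal the full model on the example", {
  ex <- exampleFixture
  full <- solveFull(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                    fixed = ex$fixed)
  for (m in 1:3) {
    sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = ex$vc,
                  fixed = ex$fixed, method = m)
    expect_lt(max(abs(animalSolutions(sol) - animalSolutions(full))), 1e-10)
    expect_lt(max(abs(fixedSolutions(sol) - fixedSolutions(full))), 1e-10)
  }
})

test_that("system orders shrink monotonically across the reductions", {
  for (seed in c(21, 22)) {
    sim <- smallSim(seed)
    md <- simMarkers(sim)
    G <- buildG(md)
    orders <- sapply(1:3, function(m) {
      sol <- runRAM(sim$records, sim$ped, sim$genotyped, G = G, vc = sim$vc,
                    fixed = sim$fixed, method = m, details = TRUE)
      systemOrder(attr(sol, "system"))
    })
    full <- nAnimals(sim$ped) + 2
    expect_lte(orders[3], orders[1])
    expect_lte(orders[1], full)
  }
})

test_that("as genetic variance vanishes, absorbed solutions tend to parent averages", {
  ex <- exampleFixture
  vc0 <- varianceComponents(sigmaA2 = 1e-8, sigmaE2 = 2)
  ## G on the same scale: keep as-is (relationships, not variances)
  sol <- runRAM(ex$records, ex$ped, ex$genotyped, G = ex$G, vc = vc0,
                fixed = ex$fixed, method = 1)
  a <- animalSolutions(sol)
  expect_lt(abs(a["9"] - (a["4"] + a["5"]) / 2), 1e-6)
  expect_lt(abs(a["11"] - (a["6"] + a["7"]) / 2), 1e-6)
})

test_that("reduction of nothing: with no absorbable animals RAM equals the full system", {
  ## every animal genotyped: p = all, no back-solving
  sim <- smallSim(31, genotypedFraction = 1)
  md <- simMarkers(sim)
  G <- buildG(md)
  G <- G + diag(0.01, nrow(G))  # keep well-conditioned at full density
  sol <- runRAM(sim$records, sim$ped, sim$genotyped, G = G, vc = sim$vc,
                fixed = sim$fixed, method = 1, details = TRUE)
  expect_equal(systemOrder(attr(sol, "system")), nAnimals(sim$ped) + 2)
  full <- solveFull(sim$records, sim$ped, sim$genotyped, G = G, vc = sim$vc,
                    fixed = sim$fixed)
  expect_lt(max(abs(animalSolutions(sol) - animalSolutions(full))), 1e-8)
  expect_true(all(solutionProvenance(sol) == "direct"))
})

test_that("RAM equals full ssGBLUP on random simulated data", {
  for (seed in c(101, 202, 303)) {
    sim <- smallSim(seed)
    md <- simMarkers(sim)
    full <- solveFull(sim$records, sim$ped, markers = md, vc = sim$vc,
                      fixed = sim$fixed)
    G <- buildG(md)
    for (m in 1:3) {
      sol <- runRAM(sim$records, sim$ped, sim$genotyped, G = G, vc = sim$vc,
                    fixed = sim$fixed, method = m)
      expect_lt(max(abs(animalSolutions(sol) - animalSolutions(full))), 1e-8)
    }
  }
})
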