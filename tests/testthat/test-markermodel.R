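ssmmVc <- function(sa = 0.7, sd = 0.3, se = 2)
  varianceComponents(sigmaE2 = se, sigmaAlpha2 = sa, sigmaDelta2 = sd)

test_that("imputation gives parent averages for terminal progeny", {
  ped <- Pedigree(c("s", "d", "x"), sire = c(0, 0, "s"), dam = c(0, 0, "d"))
  M2 <- matrix(c(1, -1, 0.5, 0.2), 2, 2,
               dimnames = list(c("s", "d"), c("m1", "m2")))
  M1 <- imputeM1(aInverse(ped), M2)
  expect_equal(M1["x", ], colMeans(M2), ignore_attr = TRUE, tolerance = 1e-12)
  ## zero observed genotypes impute to zero
  expect_equal(max(abs(imputeM1(aInverse(ped), M2 * 0))), 0)
})

test_that("sparse imputation matches a dense linear solve", {
  set.seed(8)
  ex <- exampleFixture
  geno <- geneDrop(ex$ped, runif(30, 0.2, 0.8))
  md <- markerData(geno[ex$genotyped, , drop = FALSE])
  Ai <- aInverse(ex$ped)
  nong <- setdiff(animalIds(ex$ped), ex$genotyped)
  M1 <- imputeM1(Ai, md@centered)
  dense <- -solve(as.matrix(Ai)[nong, nong],
                  as.matrix(Ai)[nong, ex$genotyped] %*% md@centered)
  expect_lt(max(abs(M1[nong, ] - dense)), 1e-10)
  ## imputation is invariant to which animal set hosts the system
  sets <- classifyAnimals(ex$ped, ex$genotyped, ex$records$animal)
  Appi <- subsetInverse(Ai, sets@m1p)
  M1p <- imputeM1(Appi, md@centered)
  common <- intersect(rownames(M1p), rownames(M1))
  expect_lt(max(abs(M1p[common, ] - M1[common, ])), 1e-9)
})

test_that("full marker model equals equivalent-G ssGBLUP", {
  for (seed in c(7, 17)) {
    sim <- smallSim(seed)
    md <- simMarkers(sim)
    vc <- ssmmVc()
    sol <- runSSMM(sim$records, sim$ped, md, vc, sim$fixed, sim$genotyped)
    M2s <- md@centered[sim$genotyped, , drop = FALSE]
    A22 <- tabularA(sim$ped, sim$genotyped)
    Geq <- (tcrossprod(M2s) * vc$sigmaAlpha2 + A22 * vc$sigmaDelta2) /
      vc$sigmaA2
    ss <- solveFull(sim$records, sim$ped, sim$genotyped, G = Geq, vc = vc,
                    fixed = sim$fixed)
    expect_lt(max(abs(totalMerit(sol) - animalSolutions(ss))), 1e-6)
  }
})

test_that("ssmm system bookkeeping: effect counts and epsilon span", {
  sim <- smallSim(9)
  md <- simMarkers(sim)
  a <- assembleSSMM(sim$records, sim$ped, md, ssmmVc(), sim$fixed,
                    sim$genotyped, method = "full")
  tab <- table(a$sys@effects$type)
  nong <- setdiff(animalIds(sim$ped), sim$genotyped)
  expect_equal(unname(tab["epsilon"]), length(nong))
  expect_equal(unname(tab["delta"]), nAnimals(sim$ped))
  expect_equal(unname(tab["marker"]), ncol(md@centered))

  ## reduced method 3: delta spans q, epsilon the nongenotyped part of q
  sets <- classifyAnimals(sim$ped, sim$genotyped, sim$records$animal)
  a3 <- assembleSSMM(sim$records, sim$ped, md, ssmmVc(), sim$fixed,
                     sim$genotyped, method = 3)
  tab3 <- table(a3$sys@effects$type)
  expect_equal(unname(tab3["delta"]), length(sets@m3q))
  expect_equal(unname(tab3["epsilon"]),
               length(setdiff(sets@m3q, sets@genotyped)))
})

test_that("epsilon vanishes when every animal is genotyped", {
  sim <- smallSim(13, genotypedFraction = 1)
  md <- simMarkers(sim)
  sol <- runSSMM(sim$records, sim$ped, md, ssmmVc(), sim$fixed,
                 sim$genotyped)
  expect_length(sol@epsilon, 0)
})

test_that("zero markers collapse the marker model to pedigree BLUP", {
  sim <- smallSim(19)
  vc <- ssmmVc(sa = 0.5, sd = 1, se = 2)   # sigmaA2 = 1.5
  sol <- runSSMM(sim$records, sim$ped, NULL, vc, sim$fixed,
                 genotyped = character(0))
  blup <- solveFull(sim$records, sim$ped,
                    vc = varianceComponents(sigmaA2 = vc$sigmaDelta2,
                                            sigmaE2 = 2),
                    fixed = sim$fixed)
  expect_length(sol@alpha, 0)
  expect_length(sol@epsilon, 0)
  expect_lt(max(abs(sol@delta[animalIds(sim$ped)] -
                      animalSolutions(blup))), 1e-9)
  expect_lt(max(abs(totalMerit(sol) - animalSolutions(blup))), 1e-9)
})

test_that("reduced marker models equal the full marker model", {
  for (seed in c(23, 29)) {
    sim <- smallSim(seed)
    md <- simMarkers(sim)
    vc <- ssmmVc()
    full <- runSSMM(sim$records, sim$ped, md, vc, sim$fixed, sim$genotyped)
    for (m in c("1", "2", "3")) {
      red <- runSSMM(sim$records, sim$ped, md, vc, sim$fixed, sim$genotyped,
                     method = m)
      expect_lt(max(abs(totalMerit(red) - totalMerit(full))), 1e-8)
      expect_lt(max(abs(red@epsilon[names(full@epsilon)] - full@epsilon)),
                1e-8)
      expect_lt(max(abs(red@delta[names(full@delta)] - full@delta)), 1e-8)
      expect_lt(max(abs(fixedSolutions(red) - fixedSolutions(full))), 1e-8)
    }
  }
})

test_that("back-solve honours the genotyped-parent epsilon-zero rule", {
  ## x: phenotyped nonparent, genotyped sire + nongenotyped dam
  ped <- Pedigree(c("s", "d", "g2", "x"), sire = c(0, 0, 0, "s"),
                  dam = c(0, 0, 0, "d"))
  set.seed(3)
  geno <- geneDrop(ped, runif(40, 0.3, 0.7))[c("s", "g2"), , drop = FALSE]
  recs <- data.frame(animal = c("d", "x"), value = c(10.2, 11.5))
  vc <- ssmmVc()
  md <- markerData(geno)
  full <- runSSMM(recs, ped, md, vc, ~1, c("s", "g2"))
  red <- runSSMM(recs, ped, md, vc, ~1, c("s", "g2"), method = 1)
  expect_equal(unname(solutionProvenance(red)["x"]), "backsolved")
  expect_lt(max(abs(totalMerit(red) - totalMerit(full))), 1e-8)
  expect_lt(abs(red@epsilon[["x"]] - full@epsilon[["x"]]), 1e-8)
  ## manual recomputation of the joint back-solve for x
  d <- buildDesign(recs, ped, ~1, vc)
  xb <- as.numeric(d$X %*% fixedSolutions(red))[2]
  paMerit <- (totalMerit(red)[["s"]] + totalMerit(red)[["d"]]) / 2
  paEps <- red@epsilon[["d"]] / 2    # genotyped sire contributes zero
  B <- mendelianB(0.5, vc$sigmaA2, vc$sigmaE2)
  dev <- B * (11.5 - xb - paMerit)
  expect_equal(totalMerit(red)[["x"]], paMerit + dev, tolerance = 1e-10)
  expect_equal(red@epsilon[["x"]],
               paEps + vc$sigmaAlpha2 / vc$sigmaA2 * dev, tolerance = 1e-10)
})
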