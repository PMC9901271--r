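## The worked 12-animal example dataset, with the catalogue of expected
## intermediate matrices and solutions used throughout the test suite.

#' Worked 12-animal single-step example
#'
#' A small pedigree of 12 animals (3 founders; animals with odd labels are
#' female), two genotyped animals (5 and 10) with a given 2x2 genomic
#' relationship matrix, six phenotyped animals, a sex fixed effect, additive
#' genetic variance 1 and residual variance 2. The returned list carries the
#' inputs ready for [solveFull()], [runRAM()] and [runSSMM()], plus an
#' `expected` catalogue of the known intermediate matrices and solution
#' vectors of this example (to 4 decimals where decimal, exact rationals
#' where integer-over-6 or -over-3), which the package's tests reproduce.
#'
#' @return list with `ped`, `records`, `genotyped`, `G`, `vc`, `fixed` and
#'   `expected`.
#' @examples
#' ex <- ssramExample()
#' sol <- solveFull(ex$records, ex$ped, ex$genotyped, G = ex$G,
#'                  vc = ex$vc, fixed = ex$fixed)
#' round(animalSolutions(sol), 4)
#' @export
ssramExample <- function() {
  ped <- Pedigree(id = as.character(1:12),
                  sire = c(0, 0, 0, 0, 2, 2, 0, 4, 4, 6, 6, 4),
                  dam  = c(0, 0, 0, 1, 0, 0, 3, 0, 5, 5, 7, 7))
  records <- data.frame(
    animal = as.character(c(4, 5, 9, 10, 11, 12)),
    value = c(5.64, 4.30, 4.32, 5.39, 7.72, 4.36),
    sex = c("m", "f", "f", "m", "f", "m"),   # odd labels female
    stringsAsFactors = FALSE)
  G <- matrix(c(0.96, 0.56, 0.56, 1.16), 2, 2,
              dimnames = list(c("5", "10"), c("5", "10")))
  vc <- varianceComponents(sigmaA2 = 1, sigmaE2 = 2)

  lab <- function(M, l) {
    dimnames(M) <- list(l, l)
    M
  }
  p1 <- as.character(c(1:7, 10))
  q3 <- as.character(c(4:7, 10))
  p2 <- as.character(c(4, 5, 9, 10, 11, 12))

  aInv6 <- matrix(c(
     8,  0,  0, -4,  0,  0,  0,  0,  0,  0,  0,  0,
     0, 10,  0,  0, -4, -4,  0,  0,  0,  0,  0,  0,
     0,  0,  8,  0,  0,  0, -4,  0,  0,  0,  0,  0,
    -4,  0,  0, 16,  3,  0,  3, -4, -6,  0,  0, -6,
     0, -4,  0,  3, 14,  3,  0,  0, -6, -6,  0,  0,
     0, -4,  0,  0,  3, 14,  3,  0,  0, -6, -6,  0,
     0,  0, -4,  3,  0,  3, 14,  0,  0,  0, -6, -6,
     0,  0,  0, -4,  0,  0,  0,  8,  0,  0,  0,  0,
     0,  0,  0, -6, -6,  0,  0,  0, 12,  0,  0,  0,
     0,  0,  0,  0, -6, -6,  0,  0,  0, 12,  0,  0,
     0,  0,  0,  0,  0, -6, -6,  0,  0,  0, 12,  0,
     0,  0,  0, -6,  0,  0, -6,  0,  0,  0,  0, 12), 12, 12, byrow = TRUE)

  appInv6 <- matrix(c(
     8,  0,  0, -4,  0,  0,  0,  0,
     0, 10,  0,  0, -4, -4,  0,  0,
     0,  0,  8,  0,  0,  0, -4,  0,
    -4,  0,  0,  8,  0,  0,  0,  0,
     0, -4,  0,  0, 11,  3,  0, -6,
     0, -4,  0,  0,  3, 11,  0, -6,
     0,  0, -4,  0,  0,  0,  8,  0,
     0,  0,  0,  0, -6, -6,  0, 12), 8, 8, byrow = TRUE)

  aqqInv3 <- matrix(c(
    3,   0,   0, 0,  0,
    0, 4.7, 0.7, 0, -3,
    0, 0.7, 4.7, 0, -3,
    0,   0,   0, 3,  0,
    0,  -3,  -3, 0,  6), 5, 5, byrow = TRUE)

  appInvM2 <- matrix(c(
     1.8670,  0.5150, -1, -0.0644,  0.2017, -0.7339,
     0.5150,  2.0386, -1, -0.8798,  0.0901, -0.0300,
    -1,      -1,       2,  0,       0,       0,
    -0.0644, -0.8798,  0,  1.4850, -0.3863,  0.1288,
     0.2017,  0.0901,  0, -0.3863,  1.2103, -0.4034,
    -0.7339, -0.0300,  0,  0.1288, -0.4034,  1.4678), 6, 6, byrow = TRUE)

  W <- matrix(0, 6, 8, dimnames = list(p2, p1))
  W["4", "4"] <- 1; W["5", "5"] <- 1; W["10", "10"] <- 1
  W["9", c("4", "5")] <- 0.5
  W["11", c("6", "7")] <- 0.5
  W["12", c("4", "7")] <- 0.5
  Wq <- W[, q3]

  expected <- list(
    gInv = lab(matrix(c(1.45, -0.7, -0.7, 1.2), 2, 2), c("5", "10")),
    a22Inv = lab(matrix(c(1.5319, -0.8511, -0.8511, 1.3617), 2, 2),
                 c("5", "10")),
    aInvTimes6 = lab(aInv6, as.character(1:12)),
    appInvTimes6 = lab(appInv6, p1),
    aqqInvTimes3 = lab(aqqInv3, q3),
    appInvMethod2 = lab(appInvM2, p2),
    Dnn = setNames(c(0.5, 0.5, 0.5), c("9", "11", "12")),
    RtildeNn = setNames(c(0.4, 0.4, 0.4), c("9", "11", "12")),
    B = setNames(c(3, 2.2, 2.2, 2.2) / 11, c("8", "9", "11", "12")),
    W = W,
    Wq = Wq,
    m1p = p1, m1n = as.character(c(8, 9, 11, 12)),
    m2p = p2, m2n = as.character(c(1, 2, 3, 6, 7, 8)),
    m3q = q3, m3r = as.character(1:3), m3n = as.character(c(8, 9, 11, 12)),
    bHat = c(5.1938, 0.3287),
    aHat = setNames(c(-0.0476, -0.0414, 0.1040, -0.0953, -0.4302, 0.3268,
                      0.2080, -0.0476, -0.4507, 0.0255, 0.6534, -0.1217),
                    as.character(1:12)),
    aHatP1 = setNames(c(-0.0476, -0.0414, 0.1040, -0.0953, -0.4302, 0.3268,
                        0.2080, 0.0255), p1),
    adjustedRecords1 = setNames(c(-1.2025, 2.1975, -0.8338),
                                c("9", "11", "12")),
    aHatN1 = setNames(c(-0.0476, -0.4507, 0.6534, -0.1217),
                      c("8", "9", "11", "12")),
    aHatP2 = setNames(c(-0.0953, -0.4302, -0.4507, 0.0255, 0.6534, -0.1217),
                      p2),
    aHatN2 = setNames(c(-0.0476, -0.0414, 0.1040, 0.3268, 0.2080, -0.0476),
                      c("1", "2", "3", "6", "7", "8")),
    ## entry for animal 6 follows the full-model solution
    aHatQ3 = setNames(c(-0.0953, -0.4302, 0.3268, 0.2080, 0.0255), q3),
    aHatR3 = setNames(c(-0.0476, -0.0414, 0.1040), c("1", "2", "3")))

  list(ped = ped, records = records, genotyped = c("5", "10"), G = G,
       vc = vc, fixed = ~sex, expected = expected)
}
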