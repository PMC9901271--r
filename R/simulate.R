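## Gene-dropping simulator: random pedigrees, marker genotypes transmitted
## as independent loci, breeding values and phenotypes with the statistical
## structure the evaluation models assume.

#' Simulate a random multi-generation pedigree
#'
#' Discrete generations with random mating: each generation draws sires and
#' dams from the previous one and produces `progenyPerMating` offspring per
#' mating. Parents can be masked to unknown with the given probabilities
#' (masked parents still transmit genes, emulating incomplete recording).
#'
#' @param nFounders founder animals (half of each sex).
#' @param nGenerations number of offspring generations.
#' @param nMatingsPerGen matings per generation.
#' @param progenyPerMating offspring per mating.
#' @param pMissingSire,pMissingDam probability a recorded parent is masked.
#' @return list with `ped` (a [Pedigree]), `sex` (named vector `"m"`/`"f"`),
#'   and `trueParents` (data.frame of unmasked parentage used for gene
#'   dropping).
#' @export
simulatePedigree <- function(nFounders = 20, nGenerations = 3,
                             nMatingsPerGen = 10, progenyPerMating = 2,
                             pMissingSire = 0, pMissingDam = 0) {
  id <- as.character(seq_len(nFounders))
  sex <- rep(c("m", "f"), length.out = nFounders)
  sire <- dam <- rep(NA_character_, nFounders)
  sireTrue <- damTrue <- rep(NA_character_, nFounders)
  prevGen <- id
  nextId <- nFounders + 1L
  for (g in seq_len(nGenerations)) {
    males <- prevGen[sex[match(prevGen, id)] == "m"]
    females <- prevGen[sex[match(prevGen, id)] == "f"]
    if (!length(males) || !length(females)) break
    newGen <- character(0)
    for (k in seq_len(nMatingsPerGen)) {
      s <- sample(males, 1)
      d <- sample(females, 1)
      for (o in seq_len(progenyPerMating)) {
        lab <- as.character(nextId); nextId <- nextId + 1L
        id <- c(id, lab)
        sex <- c(sex, sample(c("m", "f"), 1))
        sireTrue <- c(sireTrue, s)
        damTrue <- c(damTrue, d)
        sire <- c(sire, if (runif(1) < pMissingSire) NA_character_ else s)
        dam <- c(dam, if (runif(1) < pMissingDam) NA_character_ else d)
        newGen <- c(newGen, lab)
      }
    }
    prevGen <- newGen
  }
  list(ped = Pedigree(id, sire, dam),
       sex = setNames(sex, id),
       trueParents = data.frame(id = id, sire = sireTrue, dam = damTrue,
                                stringsAsFactors = FALSE))
}

#' Gene-drop marker genotypes down a pedigree
#'
#' Founder alleles are Bernoulli draws at each locus frequency; every
#' offspring receives one allele picked at random from each parent,
#' independently per locus (no linkage). An unknown parent's contribution is
#' drawn from the founder allele frequencies.
#'
#' @param ped a [Pedigree] (or the `trueParents` frame of
#'   [simulatePedigree()] via `sire`/`dam` arguments).
#' @param freq per-locus allele frequencies.
#' @param sire,dam optional parent label vectors overriding the pedigree
#'   (used to gene-drop through masked parents).
#' @return allele-count matrix (animals x loci).
#' @export
geneDrop <- function(ped, freq, sire = NULL, dam = NULL) {
  ids <- ped@id
  n <- length(ids)
  m <- length(freq)
  if (is.null(sire)) sire <- sireIds(ped)
  if (is.null(dam)) dam <- damIds(ped)
  al1 <- matrix(0L, n, m, dimnames = list(ids, NULL))
  al2 <- matrix(0L, n, m, dimnames = list(ids, NULL))
  drawFounder <- function() rbinom(m, 1L, freq)
  transmit <- function(p) {
    if (is.na(p)) return(drawFounder())
    pick <- runif(m) < 0.5
    ifelse(pick, al1[p, ], al2[p, ])
  }
  for (i in seq_len(n)) {
    al1[i, ] <- transmit(sire[i])
    al2[i, ] <- transmit(dam[i])
  }
  geno <- al1 + al2
  colnames(geno) <- paste0("m", seq_len(m))
  geno
}

#' Simulate breeding values by the pedigree recursion
#'
#' Draws `u_i = (u_s + u_d)/2 + m_i`, `m_i ~ N(0, D_i sigmaA2)` down the
#' pedigree (the `A = TDT'` recursion), so that `u ~ N(0, A sigmaA2)`
#' exactly. Vectorised over replicates.
#'
#' @param ped a [Pedigree].
#' @param sigmaA2 additive genetic variance.
#' @param nrep number of independent replicate vectors.
#' @return animals x `nrep` matrix of breeding values.
#' @export
simulateBreedingValues <- function(ped, sigmaA2 = 1, nrep = 1) {
  n <- length(ped@id)
  D <- inbreeding(ped)$D
  u <- matrix(0, n, nrep, dimnames = list(ped@id, NULL))
  for (i in seq_len(n)) {
    pa <- rep(0, nrep)
    for (p in parentIdx(ped, i)) pa <- pa + u[p, ] / 2
    u[i, ] <- pa + rnorm(nrep, 0, sqrt(D[i] * sigmaA2))
  }
  u
}

#' Simulate a complete single-step dataset
#'
#' Builds a random pedigree, gene-drops marker genotypes, assigns true
#' breeding values and phenotypes, and samples the genotyped and phenotyped
#' subsets. With `trueGenetic = "marker"` (default) the true breeding values
#' are `u = M_c alpha` with `alpha ~ N(0, sigmaA2 / k)` over the gene-dropped
#' loci, so that marginally `u` has (approximately) the pedigree covariance
#' while the genomic data are genuinely informative about `u`; with
#' `"polygenic"` the `A = TDT'` recursion is used directly and the markers
#' are independent of `u`. Phenotypes are `y = Xb + u + e` with a two-level
#' sex effect.
#'
#' @param nFounders,nGenerations,nMatingsPerGen,progenyPerMating,pMissingSire,pMissingDam
#'   passed to [simulatePedigree()].
#' @param nMarkers number of independent loci.
#' @param freqRange founder allele frequencies drawn uniformly in this range.
#' @param genotypedFraction,phenotypedFraction sampled fractions of animals.
#' @param b fixed effects: intercept and the effect of the second sex level.
#' @param sigmaA2,sigmaE2 variance components.
#' @param trueGenetic `"marker"` or `"polygenic"` (see above).
#' @param seed mandatory RNG seed.
#' @return list with `ped`, `records`, `genotyped`, `geno` (allele counts of
#'   the genotyped animals), `genoAll`, `freq` (the founder allele
#'   frequencies; centering genotypes at these keeps G invertible, whereas
#'   observed-frequency centering always leaves the ones-vector in G's null
#'   space), `trueBV`, `sex`, `vc`, `fixed`.
#' @export
simulateDataset <- function(nFounders = 20, nGenerations = 3,
                            nMatingsPerGen = 12, progenyPerMating = 3,
                            pMissingSire = 0.05, pMissingDam = 0.05,
                            nMarkers = 100, freqRange = c(0.2, 0.8),
                            genotypedFraction = 0.3, phenotypedFraction = 0.6,
                            b = c(10, 1), sigmaA2 = 1, sigmaE2 = 2,
                            trueGenetic = c("marker", "polygenic"),
                            seed) {
  if (missing(seed)) stop("a seed is required")
  trueGenetic <- match.arg(trueGenetic)
  set.seed(seed)
  sim <- simulatePedigree(nFounders, nGenerations, nMatingsPerGen,
                          progenyPerMating, pMissingSire, pMissingDam)
  ped <- sim$ped
  ids <- ped@id
  n <- length(ids)
  freq <- runif(nMarkers, freqRange[1], freqRange[2])
  genoAll <- geneDrop(ped, freq,
                      sire = sim$trueParents$sire[match(ids, sim$trueParents$id)],
                      dam = sim$trueParents$dam[match(ids, sim$trueParents$id)])
  if (trueGenetic == "marker") {
    p <- colMeans(genoAll) / 2
    keep <- p > 0 & p < 1
    Mc <- sweep(genoAll[, keep, drop = FALSE], 2, 2 * p[keep])
    k <- 2 * sum(p[keep] * (1 - p[keep]))
    alpha <- rnorm(sum(keep), 0, sqrt(sigmaA2 / k))
    u <- as.numeric(Mc %*% alpha)
  } else {
    u <- as.numeric(simulateBreedingValues(ped, sigmaA2, 1))
  }
  names(u) <- ids

  nGeno <- max(2L, round(genotypedFraction * n))
  nPhen <- max(2L, round(phenotypedFraction * n))
  genotyped <- sort(sample(n, nGeno))
  phenotyped <- sort(sample(n, nPhen))
  sex <- sim$sex[ids]
  X2 <- as.numeric(sex[phenotyped] == "f")
  y <- b[1] + b[2] * X2 + u[phenotyped] + rnorm(nPhen, 0, sqrt(sigmaE2))
  records <- data.frame(animal = ids[phenotyped], value = y,
                        sex = sex[phenotyped], stringsAsFactors = FALSE)
  if (length(unique(records$sex)) < 2) records$sex <- NULL

  list(ped = ped, records = records, genotyped = ids[genotyped],
       geno = genoAll[genotyped, , drop = FALSE], genoAll = genoAll,
       freq = freq, trueBV = u, sex = sex,
       vc = varianceComponents(sigmaA2 = sigmaA2, sigmaE2 = sigmaE2),
       fixed = if (is.null(records$sex)) ~1 else ~sex)
}
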