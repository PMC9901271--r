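## Reduced animal models for single-step evaluation: the three reduced
## systems and their exact back-solving steps.

keptSet <- function(sets, method) {
  switch(as.character(method),
         "1" = sets@m1p, "2" = sets@m2p, "3" = sets@m3q,
         stop("method must be 1, 2 or 3"))
}

absorbedSets <- function(sets, method) {
  switch(as.character(method),
         "1" = list(n = sets@m1n, r = character(0)),
         "2" = list(n = sets@m2n, r = character(0)),
         "3" = list(n = sets@m3n, r = sets@m3r))
}

#' Build the reduced design for a RAM variant
#'
#' Records of kept animals get identity rows in the record-by-kept-animal
#' matrix `W` and their plain residual precision. A record of an absorbed
#' phenotyped nonparent (methods 1 and 3) gets `0.5` at each known parent
#' column and the Mendelian-sampling-inflated residual precision
#' `1 / (R_ii + D_i * sigmaA2)`, which absorbs the animal's own Mendelian
#' sampling deviation into the residual. Method 2 absorbs only nonphenotyped
#' animals, so every record keeps an identity row and plain precision.
#'
#' @param records phenotype data.frame.
#' @param ped a [Pedigree].
#' @param sets an [AnimalSets] from [classifyAnimals()].
#' @param mv Mendelian-sampling variances from [inbreeding()].
#' @param vc variance components.
#' @param method 1, 2 or 3.
#' @return list with `W` (sparse record x kept matrix), `RtildeInv`
#'   (per-record precision diagonal), `kept`, `absorbedPhenotyped`, `method`.
#' @export
buildReducedDesign <- function(records, ped, sets, mv, vc, method) {
  records <- checkRecords(records, ped)
  kept <- keptSet(sets, method)
  rv <- residualVariances(records, vc)
  D <- setNames(mv$D, mv$id)

  n <- nrow(records)
  ti <- list(); tj <- list(); tx <- list()
  RtInv <- numeric(n)
  absorbed <- character(0)
  for (r in seq_len(n)) {
    an <- records$animal[r]
    if (an %in% kept) {
      ti[[r]] <- r; tj[[r]] <- match(an, kept); tx[[r]] <- 1
      RtInv[r] <- 1 / rv[r]
    } else {
      if (method == 2)
        stop("method 2 cannot absorb a phenotyped animal (", an,
             "); classification is inconsistent")
      par <- ped@id[parentIdx(ped, match(an, ped@id))]
      if (!all(par %in% kept))
        stop("known parent of absorbed phenotyped animal ", an,
             " is not kept; classification is inconsistent")
      absorbed <- c(absorbed, an)
      ti[[r]] <- rep(r, length(par))
      tj[[r]] <- match(par, kept)
      tx[[r]] <- rep(0.5, length(par))
      RtInv[r] <- 1 / (rv[r] + D[[an]] * vc$sigmaA2)
    }
  }
  if (anyDuplicated(absorbed))
    stop("absorbed animals with repeated records are not supported: ",
         paste(unique(absorbed[duplicated(absorbed)]), collapse = ", "))
  W <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, length(kept)),
                            dimnames = list(NULL, kept))
  list(W = W, RtildeInv = RtInv, kept = kept,
       absorbedPhenotyped = absorbed, method = method)
}

#' Assemble a reduced equation system
#'
#' Same block structure as [assembleFull()], with the reduced design `W`,
#' the (possibly inflated) residual precision diagonal, and the reduced
#' single-step inverse (`Hpp^-1` or `Hqq^-1`) as the genetic precision.
#'
#' @param rd reduced design from [buildReducedDesign()].
#' @param X fixed-effect design over all records.
#' @param y phenotype vector.
#' @param hReducedInv reduced single-step inverse over exactly `rd$kept`.
#' @param vc variance components.
#' @return an [EquationSystem] of order `ncol(X) + length(rd$kept)`.
#' @export
assembleReduced <- function(rd, X, y, hReducedInv, vc) {
  assembleFull(X, rd$W, rd$RtildeInv, y, hReducedInv, vc)
}

## Mendelian-sampling regression coefficient for one absorbed record
mendelianB <- function(D, sigmaA2, sigmaE2) D * sigmaA2 / (sigmaE2 + D * sigmaA2)

## parent-average of a named solution vector; unknown parents contribute 0
parentAverage <- function(sol, ped, i) {
  p <- c(ped@sire[i], ped@dam[i])
  sum(sol[ped@id[p[!is.na(p)]]]) / 2
}

#' Back-solve absorbed nonparents on the Mendelian-sampling regression
#'
#' For each absorbed animal `i` with parent-average solution `PA` (an
#' unknown parent contributes 0): if `i` is phenotyped,
#' `a_i = B_i (y_i - x_i' b - PA) + PA` with
#' `B_i = D_i sigmaA2 / (R_ii + D_i sigmaA2)`; a nonphenotyped absorbed
#' animal gets the parent average itself. All parents must already carry
#' solutions.
#'
#' @param sol a [SolutionSet] holding solutions for all parents of
#'   `absorbed`.
#' @param records phenotype data.frame.
#' @param X fixed-effect design aligned with `records`.
#' @param ped a [Pedigree].
#' @param mv Mendelian-sampling variances from [inbreeding()].
#' @param vc variance components.
#' @param absorbed labels to back-solve.
#' @return `sol` extended with the back-solved animals (provenance
#'   `"backsolved"`).
#' @export
backsolveMendelian <- function(sol, records, X, ped, mv, vc, absorbed) {
  if (!length(absorbed)) return(sol)
  records <- checkRecords(records, ped)
  rv <- residualVariances(records, vc)
  D <- setNames(mv$D, mv$id)
  xb <- as.numeric(X %*% sol@fixed)
  a <- sol@animal
  prov <- sol@provenance
  for (an in intersect(ped@id, absorbed)) {  # pedigree order: parents first
    i <- match(an, ped@id)
    par <- ped@id[parentIdx(ped, i)]
    if (!all(par %in% names(a)))
      stop("unsolved parent of ", an, " during back-solving (ordering bug)")
    pa <- parentAverage(a, ped, i)
    r <- which(records$animal == an)
    if (length(r) > 1L)
      stop("absorbed animal ", an, " has repeated records")
    a[an] <- if (length(r) == 1L) {
      B <- mendelianB(D[[an]], vc$sigmaA2, rv[r])
      B * (records$value[r] - xb[r] - pa) + pa
    } else pa
    prov[an] <- "backsolved"
  }
  sol@animal <- a
  sol@provenance <- prov
  validObject(sol)
  sol
}

#' Back-solve absorbed animals from pedigree-inverse blocks
#'
#' Solves the sparse system `A^nn a_n = -A^np a_p` for the absorbed animals,
#' where the blocks come from a pedigree-only inverse over the relevant
#' animal set (full `A^-1` for method 2; `App^-1` for method 3's `r`
#' animals). These blocks never contain genomic terms, which is what keeps
#' back-solving cheap.
#'
#' @param sol a [SolutionSet] with solutions for all of
#'   `setdiff(rownames(aInv), absorbed)`.
#' @param aInv labelled pedigree-based inverse.
#' @param absorbed labels to back-solve (subset of `rownames(aInv)`).
#' @return `sol` extended with the back-solved animals.
#' @export
backsolveAbsorbed <- function(sol, aInv, absorbed) {
  if (!length(absorbed)) return(sol)
  labs <- rownames(aInv)
  if (!all(absorbed %in% labs))
    stop("absorbed labels missing from the inverse: ",
         paste(setdiff(absorbed, labs), collapse = ", "))
  keep <- setdiff(labs, absorbed)
  if (!all(keep %in% names(sol@animal)))
    stop("unsolved animals needed for back-solving: ",
         paste(setdiff(keep, names(sol@animal)), collapse = ", "))
  Ann <- aInv[absorbed, absorbed, drop = FALSE]
  Anp <- aInv[absorbed, keep, drop = FALSE]
  an <- -as.numeric(Matrix::solve(Ann, Anp %*% sol@animal[keep]))
  sol@animal[absorbed] <- an
  sol@provenance[absorbed] <- "backsolved"
  validObject(sol)
  sol
}

#' Single-step evaluation via a reduced animal model
#'
#' End-to-end pipeline for the three RAM variants: classify animals, build
#' the reduced design and the reduced single-step inverse, solve the reduced
#' system, and recover every absorbed animal exactly by back-solving
#' (Mendelian-sampling regression for absorbed nonparents; pedigree-inverse
#' blocks for absorbed parents and nonphenotyped animals). The merged
#' solutions equal the full ssGBLUP solutions.
#'
#' @inheritParams solveFull
#' @param method 1 (keep genotyped + nongenotyped parents), 2 (keep
#'   genotyped + nongenotyped phenotyped) or 3 (keep genotyped +
#'   nongenotyped parents of phenotyped nongenotyped nonparents).
#' @param details also return the intermediate objects (sets, design,
#'   system, reduced inverses) as attributes of the result.
#' @return a [SolutionSet] covering every pedigree animal, tagged
#'   `"ram1"`/`"ram2"`/`"ram3"`, with per-animal provenance.
#' @export
runRAM <- function(records, ped, genotyped, G = NULL, markers = NULL,
                   vc, fixed = ~1, method = 1, solver = "direct",
                   tol = 1e-12, details = FALSE) {
  records <- checkRecords(records, ped)
  genotyped <- checkSubset(genotyped, ped, "genotyped")
  sets <- classifyAnimals(ped, genotyped, unique(records$animal))
  mv <- inbreeding(ped)
  aInv <- aInverse(ped)
  if (is.null(G)) {
    if (is.null(markers)) stop("supply G or markers")
    G <- buildG(markers)
  }
  a22Inv <- subsetInverse(aInv, genotyped)
  gInv <- invertG(G)

  kept <- keptSet(sets, method)
  AkkInv <- subsetInverse(aInv, kept)
  HkkInv <- hInverse(AkkInv, gInv, a22Inv)

  d <- buildDesign(records, ped, fixed, vc)
  rd <- buildReducedDesign(records, ped, sets, mv, vc, method)
  sys <- assembleReduced(rd, d$X, d$y, HkkInv, vc)
  sol <- solveMME(sys, method = solver, tol = tol,
                  methodTag = paste0("ram", method))

  abs <- absorbedSets(sets, method)
  if (method == 2) {
    sol <- backsolveAbsorbed(sol, aInv, abs$n)
  } else if (method == 3) {
    AppInv <- subsetInverse(aInv, sets@m1p)
    sol <- backsolveAbsorbed(sol, AppInv, abs$r)
    sol <- backsolveMendelian(sol, records, d$X, ped, mv, vc, abs$n)
  } else {
    sol <- backsolveMendelian(sol, records, d$X, ped, mv, vc, abs$n)
  }
  sol@animal <- sol@animal[ped@id]
  sol@provenance <- sol@provenance[ped@id]
  if (details) {
    attr(sol, "sets") <- sets
    attr(sol, "design") <- rd
    attr(sol, "system") <- sys
    attr(sol, "HkkInv") <- HkkInv
    attr(sol, "AkkInv") <- AkkInv
  }
  sol
}
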