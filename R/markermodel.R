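## Single-step marker model: genotype imputation for nongenotyped animals,
## the full system (fixed effects, marker effects, imputation deviations,
## residual polygenic effects), its three reduced variants, and the joint
## back-solving of absorbed animals.

#' Impute marker covariates for nongenotyped animals
#'
#' Solves the sparse multi-right-hand-side system
#' `A^11 M1 = -A^12 M2`, where `A^11`/`A^12` are the
#' nongenotyped/genotyped blocks of a pedigree-based inverse. This is the
#' conditional mean of the nongenotyped animals' gene contents given the
#' observed (centered) genotypes, and is invariant to which other
#' nongenotyped animals are in the system.
#'
#' @param aInv labelled pedigree-based inverse (full `A^-1` or a subset
#'   inverse).
#' @param M2 centered genotype matrix, rownames = genotyped labels (must be
#'   a subset of `rownames(aInv)`).
#' @param nongenotyped labels to impute (default: all non-genotyped labels
#'   of `aInv`).
#' @return matrix of imputed covariates, rownames = `nongenotyped`.
#' @export
imputeM1 <- function(aInv, M2, nongenotyped = NULL) {
  labs <- rownames(aInv)
  gen <- rownames(M2)
  if (!all(gen %in% labs))
    stop("genotyped labels missing from the inverse: ",
         paste(setdiff(gen, labs), collapse = ", "))
  if (is.null(nongenotyped)) nongenotyped <- setdiff(labs, gen)
  if (!length(nongenotyped) || ncol(M2) == 0L)
    return(matrix(0, length(nongenotyped), ncol(M2),
                  dimnames = list(nongenotyped, colnames(M2))))
  A11 <- aInv[nongenotyped, nongenotyped, drop = FALSE]
  A12 <- aInv[nongenotyped, gen, drop = FALSE]
  M1 <- -as.matrix(Matrix::solve(A11, A12 %*% M2))
  dimnames(M1) <- list(nongenotyped, colnames(M2))
  M1
}

## Everything the ssMM assembly and back-solving need, computed once.
ssmmContext <- function(records, ped, markers, vc, fixed = ~1,
                        genotyped = NULL, method = "full") {
  method <- as.character(method)
  if (!method %in% c("full", "1", "2", "3"))
    stop("method must be 'full', 1, 2 or 3")
  if (is.null(vc$sigmaAlpha2) || is.null(vc$sigmaDelta2))
    stop("the marker model needs sigmaAlpha2 and sigmaDelta2")
  records <- checkRecords(records, ped)
  if (!is.null(markers) && !is(markers, "MarkerData"))
    markers <- markerData(markers)
  if (is.null(genotyped))
    genotyped <- if (is.null(markers)) character(0) else rownames(markers@raw)
  genotyped <- checkSubset(genotyped, ped, "genotyped")
  if (!is.null(markers) && !setequal(rownames(markers@raw), genotyped))
    stop("marker rows and genotyped set must match")

  sets <- classifyAnimals(ped, genotyped, unique(records$animal))
  mv <- inbreeding(ped)
  aInvFull <- aInverse(ped)

  kept <- if (method == "full") ped@id else keptSet(sets, method)
  aInvK <- if (method == "full") aInvFull else subsetInverse(aInvFull, kept)
  nMark <- if (is.null(markers)) 0L else ncol(markers@centered)
  ## no markers: no deviation effects either; the model collapses to BLUP
  K1 <- if (nMark) setdiff(kept, genotyped) else character(0)
  M2 <- if (nMark) markers@centered[genotyped, , drop = FALSE] else
    matrix(0, length(genotyped), 0L, dimnames = list(genotyped, NULL))
  M1 <- imputeM1(aInvK, M2, nongenotyped = K1)
  MK <- if (nMark) rbind(M1, M2)[kept, , drop = FALSE] else
    matrix(0, length(kept), 0L, dimnames = list(kept, NULL))

  d <- buildDesign(records, ped, fixed, vc)
  if (method %in% c("1", "3")) {
    rd <- buildReducedDesign(records, ped, sets, mv, vc, method)
  } else if (method == "2") {
    rd <- buildReducedDesign(records, ped, sets, mv, vc, 2)
  } else {
    rd <- list(W = d$Z, RtildeInv = d$Rinv, kept = ped@id,
               absorbedPhenotyped = character(0), method = "full")
  }
  stopifnot(identical(colnames(rd$W), kept))
  list(records = records, ped = ped, markers = markers, vc = vc,
       genotyped = genotyped, sets = sets, mv = mv, aInvFull = aInvFull,
       aInvK = aInvK, method = method, kept = kept, K1 = K1,
       M1 = M1, M2 = M2, MK = MK, X = d$X, y = d$y, rd = rd)
}

#' Assemble a single-step marker-model equation system
#'
#' Builds the symmetric system over fixed effects, marker effects (`alpha`),
#' imputation deviations of the nongenotyped animals in the system
#' (`epsilon`, prior precision `A^11 / sigmaAlpha2`) and residual polygenic
#' effects of all animals in the system (`delta`, prior precision
#' `A^-1 / sigmaDelta2`). For the reduced variants (`method` 1, 2 or 3) the
#' pedigree inverse is replaced by the corresponding subset inverse, the
#' absorbed phenotyped records enter through parent-average rows with
#' Mendelian-sampling-inflated residuals (with
#' `sigmaA2 = sigmaAlpha2 + sigmaDelta2`), and the `epsilon`/`delta`
#' equations span only the kept animals. With zero markers the model
#' collapses to pedigree BLUP on `delta` (no marker or deviation equations).
#'
#' The genotype matrix is expected centered and scaled so that `M M'` is on
#' the relationship scale ([markerData()] default); this makes one variance
#' `sigmaAlpha2` coherent for both the marker-effect and deviation priors.
#'
#' @inheritParams runSSMM
#' @return list with `sys` (an [EquationSystem]) and `ctx` (the assembly
#'   context consumed by [backsolveSSMM()]).
#' @export
assembleSSMM <- function(records, ped, markers, vc, fixed = ~1,
                         genotyped = NULL, method = "full") {
  ctx <- ssmmContext(records, ped, markers, vc, fixed, genotyped, method)
  list(sys = ssmmSystem(ctx), ctx = ctx)
}

ssmmSystem <- function(ctx) {
  vc <- ctx$vc
  X <- ctx$X
  W <- ctx$rd$W
  V <- ctx$rd$RtildeInv
  y <- ctx$y
  K1 <- ctx$K1
  m <- ncol(ctx$MK)
  Weps <- W[, K1, drop = FALSE]
  ZM <- as.matrix(W %*% ctx$MK)
  aInvK <- as.matrix(ctx$aInvK)[ctx$kept, ctx$kept, drop = FALSE]

  Rd <- Matrix::Diagonal(x = V)
  XV <- t(X * V)
  ZMV <- t(ZM * V)
  WepsV <- Matrix::t(Rd %*% Weps)
  WV <- Matrix::t(Rd %*% W)

  sa <- 1 / vc$sigmaAlpha2
  sd <- 1 / vc$sigmaDelta2
  A11 <- aInvK[K1, K1, drop = FALSE]

  mLab <- colnames(ctx$MK)
  if (is.null(mLab) && m) mLab <- paste0("m", seq_len(m))

  blocksRow <- function(...) do.call(cbind, lapply(list(...), as.matrix))
  lhs <- rbind(
    blocksRow(XV %*% X, XV %*% ZM, XV %*% Weps, XV %*% W),
    blocksRow(ZMV %*% X, ZMV %*% ZM + diag(sa, m), ZMV %*% Weps, ZMV %*% W),
    blocksRow(WepsV %*% X, WepsV %*% ZM,
              WepsV %*% Weps + A11 * sa, WepsV %*% W),
    blocksRow(WV %*% X, WV %*% ZM, WV %*% Weps, WV %*% W + aInvK * sd))
  rhs <- c(as.numeric(XV %*% y), as.numeric(ZMV %*% y),
           as.numeric(WepsV %*% y), as.numeric(WV %*% y))
  effects <- data.frame(
    type = c(rep("fixed", ncol(X)), rep("marker", m),
             rep("epsilon", length(K1)), rep("delta", length(ctx$kept))),
    label = c(colnames(X), mLab, K1, ctx$kept),
    stringsAsFactors = FALSE)
  dimnames(lhs) <- NULL
  new("EquationSystem", lhs = symmetrize(lhs), rhs = rhs, effects = effects)
}

## epsilon of a parent: 0 when genotyped, unknown, or absent (zero markers)
epsLookup <- function(eps, genotyped) function(lab) {
  if (is.na(lab) || lab %in% genotyped || !lab %in% names(eps)) 0
  else eps[[lab]]
}

#' Total genetic merit from a marker-model solution
#'
#' For genotyped animals merit is `M2 alpha + delta`; for nongenotyped
#' animals `M1 alpha + epsilon + delta`; back-solved animals carry their
#' back-solved merit directly. [runSSMM()] stores this in the `animal` slot,
#' which this accessor returns.
#'
#' @param sol a [SolutionSet] from [runSSMM()].
#' @return named numeric vector of total merit per animal.
#' @export
totalMerit <- function(sol) sol@animal

meritOfKept <- function(ctx, alpha, eps, delta) {
  merit <- as.numeric(ctx$MK %*% alpha) + delta[ctx$kept]
  names(merit) <- ctx$kept
  merit[ctx$K1] <- merit[ctx$K1] + eps[ctx$K1]
  merit
}

#' Back-solve absorbed animals of a reduced marker model
#'
#' Recovers total merit, imputation deviations and residual polygenic
#' effects for the absorbed animals. Absorbed nonparents (methods 1 and 3)
#' use the Mendelian-sampling regression jointly for the three components:
#' with `dev = y - x'b - PA(merit)` and `B = D sigmaA2 / (R + D sigmaA2)`,
#' merit gains `B dev` over its parent average while `epsilon` and `delta`
#' gain the shares `sigmaAlpha2/sigmaA2 * B dev` and
#' `sigmaDelta2/sigmaA2 * B dev` over theirs (a genotyped or unknown parent
#' contributes 0 to the `epsilon` parent average). Nonphenotyped absorbed
#' animals (and method 2's absorbed set, which is nonphenotyped by
#' construction) are conditional means through pedigree-inverse blocks:
#' `A^nn x_n = -A^np x_p` applied to merit, `epsilon` and `delta` alike.
#'
#' @param sol a [SolutionSet] holding the kept-animal solutions.
#' @param ctx assembly context from [assembleSSMM()].
#' @return the completed [SolutionSet].
#' @export
backsolveSSMM <- function(sol, ctx) {
  method <- ctx$method
  if (method == "full") return(sol)
  sets <- ctx$sets
  if (method == "2") {
    sol <- ssmmAbsorbBlocks(sol, ctx$aInvFull, sets@m2n, ctx)
  } else if (method == "3") {
    AppInv <- subsetInverse(ctx$aInvFull, sets@m1p)
    sol <- ssmmAbsorbBlocks(sol, AppInv, sets@m3r, ctx)
    sol <- ssmmMendelian(sol, sets@m3n, ctx)
  } else {
    sol <- ssmmMendelian(sol, sets@m1n, ctx)
  }
  sol
}

ssmmAbsorbBlocks <- function(sol, aInv, absorbed, ctx) {
  if (!length(absorbed)) return(sol)
  labs <- rownames(aInv)
  keep <- setdiff(labs, absorbed)
  Ann <- aInv[absorbed, absorbed, drop = FALSE]
  Anp <- aInv[absorbed, keep, drop = FALSE]
  epsKeep <- setNames(numeric(length(keep)), keep)
  ngKeep <- intersect(keep, names(sol@epsilon))
  epsKeep[ngKeep] <- sol@epsilon[ngKeep]
  rhs <- cbind(merit = sol@animal[keep], eps = epsKeep,
               delta = sol@delta[keep])
  xn <- -as.matrix(Matrix::solve(Ann, Anp %*% rhs))
  rownames(xn) <- absorbed
  sol@animal[absorbed] <- xn[, "merit"]
  sol@epsilon[absorbed] <- xn[, "eps"]
  sol@delta[absorbed] <- xn[, "delta"]
  sol@provenance[absorbed] <- "backsolved"
  sol
}

ssmmMendelian <- function(sol, absorbed, ctx) {
  if (!length(absorbed)) return(sol)
  ped <- ctx$ped
  vc <- ctx$vc
  records <- ctx$records
  rv <- residualVariances(records, vc)
  D <- setNames(ctx$mv$D, ctx$mv$id)
  xb <- as.numeric(ctx$X %*% sol@fixed)
  getEps <- epsLookup(sol@epsilon, ctx$genotyped)
  shareA <- vc$sigmaAlpha2 / vc$sigmaA2
  shareD <- vc$sigmaDelta2 / vc$sigmaA2
  for (an in intersect(ped@id, absorbed)) {
    i <- match(an, ped@id)
    par <- ped@id[parentIdx(ped, i)]
    paMerit <- sum(sol@animal[par]) / 2
    paEps <- sum(vapply(par, getEps, 0)) / 2
    paDelta <- sum(sol@delta[par]) / 2
    r <- which(records$animal == an)
    bdev <- if (length(r) == 1L) {
      B <- mendelianB(D[[an]], vc$sigmaA2, rv[r])
      B * (records$value[r] - xb[r] - paMerit)
    } else 0
    sol@animal[an] <- paMerit + bdev
    sol@epsilon[an] <- paEps + shareA * bdev
    sol@delta[an] <- paDelta + shareD * bdev
    sol@provenance[an] <- "backsolved"
  }
  sol
}

#' Single-step marker-model evaluation
#'
#' Full or reduced single-step marker model: assembles the system of
#' [assembleSSMM()], solves it, computes total merit for the animals in the
#' system and back-solves the absorbed ones via [backsolveSSMM()]. Total
#' merit equals the ssGBLUP breeding values of the equivalent model with
#' `G = (M2 M2' sigmaAlpha2 + A22 sigmaDelta2) / sigmaA2`.
#'
#' @param records phenotype data.frame (see [buildDesign()]).
#' @param ped a [Pedigree].
#' @param markers a [MarkerData] (relationship-scaled by default), or
#'   `NULL` for the zero-marker collapse to pedigree BLUP.
#' @param vc variance components with `sigmaAlpha2` and `sigmaDelta2`.
#' @param fixed fixed-effect formula.
#' @param genotyped genotyped labels (default: marker rownames).
#' @param method `"full"`, 1, 2 or 3.
#' @param solver,tol passed to [solveMME()].
#' @return a [SolutionSet] with total merit in `animal`, marker effects in
#'   `alpha`, deviations in `epsilon`, residual polygenic effects in
#'   `delta`, tagged `"ssmm"`/`"ssmm-ram1"`/... .
#' @export
runSSMM <- function(records, ped, markers, vc, fixed = ~1, genotyped = NULL,
                    method = "full", solver = "direct", tol = 1e-12) {
  a <- assembleSSMM(records, ped, markers, vc, fixed, genotyped, method)
  ctx <- a$ctx
  tag <- if (ctx$method == "full") "ssmm" else paste0("ssmm-ram", ctx$method)
  sol <- solveMME(a$sys, method = solver, tol = tol, methodTag = tag)
  sol@animal <- meritOfKept(ctx, sol@alpha, sol@epsilon, sol@delta)
  sol@provenance <- setNames(rep("direct", length(sol@animal)),
                             names(sol@animal))
  sol <- backsolveSSMM(sol, ctx)
  ord <- ped@id
  sol@animal <- sol@animal[ord]
  sol@provenance <- sol@provenance[ord]
  sol@delta <- sol@delta[intersect(ord, names(sol@delta))]
  sol@epsilon <- sol@epsilon[intersect(ord, names(sol@epsilon))]
  validObject(sol)
  sol
}
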