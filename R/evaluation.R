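## Design matrices, full ssGBLUP/BLUP mixed-model equations, and solvers.

#' Variance components
#'
#' Container for the variance components of the single-trait models:
#' additive genetic variance `sigmaA2`, residual variance `sigmaE2`, and for
#' the marker model the marker-part variance `sigmaAlpha2` and residual
#' polygenic variance `sigmaDelta2` (in which case
#' `sigmaA2 = sigmaAlpha2 + sigmaDelta2` unless given).
#'
#' @param sigmaA2 additive genetic variance.
#' @param sigmaE2 residual variance.
#' @param sigmaAlpha2,sigmaDelta2 marker and residual polygenic variances
#'   (marker model only).
#' @return a list of class `"VarianceComponents"`.
#' @export
varianceComponents <- function(sigmaA2 = NULL, sigmaE2,
                               sigmaAlpha2 = NULL, sigmaDelta2 = NULL) {
  if (is.null(sigmaA2)) {
    if (is.null(sigmaAlpha2) || is.null(sigmaDelta2))
      stop("supply sigmaA2, or both sigmaAlpha2 and sigmaDelta2")
    sigmaA2 <- sigmaAlpha2 + sigmaDelta2
  }
  vc <- list(sigmaA2 = sigmaA2, sigmaE2 = sigmaE2,
             sigmaAlpha2 = sigmaAlpha2, sigmaDelta2 = sigmaDelta2)
  for (nm in names(vc))
    if (!is.null(vc[[nm]]) && (!is.numeric(vc[[nm]]) || vc[[nm]] <= 0))
      stop(nm, " must be a positive number")
  class(vc) <- "VarianceComponents"
  vc
}

checkRecords <- function(records, ped) {
  if (!is.data.frame(records) || !all(c("animal", "value") %in% names(records)))
    stop("records must be a data.frame with 'animal' and 'value' columns")
  records$animal <- as.character(records$animal)
  checkSubset(records$animal, ped, "record animal")
  if (anyNA(records$value)) stop("missing phenotype values")
  records
}

## per-record residual variances (optional per-record override column)
residualVariances <- function(records, vc) {
  if (!is.null(records$residualVariance)) {
    rv <- as.numeric(records$residualVariance)
    rv[is.na(rv)] <- vc$sigmaE2
    if (any(rv <= 0)) stop("residual variances must be positive")
    rv
  } else rep(vc$sigmaE2, nrow(records))
}

## character covariates coded as factors with first-seen level as reference
firstSeenFactors <- function(df, fixed) {
  vars <- all.vars(fixed)
  for (v in vars) {
    if (!v %in% names(df)) stop("fixed-effect column not in records: ", v)
    x <- df[[v]]
    if (is.character(x) || is.logical(x)) df[[v]] <- factor(x, levels = unique(x))
    if (is.factor(x)) df[[v]] <- factor(x, levels = unique(as.character(x)))
  }
  df
}

#' Build design matrices for an animal-model evaluation
#'
#' Constructs the fixed-effect design `X` (intercept plus reference-coded
#' dummies, baseline = first-seen level), the 0/1 record-by-animal incidence
#' `Z` over all pedigree animals, the diagonal inverse residual matrix and
#' the phenotype vector.
#'
#' @param records data.frame with columns `animal`, `value`, the covariates
#'   named in `fixed`, and optionally `residualVariance` per record.
#' @param ped a [Pedigree].
#' @param fixed one-sided formula of categorical fixed effects (default
#'   intercept-only `~ 1`).
#' @param vc a [varianceComponents()] list (supplies `sigmaE2`).
#' @return list with `X` (dense), `Z` (sparse), `Rinv` (numeric diagonal),
#'   `y`.
#' @export
buildDesign <- function(records, ped, fixed = ~1, vc) {
  records <- checkRecords(records, ped)
  df <- firstSeenFactors(records, fixed)
  X <- model.matrix(fixed, data = df)
  qrX <- qr(X)
  if (nrow(X) > 0L && qrX$rank < ncol(X))
    stop("fixed-effect design is rank deficient; confounded columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(records)),
                            j = match(records$animal, ped@id),
                            x = 1,
                            dims = c(nrow(records), length(ped@id)),
                            dimnames = list(NULL, ped@id))
  list(X = X, Z = Z, Rinv = 1 / residualVariances(records, vc),
       y = records$value)
}

#' Assemble the full mixed-model equations
#'
#' Builds the symmetric system
#' `[X'R^-1 X, X'R^-1 Z; Z'R^-1 X, Z'R^-1 Z + Kinv / sigmaA2]` for any
#' labelled genetic precision matrix `Kinv` (pedigree `A^-1` for BLUP, `H^-1` for ssGBLUP,
#' reduced `Hpp^-1`/`Hqq^-1` for the reduced models when paired with the
#' matching design).
#'
#' @param X,Z,Rinv,y design components as from [buildDesign()] (`Rinv` is the
#'   diagonal of the inverse residual matrix).
#' @param Kinv labelled genetic precision matrix; its labels must match
#'   `colnames(Z)` as a set.
#' @param vc variance components (supplies `sigmaA2`).
#' @return an [EquationSystem].
#' @export
assembleFull <- function(X, Z, Rinv, y, Kinv, vc) {
  if (!setequal(colnames(Z), rownames(Kinv)))
    stop("genetic-effect labels of Z and Kinv do not match")
  Kinv <- Kinv[colnames(Z), colnames(Z), drop = FALSE]
  XR <- X * Rinv
  ZR <- Matrix::Diagonal(x = Rinv) %*% Z
  lhs <- rbind(
    cbind(crossprod(XR, X), as.matrix(Matrix::crossprod(XR, Z))),
    cbind(as.matrix(Matrix::crossprod(ZR, X)),
          as.matrix(Matrix::crossprod(ZR, Z) + Kinv / vc$sigmaA2)))
  rhs <- c(as.numeric(crossprod(XR, y)), as.numeric(Matrix::crossprod(ZR, y)))
  effects <- data.frame(
    type = c(rep("fixed", ncol(X)), rep("animal", ncol(Z))),
    label = c(colnames(X), colnames(Z)),
    stringsAsFactors = FALSE)
  lhs <- symmetrize(lhs)
  dimnames(lhs) <- NULL
  new("EquationSystem", lhs = as.matrix(lhs), rhs = rhs, effects = effects)
}

#' Solve a mixed-model equation system
#'
#' Direct dense factorization (the default for the system sizes this package
#' targets, below about 10,000 equations) or Jacobi-preconditioned conjugate
#' gradients.
#'
#' @param sys an [EquationSystem].
#' @param method `"direct"` or `"pcg"`.
#' @param tol relative residual tolerance for PCG (default `1e-12`).
#' @param maxit PCG iteration cap.
#' @param methodTag tag recorded in the returned solution set.
#' @return a [SolutionSet] whose slots are filled according to the effect
#'   types present in the system; all animal solutions are tagged
#'   `"direct"`.
#' @export
solveMME <- function(sys, method = c("direct", "pcg"), tol = 1e-12,
                     maxit = 10000L, methodTag = "mme") {
  method <- match.arg(method)
  A <- as.matrix(sys@lhs)
  b <- sys@rhs
  x <- if (method == "direct") {
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("singular equation system: ", conditionMessage(e)))
    as.numeric(sol)
  } else {
    pcgSolve(A, b, tol = tol, maxit = maxit)
  }
  eff <- sys@effects
  pick <- function(tp) setNames(x[eff$type == tp], eff$label[eff$type == tp])
  animal <- pick("animal")
  new("SolutionSet",
      fixed = pick("fixed"), animal = animal,
      alpha = pick("marker"), epsilon = pick("epsilon"), delta = pick("delta"),
      provenance = setNames(rep("direct", length(animal)), names(animal)),
      method = methodTag)
}

pcgSolve <- function(A, b, tol = 1e-12, maxit = 10000L) {
  Minv <- 1 / diag(A)
  if (any(!is.finite(Minv))) stop("zero diagonal in equation system")
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) / bnorm <= tol) return(x)
    z <- Minv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  stop("PCG did not converge in ", maxit, " iterations (relative residual ",
       format(sqrt(sum(r * r)) / bnorm, digits = 3), ")")
}

#' Full single-step (or pedigree) animal-model evaluation
#'
#' Convenience pipeline: builds `A^-1`, the genotyped-subset inverse and
#' `H^-1` (when genomic information is supplied), assembles the full
#' mixed-model equations and solves them. With neither `G` nor `markers`
#' this is pedigree BLUP.
#'
#' @param records phenotype data.frame (see [buildDesign()]).
#' @param ped a [Pedigree].
#' @param genotyped genotyped animal labels (required with genomic input).
#' @param G genomic relationship matrix over the genotyped animals, or
#'   `NULL` to build it from `markers`.
#' @param markers a [MarkerData] used when `G` is `NULL`.
#' @param vc variance components.
#' @param fixed fixed-effect formula.
#' @param solver `"direct"` or `"pcg"`.
#' @param tol PCG tolerance.
#' @return a [SolutionSet] (method `"ssgblup"` or `"blup"`).
#' @export
solveFull <- function(records, ped, genotyped = NULL, G = NULL, markers = NULL,
                      vc, fixed = ~1, solver = "direct", tol = 1e-12) {
  aInv <- aInverse(ped)
  if (is.null(G) && !is.null(markers)) {
    G <- buildG(markers)
    if (is.null(genotyped)) genotyped <- rownames(G)
  }
  if (!is.null(G)) {
    if (is.null(genotyped)) genotyped <- rownames(G)
    genotyped <- checkSubset(genotyped, ped, "genotyped")
    a22Inv <- subsetInverse(aInv, genotyped)
    Kinv <- hInverse(aInv, invertG(G), a22Inv)
    tag <- "ssgblup"
  } else {
    Kinv <- aInv
    tag <- "blup"
  }
  d <- buildDesign(records, ped, fixed, vc)
  sys <- assembleFull(d$X, d$Z, d$Rinv, d$y, Kinv, vc)
  sol <- solveMME(sys, method = solver, tol = tol, methodTag = tag)
  sol@animal <- sol@animal[ped@id]
  sol@provenance <- setNames(rep("direct", length(sol@animal)), ped@id)
  sol
}
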