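## Pedigree-based numerator relationship machinery: tabular A, inbreeding
## and Mendelian-sampling variances, Henderson's sparse A-inverse, and
## Schur-complement subset inverses.

#' Tabular numerator relationship matrix
#'
#' Computes A by the recursive tabular rules: `a(i,i) = 1 + F_i` with
#' `F_i = a(s,d)/2`, and `a(i,j) = (a(j,s) + a(j,d))/2` for `j` preceding
#' `i`. When `subset` is given, the pedigree is first restricted to the
#' subset and all its ancestors, and the final matrix is sliced to the
#' subset (in the order supplied). Serves as the dense oracle for all sparse
#' inverse routines.
#'
#' @param ped a [Pedigree].
#' @param subset animal labels to keep, or `NULL` for all.
#' @return dense symmetric matrix with animal labels as dimnames.
#' @export
tabularA <- function(ped, subset = NULL) {
  if (!is.null(subset)) {
    subset <- checkSubset(subset, ped, "subset")
    anc <- ancestorClosure(ped, subset)
    sub <- restrictPedigree(ped, anc)
    return(tabularA(sub)[subset, subset, drop = FALSE])
  }
  n <- length(ped@id)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else numeric(i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else numeric(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

## labels of subset plus all its ancestors
ancestorClosure <- function(ped, subset) {
  keep <- logical(length(ped@id))
  keep[match(subset, ped@id)] <- TRUE
  for (i in rev(seq_along(ped@id)))   # topological order: scan top-down
    if (keep[i]) keep[parentIdx(ped, i)] <- TRUE
  ped@id[keep]
}

## restrict to a label set closed under known parents
restrictPedigree <- function(ped, keep) {
  kIdx <- match(keep, ped@id)
  kIdx <- kIdx[order(kIdx)]
  s <- sireIds(ped)[kIdx]; d <- damIds(ped)[kIdx]
  s[!(s %in% ped@id[kIdx])] <- NA
  d[!(d %in% ped@id[kIdx])] <- NA
  Pedigree(ped@id[kIdx], s, d)
}

#' Inbreeding coefficients and Mendelian-sampling variances
#'
#' Inbreeding is computed by the Meuwissen-Luo recursive algorithm (tracing
#' each animal's ancestor tree through the `A = TDT'` decomposition), and the
#' Mendelian-sampling variance ratio is the diagonal of `D`:
#' `D_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_known` with one, and `1` with none.
#'
#' @param ped a [Pedigree].
#' @return data.frame with columns `id`, `F` (inbreeding) and `D`
#'   (Mendelian-sampling variance ratio), in pedigree order.
#' @export
inbreeding <- function(ped) {
  n <- length(ped@id)
  F <- numeric(n)
  D <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    ## F = -1 convention for unknown parents folds the three D cases into one
    Fs <- if (is.na(s)) -1 else F[s]
    Fd <- if (is.na(d)) -1 else F[d]
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (is.na(s) || is.na(d)) next
    ## a(i,i) = sum over ancestors j of L_ij^2 D_j; F_i = a(i,i) - 1
    L[] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      sj <- ped@sire[j]; dj <- ped@dam[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * L[j]
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  data.frame(id = ped@id, F = F, D = D, stringsAsFactors = FALSE)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules: for
#' each animal add `1/D_i` to its own diagonal, `-1/(2 D_i)` to each
#' (animal, known parent) pair and `1/(4 D_i)` to each pair of known
#' parents. With `withInbreeding = TRUE` (the default) `D_i` accounts for
#' parental inbreeding.
#'
#' @param ped a [Pedigree].
#' @param withInbreeding use inbreeding-adjusted Mendelian-sampling
#'   variances (default `TRUE`).
#' @return sparse symmetric `Matrix` (class `dsCMatrix`) with animal labels.
#' @export
aInverse <- function(ped, withInbreeding = TRUE) {
  n <- length(ped@id)
  if (withInbreeding) {
    D <- inbreeding(ped)$D
  } else {
    nk <- (!is.na(ped@sire)) + (!is.na(ped@dam))
    D <- c(1, 0.75, 0.5)[nk + 1L]
  }
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  for (i in seq_len(n)) {
    di <- 1 / D[i]
    par <- parentIdx(ped, i)
    ti <- c(i, rep(par, each = 1L), rep(i, length(par)))
    tj <- c(i, rep(i, length(par)), par)
    tx <- c(di, rep(-di / 2, 2L * length(par)))
    if (length(par)) {
      pp <- expand.grid(par, par)
      ti <- c(ti, pp[[1]]); tj <- c(tj, pp[[2]])
      tx <- c(tx, rep(di / 4, nrow(pp)))
    }
    ii[[i]] <- ti; jj[[i]] <- tj; xx[[i]] <- tx
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(M)
}

#' Inverse of a relationship submatrix from the full sparse inverse
#'
#' Given A-inverse (or any labelled symmetric positive-definite inverse),
#' returns the inverse of the corresponding relationship matrix restricted
#' to `keep`, via the Schur complement on the discarded block:
#' `A_kk^-1 = A^kk - A^kn (A^nn)^-1 A^nk`, using a sparse factorization of
#' the discarded block. This is how `A22^-1`, `App^-1` and `Aqq^-1` are
#' obtained without ever inverting a dense A.
#'
#' @param aInv labelled symmetric matrix (typically from [aInverse()]).
#' @param keep labels to keep; the result follows this order.
#' @return symmetric matrix over `keep` (sparse when the input is sparse).
#' @export
subsetInverse <- function(aInv, keep) {
  labs <- rownames(aInv)
  keep <- as.character(keep)
  if (!all(keep %in% labs))
    stop("keep labels absent from matrix: ",
         paste(setdiff(keep, labs), collapse = ", "))
  drop <- setdiff(labs, keep)
  if (!length(drop))
    return(symmetrize(aInv[keep, keep, drop = FALSE]))
  Ann <- aInv[drop, drop, drop = FALSE]
  Ank <- aInv[drop, keep, drop = FALSE]
  S <- aInv[keep, keep, drop = FALSE] -
    Matrix::crossprod(Ank, Matrix::solve(Ann, Ank))
  symmetrize(S)
}

symmetrize <- function(M) {
  dn <- dimnames(M)
  S <- (M + Matrix::t(M)) / 2
  if (is(S, "Matrix")) S <- Matrix::forceSymmetric(S)
  dimnames(S) <- dn
  S
}
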