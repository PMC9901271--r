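## Genomic relationship handling and single-step H-inverse assembly.

#' Marker data container
#'
#' Validates an allele-count matrix (0/1/2, no missing values), computes or
#' accepts per-marker allele frequencies, centers the genotypes at `2 p_j`
#' and records the VanRaden denominator `k = 2 sum p_j (1 - p_j)`.
#' Monomorphic markers (given the frequencies used) carry no information and
#' are dropped with a message.
#'
#' @param geno matrix of allele counts, rownames = animal labels.
#' @param alleleFreq optional per-marker allele frequencies; default observed
#'   frequencies `mean(count)/2`.
#' @param scale `"relationship"` divides the centered matrix by `sqrt(k)` so
#'   that `M M'` is on the relationship scale (the convention the marker
#'   model uses); `"centered"` leaves it centered only.
#' @return a [MarkerData].
#' @export
markerData <- function(geno, alleleFreq = NULL,
                       scale = c("relationship", "centered")) {
  scale <- match.arg(scale)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (is.null(rownames(geno)))
    stop("genotype matrix needs animal labels as rownames")
  if (anyNA(geno) || !all(geno %in% c(0, 1, 2)))
    stop("genotypes must be complete allele counts in {0, 1, 2}")
  if (is.null(alleleFreq)) alleleFreq <- colMeans(geno) / 2
  if (length(alleleFreq) != ncol(geno))
    stop("alleleFreq length must equal the number of markers")
  poly <- alleleFreq > 0 & alleleFreq < 1
  if (ncol(geno) > 0 && !any(poly))
    stop("all markers are monomorphic; no genomic information")
  if (any(!poly)) {
    message("dropping ", sum(!poly), " monomorphic marker(s)")
    geno <- geno[, poly, drop = FALSE]
    alleleFreq <- alleleFreq[poly]
  }
  k <- 2 * sum(alleleFreq * (1 - alleleFreq))
  Mc <- sweep(geno, 2L, 2 * alleleFreq, "-")
  if (scale == "relationship" && ncol(geno) > 0) Mc <- Mc / sqrt(k)
  new("MarkerData", raw = geno, freq = as.numeric(alleleFreq), centered = Mc,
      scaleK = k, scaled = scale == "relationship")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M_c M_c' / (2 sum p_j (1 - p_j))` with `M_c` centered at twice the
#' allele frequency.
#'
#' @param markers a [MarkerData] (or allele-count matrix passed on to
#'   [markerData()]).
#' @return dense symmetric matrix over the genotyped animals.
#' @export
buildG <- function(markers) {
  if (!is(markers, "MarkerData")) markers <- markerData(markers)
  if (ncol(markers@raw) < 1L) stop("at least one polymorphic marker required")
  Mc <- markers@centered
  G <- if (markers@scaled) tcrossprod(Mc) else tcrossprod(Mc) / markers@scaleK
  symmetrize(G)
}

#' Invert a genomic relationship matrix
#'
#' Checks symmetry and positive definiteness (smallest eigenvalue above
#' `1e-8` times the largest) before inverting; a near-singular G is an
#' error, with a hint that such matrices are usually made invertible by
#' blending toward the pedigree relationships of the genotyped animals
#' (not performed here).
#'
#' @param G labelled symmetric matrix.
#' @return dense inverse with the same labels.
#' @export
invertG <- function(G) {
  G <- as.matrix(G)
  if (max(abs(G - t(G))) > 1e-8) stop("G is not symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 * max(abs(ev)))
    stop("G is singular or near-singular (min eigenvalue ",
         format(min(ev), digits = 3),
         "); consider blending G toward A22 before inversion")
  Gi <- chol2inv(chol(G))
  dimnames(Gi) <- dimnames(G)
  symmetrize(Gi)
}

#' Single-step relationship inverse
#'
#' Adds the genomic correction `G^-1 - A22^-1` into the genotyped block of a
#' pedigree-based inverse. The pedigree inverse may be the full `A^-1` (full
#' ssGBLUP H-inverse) or a subset inverse `App^-1`/`Aqq^-1` (reduced-system
#' `Hpp^-1`/`Hqq^-1`); genotyped equations are located by label, so the
#' result is independent of animal ordering.
#'
#' @param aInv pedigree-based inverse over the animal set of the system.
#' @param gInv inverse genomic relationship matrix over the genotyped
#'   animals.
#' @param a22Inv inverse of the pedigree relationship submatrix of the same
#'   genotyped animals (from [subsetInverse()]).
#' @return symmetric matrix with the same labels as `aInv`.
#' @export
hInverse <- function(aInv, gInv, a22Inv) {
  gLab <- rownames(gInv)
  if (is.null(gLab) || is.null(rownames(a22Inv)) || is.null(rownames(aInv)))
    stop("all matrices must carry animal labels as dimnames")
  if (!setequal(gLab, rownames(a22Inv)))
    stop("gInv and a22Inv must cover the same genotyped animals")
  if (!all(gLab %in% rownames(aInv)))
    stop("genotyped animals missing from the pedigree inverse: ",
         paste(setdiff(gLab, rownames(aInv)), collapse = ", "))
  corr <- as.matrix(gInv) - as.matrix(a22Inv)[gLab, gLab, drop = FALSE]
  H <- as(aInv, "CsparseMatrix")
  H <- as(H, "generalMatrix")
  idx <- match(gLab, rownames(aInv))
  H[idx, idx] <- H[idx, idx] + corr
  symmetrize(H)
}
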