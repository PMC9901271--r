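#' Pedigree class
#'
#' A validated pedigree: animals stored in topological order (parents always
#' precede progeny), with sire/dam kept as integer indices into that order
#' (`NA` = unknown parent). Construct with [Pedigree()] or [readPedigree()];
#' external files need not be sorted, ordering is recomputed internally.
#'
#' @slot id character vector of animal labels, topologically ordered.
#' @slot sire integer vector, index of each animal's sire in `id` (`NA` if
#'   unknown).
#' @slot dam integer vector, index of each animal's dam (`NA` if unknown).
#' @export
setClass("Pedigree",
         representation(id = "character", sire = "integer", dam = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    return("duplicated animal labels")
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    if (any(p[known] < 1L | p[known] > n))
      return("parent index out of range")
    if (any(p[known] >= which(known)))
      return("pedigree is not topologically ordered (parent after progeny)")
  }
  TRUE
})

#' AnimalSets class
#'
#' Per-method classification of the animals of a pedigree, as produced by
#' [classifyAnimals()]. All slots hold character label sets. For each
#' reduced-model variant the kept set and its complement are stored:
#' `m1p`/`m1n` (genotyped plus nongenotyped parents vs. the rest), `m2p`/`m2n`
#' (genotyped plus nongenotyped phenotyped vs. the rest), and `m3q`/`m3r`/`m3n`
#' (genotyped plus nongenotyped parents of phenotyped nongenotyped nonparents;
#' remaining nongenotyped parents; nongenotyped nonparents). `pruneClass`
#' carries the 0/4/3/2 pruning partition (class 2 = genotyped, 3 = direct
#' pedigree neighbours of genotyped animals, 4 = neighbours of class 3,
#' 0 = removable).
#'
#' @slot genotyped,phenotyped,parents character label sets.
#' @slot m1p,m1n,m2p,m2n,m3q,m3r,m3n character label sets per method.
#' @slot pruneClass named integer vector over all animals with values in
#'   `c(0L, 2L, 3L, 4L)`.
#' @export
setClass("AnimalSets",
         representation(genotyped = "character", phenotyped = "character",
                        parents = "character",
                        m1p = "character", m1n = "character",
                        m2p = "character", m2n = "character",
                        m3q = "character", m3r = "character", m3n = "character",
                        pruneClass = "integer"))

#' MarkerData class
#'
#' Genotypes of the genotyped animals as allele counts (0/1/2), together with
#' the allele frequencies used for centering, the centered (and optionally
#' scaled) matrix, and the VanRaden denominator `2 * sum(p * (1 - p))`.
#' Construct with [markerData()].
#'
#' @slot raw integer-valued matrix of allele counts, rownames = animal labels.
#' @slot freq per-marker allele frequency used for centering.
#' @slot centered centered (and, if `scale = "relationship"`, scaled) matrix.
#' @slot scaleK the VanRaden denominator `2 * sum(p * (1 - p))`.
#' @slot scaled logical, whether `centered` was divided by `sqrt(scaleK)`.
#' @export
setClass("MarkerData",
         representation(raw = "matrix", freq = "numeric", centered = "matrix",
                        scaleK = "numeric", scaled = "logical"))

#' EquationSystem class
#'
#' An assembled symmetric mixed-model equation system: left-hand side,
#' right-hand side and an effect index mapping every equation to an effect
#' type (`"fixed"`, `"animal"`, `"marker"`, `"epsilon"`, `"delta"`) and label.
#'
#' @slot lhs symmetric left-hand-side matrix (base or `Matrix`).
#' @slot rhs numeric right-hand side.
#' @slot effects data.frame with columns `type` and `label`, one row per
#'   equation.
#' @export
setClass("EquationSystem",
         representation(lhs = "ANY", rhs = "numeric", effects = "data.frame"))

setValidity("EquationSystem", function(object) {
  d <- dim(object@lhs)
  if (d[1] != d[2]) return("lhs must be square")
  if (length(object@rhs) != d[1]) return("rhs length must match lhs order")
  if (nrow(object@effects) != d[1]) return("effects must have one row per equation")
  if (!all(c("type", "label") %in% names(object@effects)))
    return("effects needs 'type' and 'label' columns")
  TRUE
})

#' SolutionSet class
#'
#' Solutions of a (possibly reduced) single-step evaluation. `fixed` holds
#' fixed-effect solutions by level label; `animal` the per-animal genetic
#' solutions (total genetic merit for marker models); `provenance` records,
#' per animal, whether the solution came out of the solved equation system
#' (`"direct"`) or a back-solving step (`"backsolved"`). Marker-model fits
#' additionally fill `alpha` (marker effects), `epsilon` (imputation
#' deviations of nongenotyped animals) and `delta` (residual polygenic
#' effects).
#'
#' @slot fixed,animal,alpha,epsilon,delta named numeric vectors.
#' @slot provenance named character vector parallel to `animal`.
#' @slot method character tag, e.g. `"ssgblup"`, `"ram1"`, `"ssmm"`.
#' @export
setClass("SolutionSet",
         representation(fixed = "numeric", animal = "numeric",
                        alpha = "numeric", epsilon = "numeric",
                        delta = "numeric", provenance = "character",
                        method = "character"))

setValidity("SolutionSet", function(object) {
  if (length(object@provenance) &&
      !identical(names(object@provenance), names(object@animal)))
    return("provenance must be named parallel to animal")
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", n, "animals (", founders, "founders ),",
      "topologically ordered\n")
  k <- min(n, 6L)
  df <- data.frame(animal = object@id[seq_len(k)],
                   sire = ifelse(is.na(object@sire[seq_len(k)]), "-",
                                 object@id[object@sire[seq_len(k)]]),
                   dam = ifelse(is.na(object@dam[seq_len(k)]), "-",
                                object@id[object@dam[seq_len(k)]]))
  print(df, row.names = FALSE)
  if (n > k) cat("...", n - k, "more animals\n")
})

setMethod("show", "AnimalSets", function(object) {
  cat("AnimalSets:",
      length(object@genotyped), "genotyped,",
      length(object@phenotyped), "phenotyped,",
      length(object@parents), "parents\n")
  cat("  method 1: |p| =", length(object@m1p), " |n| =", length(object@m1n), "\n")
  cat("  method 2: |p| =", length(object@m2p), " |n| =", length(object@m2n), "\n")
  cat("  method 3: |q| =", length(object@m3q), " |r| =", length(object@m3r),
      " |n| =", length(object@m3n), "\n")
  cat("  prune classes:", paste(names(table(object@pruneClass)),
                                table(object@pruneClass),
                                sep = ":", collapse = " "), "\n")
})

setMethod("show", "EquationSystem", function(object) {
  cat("EquationSystem of order", nrow(object@effects), "(",
      paste(names(table(object@effects$type)), table(object@effects$type),
            sep = ":", collapse = " "), ")\n")
})

setMethod("show", "SolutionSet", function(object) {
  cat("SolutionSet [", object@method, "]:",
      length(object@fixed), "fixed effects,",
      length(object@animal), "animal solutions (",
      sum(object@provenance == "backsolved"), "backsolved )\n")
  if (length(object@alpha))
    cat("  marker model:", length(object@alpha), "markers,",
        length(object@epsilon), "epsilon,", length(object@delta), "delta\n")
})

setMethod("show", "MarkerData", function(object) {
  cat("MarkerData:", nrow(object@raw), "animals x", ncol(object@raw),
      "markers; scaleK =", format(object@scaleK, digits = 6),
      if (object@scaled) "(scaled)" else "(centered only)", "\n")
})
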