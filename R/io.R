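## Plain-text interchange: labelled triplet matrices (the de-facto exchange
## format for relationship matrices in breeding software), genotype tables,
## pedigree and solution files. All reader/writer pairs round-trip.

#' Read a labelled symmetric matrix from a triplet file
#'
#' Format: whitespace-separated `row_label col_label value`, lower triangle
#' (or any triangle; entries are mirrored). Unknown labels define the index
#' in order of first appearance.
#'
#' @param path file path.
#' @return dense symmetric matrix with label dimnames.
#' @export
readMatrixTriplet <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed triplet line ", bad[1], " in ", path, ": ", lines[bad[1]])
  ri <- vapply(parts, `[[`, "", 1L)
  ci <- vapply(parts, `[[`, "", 2L)
  xv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(xv))
    stop("non-numeric value on triplet line ", which(is.na(xv))[1],
         " in ", path)
  labs <- unique(c(ri, ci))
  n <- length(labs)
  M <- matrix(0, n, n, dimnames = list(labs, labs))
  for (k in seq_along(ri)) {
    M[ri[k], ci[k]] <- xv[k]
    M[ci[k], ri[k]] <- xv[k]
  }
  M
}

#' Write a labelled symmetric matrix as triplets
#'
#' Lower triangle only, 12 significant digits, zeros skipped (except
#' diagonal).
#'
#' @param M labelled symmetric matrix.
#' @param path output path.
#' @export
writeMatrixTriplet <- function(M, path) {
  M <- as.matrix(M)
  labs <- rownames(M)
  if (is.null(labs)) stop("matrix must carry labels")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(M)))
    for (j in seq_len(i))
      if (M[i, j] != 0 || i == j)
        writeLines(paste(labs[i], labs[j],
                         format(M[i, j], digits = 12, scientific = FALSE)),
                   con)
  invisible(path)
}

#' Read a genotype table
#'
#' Whitespace table, first column animal label, remaining columns allele
#' counts 0/1/2 (no missing values allowed). A header line is auto-detected
#' and used for marker names.
#'
#' @param path file path.
#' @return integer-valued matrix with animal labels as rownames.
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[[:space:]]+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(first[-1])))
  df <- read.table(path, header = header, colClasses = "character")
  geno <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(geno) <- "double"
  if (anyNA(geno)) stop("non-numeric or missing genotype in ", path)
  rownames(geno) <- df[[1]]
  if (!header) colnames(geno) <- paste0("m", seq_len(ncol(geno)))
  geno
}

#' Write a pedigree as CSV
#'
#' Columns `animal,sire,dam`; unknown parents written as `0`. An optional
#' partition is added as a fourth column.
#'
#' @param ped a [Pedigree].
#' @param path output path.
#' @param partition optional named vector (e.g. from [prunePartition()]).
#' @export
writePedigree <- function(ped, path, partition = NULL) {
  df <- data.frame(animal = animalIds(ped),
                   sire = ifelse(is.na(sireIds(ped)), "0", sireIds(ped)),
                   dam = ifelse(is.na(damIds(ped)), "0", damIds(ped)),
                   stringsAsFactors = FALSE)
  if (!is.null(partition)) df$partition <- partition[df$animal]
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write solutions as CSV
#'
#' Long format with columns `effect_type,label,solution,provenance,method`.
#' Fixed effects and, when present, marker effects, deviations and residual
#' polygenic effects are included alongside the animal solutions.
#'
#' @param sol a [SolutionSet].
#' @param path output path.
#' @export
writeSolutions <- function(sol, path) {
  rows <- list(
    data.frame(effect_type = "fixed", label = names(sol@fixed),
               solution = unname(sol@fixed), provenance = "direct"),
    data.frame(effect_type = "animal", label = names(sol@animal),
               solution = unname(sol@animal),
               provenance = unname(sol@provenance[names(sol@animal)])))
  for (slotNm in c("alpha", "epsilon", "delta")) {
    v <- slot(sol, slotNm)
    if (length(v))
      rows <- c(rows, list(data.frame(effect_type = slotNm, label = names(v),
                                      solution = unname(v),
                                      provenance = "direct")))
  }
  df <- do.call(rbind, rows)
  df$method <- sol@method
  df$solution <- format(df$solution, digits = 12, scientific = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read solutions written by [writeSolutions()]
#'
#' @param path file path.
#' @return a [SolutionSet].
#' @export
readSolutions <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", colClasses = "character")
  need <- c("effect_type", "label", "solution", "provenance", "method")
  if (!all(need %in% names(df)))
    stop("not a solutions file (missing columns): ", path)
  df$solution <- as.numeric(df$solution)
  grab <- function(tp) {
    sub <- df[df$effect_type == tp, , drop = FALSE]
    setNames(sub$solution, sub$label)
  }
  animal <- grab("animal")
  new("SolutionSet",
      fixed = grab("fixed"), animal = animal,
      alpha = grab("alpha"), epsilon = grab("epsilon"), delta = grab("delta"),
      provenance = setNames(df$provenance[df$effect_type == "animal"],
                            names(animal)),
      method = df$method[1])
}
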