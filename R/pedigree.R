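## Pedigree construction, validation, ordering, classification and pruning.

normalizeParent <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% c("0", "", "NA", ".")] <- NA_character_
  x
}

#' Construct a validated, topologically ordered pedigree
#'
#' Animals may be supplied in any order; the constructor recomputes a
#' topological order (parents before progeny), normalises unknown-parent
#' codes (`0`, `NA`, `""`, `"."`) and validates the structure. A parent label
#' that never appears as an animal is an error unless `addFounders = TRUE`,
#' in which case it is added as a founder record.
#'
#' @param id animal labels (coerced to character; must be unique).
#' @param sire,dam parent labels, `0`/`NA` for unknown.
#' @param addFounders add missing parent labels as founders instead of
#'   failing (default `FALSE`).
#' @return a [Pedigree].
#' @examples
#' ped <- Pedigree(c("a", "b", "c"), sire = c(0, 0, "a"), dam = c(0, 0, "b"))
#' animalIds(ped)
#' @export
Pedigree <- function(id, sire = NA, dam = NA, addFounders = FALSE) {
  id <- trimws(as.character(id))
  n0 <- length(id)
  sire <- normalizeParent(rep_len(sire, n0))
  dam <- normalizeParent(rep_len(dam, n0))
  if (anyDuplicated(id))
    stop("duplicated animal labels: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(id %in% c("0", "", "NA", ".")))
    stop("animal labels may not use the unknown-parent codes 0/NA/.")
  missingPar <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(missingPar)) {
    if (!addFounders)
      stop("parent label(s) absent from the pedigree: ",
           paste(missingPar, collapse = ", "),
           " (use addFounders = TRUE to add them as founders)")
    id <- c(id, missingPar)
    sire <- c(sire, rep(NA_character_, length(missingPar)))
    dam <- c(dam, rep(NA_character_, length(missingPar)))
  }
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("cycle detected: animal listed as its own parent: ",
         paste(id[(!is.na(sire) & sire == id) | (!is.na(dam) & dam == id)],
               collapse = ", "))

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)

  ## Kahn topological sort; leftover animals lie on a cycle.
  nParentsLeft <- (!is.na(si)) + (!is.na(di))
  childrenOf <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i]))
      if (!is.na(p)) childrenOf[[p]] <- c(childrenOf[[p]], i)
  }
  order <- integer(0)
  ready <- which(nParentsLeft == 0L)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    order <- c(order, i)
    for (ch in childrenOf[[i]]) {
      nParentsLeft[ch] <- nParentsLeft[ch] - 1L
      if (nParentsLeft[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n)
    stop("cycle detected in pedigree involving: ",
         paste(id[setdiff(seq_len(n), order)], collapse = ", "))

  newPos <- integer(n); newPos[order] <- seq_len(n)
  obj <- new("Pedigree",
             id = id[order],
             sire = as.integer(ifelse(is.na(si[order]), NA, newPos[si[order]])),
             dam = as.integer(ifelse(is.na(di[order]), NA, newPos[di[order]])))
  validObject(obj)
  obj
}

#' Read a pedigree from a delimited text file
#'
#' Expects three resolvable columns (animal, sire, dam). The header is
#' auto-detected; `0`, `NA`, `.` or empty mean unknown parent. Comma, tab or
#' whitespace separated files are all accepted.
#'
#' @param path file path.
#' @param columns indices or names of the animal/sire/dam columns
#'   (default first three).
#' @param addFounders see [Pedigree()].
#' @return a [Pedigree].
#' @export
readPedigree <- function(path, columns = 1:3, addFounders = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  sep <- detectSep(path)
  first <- scan(path, what = "character", nlines = 1, sep = sep, quiet = TRUE,
                strip.white = TRUE)
  headerNames <- c("animal", "id", "sire", "dam", "father", "mother", "sir")
  header <- any(tolower(first) %in% headerNames)
  df <- read.table(path, header = header, sep = sep, colClasses = "character",
                   strip.white = TRUE, blank.lines.skip = TRUE,
                   stringsAsFactors = FALSE)
  if (is.character(columns)) columns <- match(columns, names(df))
  if (ncol(df) < max(columns) || anyNA(columns))
    stop("pedigree file must have resolvable animal/sire/dam columns: ", path)
  Pedigree(df[[columns[1]]], df[[columns[2]]], df[[columns[3]]],
           addFounders = addFounders)
}

detectSep <- function(path) {
  l <- readLines(path, n = 1L)
  if (grepl(",", l)) "," else if (grepl("\t", l)) "\t" else ""
}

## internal: indices of known parents of animal i
parentIdx <- function(ped, i) {
  p <- c(ped@sire[i], ped@dam[i])
  p[!is.na(p)]
}

checkSubset <- function(labels, ped, what) {
  labels <- as.character(labels)
  bad <- setdiff(labels, ped@id)
  if (length(bad))
    stop(what, " labels not in pedigree: ", paste(bad, collapse = ", "))
  labels
}

#' Classify animals for the reduced-model variants
#'
#' Splits the pedigree into the animal sets each reduced animal model keeps
#' or absorbs, and computes the 0/4/3/2 pruning partition:
#' * method 1 keeps genotyped animals and nongenotyped parents (`p`), and
#'   absorbs the rest (`n`);
#' * method 2 keeps genotyped animals and nongenotyped phenotyped animals;
#' * method 3 keeps genotyped animals and nongenotyped parents of phenotyped
#'   nongenotyped nonparents (`q`); the remaining nongenotyped parents (`r`)
#'   and nonparents (`n`) are absorbed. A phenotyped nongenotyped parent is
#'   always kept in `q` (its record needs an identity row in the reduced
#'   design, so it cannot be absorbed into `r`).
#'
#' @param ped a [Pedigree].
#' @param genotyped,phenotyped label sets (subsets of the pedigree animals).
#' @return an [AnimalSets].
#' @export
classifyAnimals <- function(ped, genotyped, phenotyped) {
  genotyped <- unique(checkSubset(genotyped, ped, "genotyped"))
  phenotyped <- unique(checkSubset(phenotyped, ped, "phenotyped"))
  ids <- ped@id
  isG <- ids %in% genotyped
  isPh <- ids %in% phenotyped
  isPar <- seq_along(ids) %in% c(ped@sire, ped@dam)

  m1p <- ids[isG | (!isG & isPar)]
  m1n <- setdiff(ids, m1p)
  m2p <- ids[isG | (!isG & isPh)]
  m2n <- setdiff(ids, m2p)

  ## phenotyped nongenotyped nonparents and their known parents
  pnn <- ids[isPh & !isG & !isPar]
  pnnParents <- unique(unlist(lapply(match(pnn, ids), function(i)
    ids[parentIdx(ped, i)])))
  m3q <- ids[isG | (ids %in% pnnParents & !isG) | (!isG & isPar & isPh)]
  m3r <- setdiff(m1p, m3q)
  m3n <- m1n

  new("AnimalSets",
      genotyped = ids[isG], phenotyped = ids[isPh], parents = ids[isPar],
      m1p = m1p, m1n = m1n, m2p = m2p, m2n = m2n,
      m3q = m3q, m3r = m3r, m3n = m3n,
      pruneClass = prunePartition(ped, genotyped))
}

#' Pruning partition of a pedigree relative to its genotyped animals
#'
#' Class 2 = genotyped animals; class 3 = nongenotyped animals that are a
#' parent, progeny or mate of a genotyped animal; class 4 = nongenotyped
#' animals that are a parent, progeny or mate of a class-3 animal; class 0 =
#' the remainder, whose equations carry no genomic information and are
#' candidates for removal before single-step evaluation.
#'
#' @param ped a [Pedigree].
#' @param genotyped genotyped animal labels.
#' @return named integer vector over all animals with values 0/2/3/4.
#' @export
prunePartition <- function(ped, genotyped) {
  genotyped <- unique(checkSubset(genotyped, ped, "genotyped"))
  ids <- ped@id
  n <- length(ids)

  ## pedigree neighbourhood: parents, progeny and mates
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    for (p in c(s, d)) if (!is.na(p)) {
      nb[[i]] <- c(nb[[i]], p)
      nb[[p]] <- c(nb[[p]], i)
    }
    if (!is.na(s) && !is.na(d)) {
      nb[[s]] <- c(nb[[s]], d)
      nb[[d]] <- c(nb[[d]], s)
    }
  }

  cls <- integer(n)
  g <- match(genotyped, ids)
  cls[g] <- 2L
  c3 <- setdiff(unique(unlist(nb[g])), g)
  cls[c3] <- 3L
  c4 <- setdiff(unique(unlist(nb[c3])), c(g, c3))
  cls[c4] <- 4L
  setNames(cls, ids)
}

#' Prune class-0 animals from a pedigree
#'
#' Removes the animals the partition marks as class 0 (no pedigree link
#' within two hops of a genotyped animal). References to removed parents are
#' set to unknown. The removed animals can be evaluated separately by
#' pedigree BLUP; removal is exact for class-0 animals absorbed as leaves or
#' founders and assumes negligible change in fixed-effect solutions
#' otherwise, so a warning is emitted whenever a kept animal loses a parent.
#'
#' @param ped a [Pedigree].
#' @param partition result of [prunePartition()] (recomputed from `genotyped`
#'   when omitted).
#' @param genotyped genotyped labels, used when `partition` is missing.
#' @return list with elements `pedigree` (pruned [Pedigree]) and `removed`
#'   (character labels).
#' @export
prunePedigree <- function(ped, partition = NULL, genotyped = NULL) {
  if (is.null(partition)) {
    if (is.null(genotyped))
      stop("supply either a partition or the genotyped label set")
    partition <- prunePartition(ped, genotyped)
  }
  partition <- partition[ped@id]
  if (!any(partition == 2L))
    stop("no genotyped animals: nothing to anchor the pruning partition")
  keep <- names(partition)[partition != 0L]
  removed <- setdiff(ped@id, keep)
  if (!length(removed))
    return(list(pedigree = ped, removed = character(0)))
  kIdx <- match(keep, ped@id)
  s <- sireIds(ped)[kIdx]; d <- damIds(ped)[kIdx]
  lost <- sum(s %in% removed, na.rm = TRUE) + sum(d %in% removed, na.rm = TRUE)
  s[s %in% removed] <- NA
  d[d %in% removed] <- NA
  if (lost > 0)
    warning(lost, " parent reference(s) to removed animals set to unknown; ",
            "solutions for the affected kept animals may shift slightly")
  list(pedigree = Pedigree(keep, s, d), removed = removed)
}
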