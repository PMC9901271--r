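#' @describeIn Pedigree number of animals
#' @param object,ped a `Pedigree`
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))

#' @describeIn Pedigree animal labels in topological order
#' @export
setGeneric("animalIds", function(object) standardGeneric("animalIds"))

#' @describeIn Pedigree sire labels (`NA` when unknown), in animal order
#' @export
setGeneric("sireIds", function(object) standardGeneric("sireIds"))

#' @describeIn Pedigree dam labels (`NA` when unknown), in animal order
#' @export
setGeneric("damIds", function(object) standardGeneric("damIds"))

setMethod("nAnimals", "Pedigree", function(object) length(object@id))
setMethod("animalIds", "Pedigree", function(object) object@id)
setMethod("sireIds", "Pedigree", function(object)
  ifelse(is.na(object@sire), NA_character_, object@id[object@sire]))
setMethod("damIds", "Pedigree", function(object)
  ifelse(is.na(object@dam), NA_character_, object@id[object@dam]))

#' Accessors for solution sets
#'
#' @param object a [SolutionSet]
#' @return `fixedSolutions`: named numeric vector of fixed-effect solutions;
#'   `animalSolutions`: named numeric vector of per-animal genetic solutions;
#'   `solutionProvenance`: named character vector (`"direct"`/`"backsolved"`);
#'   `markerSolutions`: named numeric vector of marker-effect solutions.
#' @name solution-accessors
#' @export
setGeneric("fixedSolutions", function(object) standardGeneric("fixedSolutions"))

#' @rdname solution-accessors
#' @export
setGeneric("animalSolutions", function(object) standardGeneric("animalSolutions"))

#' @rdname solution-accessors
#' @export
setGeneric("solutionProvenance", function(object) standardGeneric("solutionProvenance"))

#' @rdname solution-accessors
#' @export
setGeneric("markerSolutions", function(object) standardGeneric("markerSolutions"))

setMethod("fixedSolutions", "SolutionSet", function(object) object@fixed)
setMethod("animalSolutions", "SolutionSet", function(object) object@animal)
setMethod("solutionProvenance", "SolutionSet", function(object) object@provenance)
setMethod("markerSolutions", "SolutionSet", function(object) object@alpha)

#' Order of an equation system
#'
#' @param object an [EquationSystem]
#' @return integer, the number of equations.
#' @export
setGeneric("systemOrder", function(object) standardGeneric("systemOrder"))

setMethod("systemOrder", "EquationSystem", function(object) nrow(object@effects))
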