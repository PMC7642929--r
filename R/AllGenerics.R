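#' Accessors for sarnam containers
#'
#' @param object a sarnam S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerTable", function(object) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("familyIds", function(object) standardGeneric("familyIds"))

#' @rdname accessors
#' @param family family id.
#' @export
setGeneric("dosageMatrix", function(object, family) {
  standardGeneric("dosageMatrix")
})

#' @rdname accessors
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))

#' @rdname accessors
#' @export
setGeneric("qtlTable", function(object) standardGeneric("qtlTable"))

#' @rdname accessors
#' @export
setGeneric("qtlEffects", function(object) standardGeneric("qtlEffects"))

#' @rdname accessors
#' @export
setGeneric("pathCoefficients", function(object) {
  standardGeneric("pathCoefficients")
})

#' @rdname accessors
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))

#' @rdname accessors
#' @export
setMethod("markerTable", "GeneticMap", function(object) object@markers)

#' @rdname accessors
#' @export
setMethod("markerTable", "NamGenotypes", function(object) {
  object@map@markers
})

#' @rdname accessors
#' @export
setMethod("familyIds", "NamGenotypes", function(object) names(object@dosages))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "NamGenotypes", function(object, family) {
  if (!family %in% names(object@dosages)) {
    keyingError("unknown family '%s'", family)
  }
  object@dosages[[family]]
})

#' @rdname accessors
#' @export
setMethod("lineIds", "NamGenotypes", function(object) {
  unlist(lapply(object@dosages, rownames), use.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("qtlTable", "QtlModel", function(object) object@qtl)

#' @rdname accessors
#' @export
setMethod("qtlEffects", "QtlModel", function(object) object@effects)

#' @rdname accessors
#' @export
setMethod("pathCoefficients", "PathFit", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("fitIndices", "PathFit", function(object) object@fitIndices)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat(sprintf(
    "GeneticMap: %d markers on %d chromosome(s), %.1f cM total\n",
    nrow(m), length(unique(m$chrom)),
    sum(tapply(m$pos_cM, m$chrom, max))
  ))
})

setMethod("show", "NamGenotypes", function(object) {
  n <- vapply(object@dosages, nrow, integer(1))
  cat(sprintf(
    "NamGenotypes: %d families, %d lines, %d markers\n",
    length(n), sum(n), nrow(object@map@markers)
  ))
  cat("  families:", paste(sprintf("%s (%d)", names(n), n), collapse = ", "),
    "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d QTL rows, %d trait-trait edges, shelfSd = %.3g\n",
    nrow(object@qtl), nrow(object@pathCoeffs), object@shelfSd
  ))
})

setMethod("show", "QtlModel", function(object) {
  cat(sprintf(
    "QtlModel for %s: %d QTL (threshold %.3f on -log10 p)\n",
    object@trait, nrow(object@qtl), object@threshold
  ))
  if (nrow(object@qtl)) {
    print(object@qtl, row.names = FALSE)
  }
})

setMethod("show", "PathFit", function(object) {
  fi <- object@fitIndices
  cat(sprintf(
    "PathFit: %d group(s), %d free edges\n",
    sum(fi$group != "all"), sum(object@coefficients$op == "~")
  ))
  print(fi, row.names = FALSE)
})
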