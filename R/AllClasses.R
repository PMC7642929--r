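#' GeneticMap: ordered marker positions
#'
#' Holds marker identifiers with chromosome, physical (bp) and genetic (cM)
#' coordinates. Marker ids follow the \code{m_<chr>_<bp>} convention so a
#' marker name is self-describing.
#'
#' @slot markers data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos_bp}, \code{pos_cM}, sorted by (chrom, pos_bp).
#' @export
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker_id", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(m))) {
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$marker_id)) return("marker_id values must be unique")
  if (any(m$chrom < 1)) return("chrom must be >= 1")
  if (any(m$pos_bp < 0) || any(m$pos_cM < 0)) {
    return("positions must be non-negative")
  }
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (is.unsorted(sub$pos_cM, strictly = TRUE)) {
      return(sprintf("pos_cM not strictly increasing on chromosome %s", ch))
    }
    if (is.unsorted(sub$pos_bp, strictly = TRUE)) {
      return(sprintf("pos_bp not strictly increasing on chromosome %s", ch))
    }
  }
  TRUE
})

#' NamGenotypes: per-family line-by-marker dosage matrices
#'
#' A nested association mapping panel: several biparental RIL families that
#' share one recurrent parent and one genetic map. Each family's matrix holds
#' the probability that a line carries the non-recurrent (alternative) allele
#' at each marker; fully inbred calls are 0/1, residual heterozygosity 0.5.
#'
#' @slot map a \linkS4class{GeneticMap} shared by all families.
#' @slot dosages named list (one element per family) of numeric matrices,
#'   rows = lines, columns = markers in map order, values in [0, 1].
#' @export
setClass("NamGenotypes", representation(map = "GeneticMap", dosages = "list"))

setValidity("NamGenotypes", function(object) {
  ids <- object@map@markers$marker_id
  if (is.null(names(object@dosages)) || anyDuplicated(names(object@dosages))) {
    return("dosages must be a uniquely named list (family ids)")
  }
  for (fam in names(object@dosages)) {
    d <- object@dosages[[fam]]
    if (!is.matrix(d) || !identical(colnames(d), ids)) {
      return(sprintf("family %s: columns must match map markers", fam))
    }
    if (is.null(rownames(d)) || anyDuplicated(rownames(d))) {
      return(sprintf("family %s: rows must be uniquely named lines", fam))
    }
    if (any(d < 0 | d > 1)) {
      return(sprintf("family %s: dosages outside [0, 1]", fam))
    }
  }
  TRUE
})

#' SimTruth: ground truth for the synthetic NAM generator
#'
#' @slot qtl data.frame(marker_id, trait, family_id, effect_sun, effect_shade):
#'   per-family allele-substitution effects of the non-recurrent allele, one
#'   row per (marker, trait, family); a plasticity QTL has unequal sun/shade
#'   effects.
#' @slot pathCoeffs data.frame(from, to, coef_sun, coef_shade): directed
#'   trait-to-trait edges, restricted to the developmental order BD, RB, IG, IB.
#' @slot varComps data.frame(trait, sigma2_G, sigma2_GxE, sigma2_e).
#' @slot treatmentEffects data.frame(trait, intercept, shade_effect).
#' @slot shelfSd numeric(1), standard deviation of shelf (block) effects.
#' @export
setClass("SimTruth", representation(
  qtl = "data.frame", pathCoeffs = "data.frame", varComps = "data.frame",
  treatmentEffects = "data.frame", shelfSd = "numeric"
))

setValidity("SimTruth", function(object) {
  traits <- sarnamTraits()
  pc <- object@pathCoeffs
  if (nrow(pc)) {
    io <- match(pc$from, traits)
    jo <- match(pc$to, traits)
    if (anyNA(io) || anyNA(jo)) return("pathCoeffs traits must be BD/RB/IG/IB")
    if (any(io >= jo)) {
      return("pathCoeffs edges must respect the order BD -> RB -> IG -> IB")
    }
  }
  vc <- object@varComps
  if (!all(c("trait", "sigma2_G", "sigma2_GxE", "sigma2_e") %in% names(vc))) {
    return("varComps must have trait, sigma2_G, sigma2_GxE, sigma2_e")
  }
  if (any(vc$sigma2_G < 0) || any(vc$sigma2_GxE < 0) || any(vc$sigma2_e < 0)) {
    return("variance components must be non-negative")
  }
  if (length(object@shelfSd) != 1 || object@shelfSd < 0) {
    return("shelfSd must be a single non-negative number")
  }
  TRUE
})

#' QtlModel: accepted multi-QTL model for one scan phenotype
#'
#' @slot trait scanned trait (shade-response) name.
#' @slot qtl data.frame(marker_id, chrom, pos_bp, negLog10P, snpPve,
#'   ciLeft, ciRight) in acceptance order.
#' @slot effects data.frame(marker_id, family_id, estimate, se): per-family
#'   allele-substitution effects of each accepted QTL in the final model.
#' @slot threshold genome-wide entry threshold on the -log10 p scale.
#' @slot config the ScanConfig list used.
#' @slot log character vector of decisions taken during the search.
#' @export
setClass("QtlModel", representation(
  trait = "character", qtl = "data.frame", effects = "data.frame",
  threshold = "numeric", config = "list", log = "character"
))

#' PathSpec: a recursive path-model specification
#'
#' @slot traits trait order (developmental time).
#' @slot edges data.frame(from, to): trait-to-trait directed edges, each from
#'   an earlier to a later trait.
#' @slot qtlEdges data.frame(qtl, trait): candidate direct QTL-to-trait edges.
#' @export
setClass("PathSpec", representation(
  traits = "character", edges = "data.frame", qtlEdges = "data.frame"
))

setValidity("PathSpec", function(object) {
  if (nrow(object@edges)) {
    io <- match(object@edges$from, object@traits)
    jo <- match(object@edges$to, object@traits)
    if (anyNA(io) || anyNA(jo)) return("edge traits must be in trait order")
    if (any(io >= jo)) return("edges must point from earlier to later traits")
  }
  if (nrow(object@qtlEdges) &&
      !all(object@qtlEdges$trait %in% object@traits)) {
    return("qtlEdges traits must be in trait order")
  }
  TRUE
})

#' PathFit: fitted multi-group recursive path model
#'
#' @slot spec the \linkS4class{PathSpec} fitted.
#' @slot coefficients data.frame(group, lhs, op, rhs, estimate, se, p):
#'   regression edges ("~") and residual variances ("~~").
#' @slot fitIndices data.frame(group, chisq, df, n, cfi, rmsea, srmr);
#'   includes a pooled "all" row for multi-group fits.
#' @slot vcovs per group, per equation, coefficient covariance matrices.
#' @slot data list of the group data (used by mediation decomposition).
#' @export
setClass("PathFit", representation(
  spec = "PathSpec", coefficients = "data.frame", fitIndices = "data.frame",
  vcovs = "list", data = "list"
))
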