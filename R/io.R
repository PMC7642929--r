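## tabular I/O: TSV with headers throughout; JSON for nested results.
## `columnMapping` arguments accept external layouts: a named character
## vector mapping this package's column names to the file's column names.

.readTsv <- function(path) {
  if (!file.exists(path)) {
    stopWithClass("sarnamFileError", "file not found: %s", path)
  }
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.applyMapping <- function(df, columnMapping, need, path) {
  if (!is.null(columnMapping)) {
    for (ours in names(columnMapping)) {
      theirs <- columnMapping[[ours]]
      if (!theirs %in% names(df)) {
        stopWithClass("sarnamMissingColumn",
          "%s: mapped column '%s' (for '%s') absent", path, theirs, ours)
      }
      names(df)[names(df) == theirs] <- ours
    }
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopWithClass("sarnamMissingColumn", "%s: missing column(s) %s", path,
      paste(miss, collapse = ", "))
  }
  df
}

#' Read and write a genetic map
#'
#' TSV with header marker_id, chrom, pos_bp, pos_cM.
#'
#' @param path file path.
#' @param columnMapping optional named vector mapping package column names to
#'   the file's column names.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path, columnMapping = NULL) {
  df <- .applyMapping(.readTsv(path), columnMapping,
    c("marker_id", "chrom", "pos_bp", "pos_cM"), path)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    bad <- which(diff(sub$pos_cM) <= 0)
    if (length(bad)) {
      stopWithClass("sarnamNonMonotoneMap",
        "%s: pos_cM not increasing at marker %s (chromosome %s)",
        path, sub$marker_id[bad[1] + 1], ch)
    }
  }
  new("GeneticMap", markers = df[
    c("marker_id", "chrom", "pos_bp", "pos_cM")
  ])
}

#' @rdname readGeneticMap
#' @param map a \linkS4class{GeneticMap}.
#' @export
writeGeneticMap <- function(map, path) {
  .writeTsv(markerTable(map), path)
}

#' Read and write NAM genotypes
#'
#' One TSV per family (first column line_id, remaining columns marker
#' dosages) plus a family manifest TSV (family_id, file).
#'
#' @param manifestPath path to the manifest TSV.
#' @param map the shared \linkS4class{GeneticMap}.
#' @return a \linkS4class{NamGenotypes}.
#' @export
readNamGenotypes <- function(manifestPath, map) {
  man <- .applyMapping(.readTsv(manifestPath), NULL, c("family_id", "file"),
    manifestPath)
  base <- dirname(manifestPath)
  ids <- markerTable(map)$marker_id
  dosages <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(base, man$file[i])
    df <- .readTsv(path)
    if (names(df)[1] != "line_id") {
      stopWithClass("sarnamMissingColumn",
        "%s: first column must be line_id", path)
    }
    d <- as.matrix(df[, -1, drop = FALSE])
    rownames(d) <- df$line_id
    miss <- setdiff(ids, colnames(d))
    if (length(miss)) {
      stopWithClass("sarnamMissingColumn", "%s: missing marker column(s) %s",
        path, paste(utils::head(miss, 5), collapse = ", "))
    }
    d <- d[, ids, drop = FALSE]
    bad <- which(d < 0 | d > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      stopWithClass("sarnamDosageRange",
        "%s: dosage %g outside [0, 1] at line %s (row %d), marker %s",
        path, d[bad[1, , drop = FALSE]], rownames(d)[bad[1, 1]],
        bad[1, 1] + 1L, colnames(d)[bad[1, 2]])
    }
    d
  })
  names(dosages) <- man$family_id
  new("NamGenotypes", map = map, dosages = dosages)
}

#' @rdname readNamGenotypes
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param dir output directory (created if needed); the manifest is written
#'   as \code{families.tsv}.
#' @export
writeNamGenotypes <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fams <- familyIds(genotypes)
  files <- sprintf("genotypes_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_", fams))
  for (i in seq_along(fams)) {
    d <- genotypes@dosages[[fams[i]]]
    .writeTsv(data.frame(line_id = rownames(d), d, check.names = FALSE),
      file.path(dir, files[i]))
  }
  .writeTsv(data.frame(family_id = fams, file = files),
    file.path(dir, "families.tsv"))
  invisible(file.path(dir, "families.tsv"))
}

#' Read and write long-format phenotype records
#'
#' @param path file path.
#' @param columnMapping optional column mapping (see
#'   \code{\link{readGeneticMap}}).
#' @return validated phenotype data.frame.
#' @export
readPhenotypes <- function(path, columnMapping = NULL) {
  df <- .applyMapping(.readTsv(path), columnMapping,
    c("line_id", "family_id", "treatment", "shelf", "experiment", "trait",
      "value"), path)
  validatePhenotypes(df)
}

#' @rdname readPhenotypes
#' @param records phenotype data.frame.
#' @export
writePhenotypes <- function(records, path) {
  .writeTsv(validatePhenotypes(records), path)
}

#' Read and write a SimTruth as JSON
#'
#' @param path file path.
#' @return a \linkS4class{SimTruth}.
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  makeSimTruth(
    qtl = as.data.frame(x$qtl), pathCoeffs = as.data.frame(x$pathCoeffs),
    varComps = as.data.frame(x$varComps),
    treatmentEffects = as.data.frame(x$treatmentEffects),
    shelfSd = x$shelfSd
  )
}

#' @rdname readTruth
#' @param truth a \linkS4class{SimTruth}.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(
    list(
      qtl = truth@qtl, pathCoeffs = truth@pathCoeffs,
      varComps = truth@varComps, treatmentEffects = truth@treatmentEffects,
      shelfSd = truth@shelfSd
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a line-effects table (the QTL-scan phenotype file)
#'
#' @param lineEffects data.frame(line_id, family_id, trait, G_effect,
#'   GxE_effect).
#' @param path file path.
#' @export
writeLineEffects <- function(lineEffects, path) .writeTsv(lineEffects, path)

#' @rdname writeLineEffects
#' @param columnMapping optional column mapping.
#' @export
readLineEffects <- function(path, columnMapping = NULL) {
  .applyMapping(.readTsv(path), columnMapping,
    c("line_id", "family_id", "trait", "G_effect", "GxE_effect"), path)
}
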