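#' Pipeline configuration
#'
#' One master seed drives every stage; stage seeds are counter-derived so any
#' stage can be rerun in isolation. Unknown keys are rejected by name.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param families family ids.
#' @param linesPerFamily lines per family.
#' @param nChromosomes,markersPerChromosome,chromLengthCM map dimensions.
#' @param selfingGenerations selfing generations (F8 = 7).
#' @param repsPerLine,nShelves replication structure.
#' @param nPermutations,alpha,maxQtl,backgroundExclusionCM,pruneCorrelation,
#'   dfRule scan settings (see \code{\link{scanConfig}}).
#' @param alphaRetain backward-elimination retention alpha.
#' @param traits trait order.
#' @param transform Box-Cox + z transform traits before the mixed model.
#' @param computeCi compute QTL confidence intervals (slower).
#' @param truth optional \linkS4class{SimTruth}; default \code{demoTruth}.
#' @return named list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(outDir = tempfile("sarnam_run_"), seed = 1L,
                           families = c("Blh-1", "Bur-0", "Cvi-0"),
                           linesPerFamily = 100L, nChromosomes = 2L,
                           markersPerChromosome = 40L, chromLengthCM = 100,
                           selfingGenerations = 7L, repsPerLine = 4L,
                           nShelves = 3L, nPermutations = 100L, alpha = 0.05,
                           maxQtl = 10L, backgroundExclusionCM = 10,
                           pruneCorrelation = 0.99,
                           dfRule = "segregating-families",
                           alphaRetain = 0.01, traits = sarnamTraits(),
                           transform = TRUE, computeCi = TRUE,
                           truth = NULL) {
  structure(
    list(
      outDir = outDir, seed = as.integer(seed), families = families,
      linesPerFamily = linesPerFamily, nChromosomes = nChromosomes,
      markersPerChromosome = markersPerChromosome,
      chromLengthCM = chromLengthCM,
      selfingGenerations = selfingGenerations, repsPerLine = repsPerLine,
      nShelves = nShelves, nPermutations = nPermutations, alpha = alpha,
      maxQtl = maxQtl, backgroundExclusionCM = backgroundExclusionCM,
      pruneCorrelation = pruneCorrelation, dfRule = dfRule,
      alphaRetain = alphaRetain, traits = traits, transform = transform,
      computeCi = computeCi, truth = truth
    ),
    class = "RunConfig"
  )
}

#' Load a pipeline configuration from JSON
#'
#' Unknown keys are rejected with a named error.
#'
#' @param path JSON file.
#' @return a RunConfig.
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stopWithClass("sarnamUnknownConfigKey", "unknown config key(s): %s",
      paste(unknown, collapse = ", "))
  }
  do.call(pipelineConfig, x)
}

.stageSeed <- function(config, stage) {
  childSeed(config$seed, match(stage, c("simulate", "effects", "scan",
    "path")) * 1000L)
}

#' Run the full pipeline: simulate, effects, scan, path
#'
#' Executes every stage on synthetic data with known ground truth and writes
#' each stage's outputs (TSV/JSON) plus a run manifest. Any stage's outputs
#' are re-readable by the package's own readers.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return the run manifest (list), invisibly written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e),
        file.path(config$outDir, paste0(name, ".partial")))
      stopWithClass("sarnamStageFailure", "stage '%s' failed: %s", name,
        conditionMessage(e))
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  ## --- simulate ---------------------------------------------------------
  say("stage simulate")
  sim <- stage("simulate", {
    map <- makeMap(config$nChromosomes, config$markersPerChromosome,
      config$chromLengthCM, seed = .stageSeed(config, "simulate"))
    genotypes <- simulateNam(map, config$families, config$linesPerFamily,
      config$selfingGenerations, seed = .stageSeed(config, "simulate"))
    truth <- if (is.null(config$truth)) {
      demoTruth(map, config$families)
    } else {
      config$truth
    }
    phen <- simulatePhenotypes(genotypes, truth, config$repsPerLine,
      config$nShelves, seed = .stageSeed(config, "simulate") + 1L)
    writeGeneticMap(map, file.path(config$outDir, "map.tsv"))
    writeNamGenotypes(genotypes, file.path(config$outDir, "genotypes"))
    writePhenotypes(phen, file.path(config$outDir, "phenotypes.tsv"))
    writeTruth(truth, file.path(config$outDir, "truth.json"))
    list(map = map, genotypes = genotypes, truth = truth, phen = phen)
  })
  outputs <- c(outputs, "map.tsv", "phenotypes.tsv", "truth.json",
    "genotypes/families.tsv")

  ## --- effects ----------------------------------------------------------
  say("stage effects")
  eff <- stage("effects", {
    fit <- fitAllLineEffects(sim$phen, config$traits, config$transform)
    writeLineEffects(fit$lineEffects,
      file.path(config$outDir, "line_effects.tsv"))
    vcOut <- lapply(fit$varComps, function(v) {
      v$fixedEffects <- NULL
      v
    })
    jsonlite::write_json(vcOut,
      file.path(config$outDir, "variance_components.json"),
      auto_unbox = TRUE, digits = NA
    )
    fit
  })
  outputs <- c(outputs, "line_effects.tsv", "variance_components.json")

  ## --- scan -------------------------------------------------------------
  say("stage scan")
  scanRes <- stage("scan", {
    sc <- scanConfig(
      backgroundExclusionCM = config$backgroundExclusionCM,
      pruneCorrelation = config$pruneCorrelation,
      nPermutations = config$nPermutations, alpha = config$alpha,
      dfRule = config$dfRule, maxQtl = config$maxQtl,
      seed = .stageSeed(config, "scan")
    )
    pruned <- pruneMarkers(sim$genotypes, config$pruneCorrelation)
    models <- list()
    for (tr in config$traits) {
      le <- eff$lineEffects[eff$lineEffects$trait == tr, ]
      phenotype <- setNames(le$GxE_effect, le$line_id)
      model <- stepwiseScan(phenotype, sim$genotypes, sc, markers = pruned,
        trait = paste0(tr, "_SAR"))
      if (config$computeCi && nrow(qtlTable(model))) {
        model <- addConfidenceIntervals(model, phenotype, sim$genotypes, sc)
      }
      models[[tr]] <- model
      profile <- scanJoint(phenotype, sim$genotypes, sc, markers = pruned)
      .writeTsv(profile,
        file.path(config$outDir, sprintf("scan_profile_%s.tsv", tr)))
    }
    qtlTab <- do.call(rbind, lapply(models, function(m) {
      q <- qtlTable(m)
      if (!nrow(q)) return(NULL)
      data.frame(
        Trait = m@trait,
        QTL = sprintf("%s%d_%d", m@trait, q$chrom, seq_len(nrow(q))),
        `SNP PVE` = round(q$snpPve, 2), `QTL Marker` = q$marker_id,
        Chromosome = q$chrom, `Left Bound` = q$ciLeft,
        `Right Bound` = q$ciRight, check.names = FALSE
      )
    }))
    if (is.null(qtlTab)) {
      qtlTab <- data.frame(
        Trait = character(), QTL = character(), `SNP PVE` = numeric(),
        `QTL Marker` = character(), Chromosome = integer(),
        `Left Bound` = character(), `Right Bound` = character(),
        check.names = FALSE
      )
    }
    .writeTsv(qtlTab, file.path(config$outDir, "qtl_table.tsv"))
    jsonlite::write_json(
      list(
        dfRule = config$dfRule, alpha = config$alpha,
        nPermutations = config$nPermutations,
        thresholds = lapply(models, function(m) m@threshold),
        logs = lapply(models, function(m) m@log)
      ),
      file.path(config$outDir, "scan_manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    list(models = models, pruned = pruned, qtlTab = qtlTab)
  })
  outputs <- c(outputs, "qtl_table.tsv", "scan_manifest.json",
    sprintf("scan_profile_%s.tsv", config$traits))

  ## --- path -------------------------------------------------------------
  say("stage path")
  pathRes <- stage("path", {
    regions <- mergeOverlappingQtl(scanRes$models, sim$map)
    decomp <- NULL
    coefTab <- NULL
    fitTab <- NULL
    if (nrow(regions)) {
      qtlMarkers <- unique(regions$marker_id)
      agg <- stats::aggregate(
        value ~ line_id + family_id + treatment + trait, sim$phen, mean
      )
      for (fam in config$families) {
        sub <- agg[agg$family_id == fam, ]
        wide <- stats::reshape(
          sub[c("line_id", "treatment", "trait", "value")],
          idvar = c("line_id", "treatment"), timevar = "trait",
          direction = "wide"
        )
        names(wide) <- sub("^value\\.", "", names(wide))
        G <- dosageMatrix(sim$genotypes, fam)
        for (qm in qtlMarkers) wide[[qm]] <- G[wide$line_id, qm]
        seg <- qtlMarkers[vapply(qtlMarkers,
          function(qm) sd(wide[[qm]]) > 1e-9, logical(1))]
        spec <- pathSpec(seg, config$traits)
        dataSun <- wide[wide$treatment == "sun", ]
        dataShade <- wide[wide$treatment == "shade", ]
        red <- tryCatch(
          backwardEliminate(spec, dataSun, dataShade, config$alphaRetain),
          sarnamInvalidArgument = function(e) NULL
        )
        if (is.null(red)) {
          say("path: family %s skipped (%s)", fam, "too few complete cases")
          next
        }
        co <- pathCoefficients(red$fit)
        co$family_id <- fam
        coefTab <- rbind(coefTab, co)
        fi <- fitIndices(red$fit)
        fi$family_id <- fam
        fitTab <- rbind(fitTab, fi)
        for (qm in seg) {
          for (tr in config$traits) {
            d <- decomposeEffects(red$fit, qm, tr)
            d$family_id <- fam
            decomp <- rbind(decomp, d)
          }
        }
      }
      .writeTsv(coefTab, file.path(config$outDir, "path_coefficients.tsv"))
      .writeTsv(decomp, file.path(config$outDir, "effect_decomposition.tsv"))
      jsonlite::write_json(fitTab,
        file.path(config$outDir, "path_fit_indices.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
    }
    list(regions = regions, decomposition = decomp, coefficients = coefTab,
      fitIndices = fitTab)
  })
  if (nrow(pathRes$regions)) {
    outputs <- c(outputs, "path_coefficients.tsv",
      "effect_decomposition.tsv", "path_fit_indices.json")
  }

  ## --- manifest ---------------------------------------------------------
  cfgForHash <- config
  cfgForHash$truth <- NULL
  cfgForHash$outDir <- NULL # hash the analysis settings, not the destination
  cfgJson <- jsonlite::toJSON(unclass(cfgForHash), auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfgJson), tmp)
  manifest <- list(
    package = "sarnam",
    version = as.character(packageVersion("sarnam")),
    configHash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    stageSeeds = vapply(c("simulate", "effects", "scan", "path"),
      function(s) .stageSeed(config, s), integer(1)),
    timings = as.list(timings),
    outputs = lapply(setNames(outputs, outputs), function(f) {
      unname(tools::md5sum(file.path(config$outDir, f)))
    })
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  say("pipeline complete: %s", config$outDir)
  invisible(manifest)
}
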