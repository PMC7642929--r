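#' Build a genetic map
#'
#' Markers are evenly spaced in cM on each chromosome (optionally jittered)
#' and physical positions follow at a fixed bp-per-cM rate. Marker ids encode
#' chromosome and bp position as \code{m_<chr>_<bp>}.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param markersPerChromosome markers per chromosome (>= 2).
#' @param chromLengthCM chromosome length in centimorgans.
#' @param seed integer seed (only consumed when \code{jitter = TRUE}).
#' @param jitter if TRUE, perturb interior marker positions uniformly within
#'   half an inter-marker interval.
#' @param bpPerCM physical distance per cM (default 250 kb).
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' makeMap(1, 2, 50)
#' @export
makeMap <- function(nChromosomes, markersPerChromosome, chromLengthCM,
                    seed = 1L, jitter = FALSE, bpPerCM = 250000) {
  if (nChromosomes < 1 || markersPerChromosome < 2 || chromLengthCM <= 0) {
    invalidArg("map dimensions must be positive (>= 2 markers/chromosome)")
  }
  rows <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nChromosomes), function(ch) {
      cm <- seq(0, chromLengthCM, length.out = markersPerChromosome)
      if (jitter && markersPerChromosome > 2) {
        step <- chromLengthCM / (markersPerChromosome - 1)
        mid <- seq_len(markersPerChromosome - 2) + 1
        cm[mid] <- cm[mid] + runif(length(mid), -step / 2.5, step / 2.5)
        cm <- sort(cm)
      }
      bp <- as.integer(round(cm * bpPerCM)) + 1L # 1-based physical coords
      data.frame(
        marker_id = sprintf("m_%d_%d", ch, bp),
        chrom = ch, pos_bp = bp, pos_cM = cm
      )
    }))
  })
  new("GeneticMap", markers = rows)
}

#' Simulate one RIL family's genotypes
#'
#' Genotypes are simulated directly at the selfed-RIL limit: along each
#' chromosome the non-recurrent-allele indicator follows a Markov chain whose
#' adjacent-marker switch probability is the Haldane-Waddington expansion
#' R = 2r/(1+2r) of the per-meiosis recombination fraction r (Haldane map by
#' default; Kosambi optional). Residual heterozygosity from finite selfing is
#' injected per locus at rate (1/2)^(selfingGenerations - 1) and recorded as
#' dosage 0.5.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param nLines number of lines (>= 1).
#' @param selfingGenerations number of selfing generations (F8 = 7).
#' @param seed integer seed.
#' @param mapFunction "haldane" (default) or "kosambi".
#' @param linePrefix prefix for generated line ids.
#' @return numeric matrix lines x markers of allele dosages.
#' @export
simulateFamily <- function(map, nLines, selfingGenerations = 7L, seed = 1L,
                           mapFunction = c("haldane", "kosambi"),
                           linePrefix = "L") {
  if (nLines < 1 || selfingGenerations < 1) {
    invalidArg("nLines and selfingGenerations must be >= 1")
  }
  mapFunction <- match.arg(mapFunction)
  rfun <- if (mapFunction == "haldane") haldaneR else kosambiR
  m <- markerTable(map)
  ## F1 is fully heterozygous; each selfing generation halves the rate,
  ## so after g selfings (F8 <=> g = 7) the per-locus rate is (1/2)^g
  hetRate <- 0.5^selfingGenerations
  withSeed(seed, {
    G <- matrix(0, nLines, nrow(m),
      dimnames = list(
        sprintf("%s%04d", linePrefix, seq_len(nLines)), m$marker_id
      )
    )
    for (ch in unique(m$chrom)) {
      idx <- which(m$chrom == ch)
      d <- diff(m$pos_cM[idx])
      if (any(d < 0)) stopWithClass(
        "sarnamInternalError", "markers out of map order on chromosome %s", ch
      )
      R <- rilRecombFraction(rfun(d))
      g <- matrix(0L, nLines, length(idx))
      g[, 1] <- rbinom(nLines, 1, 0.5)
      for (j in seq_along(R)) {
        flip <- rbinom(nLines, 1, R[j]) == 1L
        g[, j + 1] <- ifelse(flip, 1L - g[, j], g[, j])
      }
      G[, idx] <- g
    }
    het <- matrix(runif(length(G)) < hetRate, nrow(G), ncol(G))
    G[het] <- 0.5
    G
  })
}

#' Simulate a NAM genotype panel
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param families character vector of family ids (non-recurrent parents);
#'   defaults to the seven classic donors.
#' @param linesPerFamily lines per family, recycled across families.
#' @param selfingGenerations selfing generations (F8 = 7).
#' @param seed integer master seed; per-family seeds are counter-derived.
#' @param mapFunction map function passed to \code{\link{simulateFamily}}.
#' @return a \linkS4class{NamGenotypes}.
#' @export
simulateNam <- function(map, families = namFamilies(), linesPerFamily = 165L,
                        selfingGenerations = 7L, seed = 1L,
                        mapFunction = "haldane") {
  linesPerFamily <- rep_len(linesPerFamily, length(families))
  dosages <- lapply(seq_along(families), function(i) {
    simulateFamily(map, linesPerFamily[i], selfingGenerations,
      seed = childSeed(seed, i), mapFunction = mapFunction,
      linePrefix = sprintf("%s_", families[i])
    )
  })
  names(dosages) <- families
  new("NamGenotypes", map = map, dosages = dosages)
}

#' The seven NAM donor parents (Col-0 recurrent)
#' @return character vector of family ids.
#' @export
namFamilies <- function() {
  c("Blh-1", "Bur-0", "Cvi-0", "Ita-0", "Jea", "Oy-0", "Sha")
}

#' Construct a SimTruth object
#'
#' @param qtl data.frame(marker_id, trait, family_id, effect_sun,
#'   effect_shade); zero rows allowed.
#' @param pathCoeffs data.frame(from, to, coef_sun, coef_shade).
#' @param varComps data.frame(trait, sigma2_G, sigma2_GxE, sigma2_e).
#' @param treatmentEffects data.frame(trait, intercept, shade_effect).
#' @param shelfSd standard deviation of shelf (block) effects.
#' @return a \linkS4class{SimTruth}.
#' @export
makeSimTruth <- function(qtl = NULL, pathCoeffs = NULL, varComps,
                         treatmentEffects, shelfSd = 0.1) {
  if (is.null(qtl)) {
    qtl <- data.frame(
      marker_id = character(), trait = character(), family_id = character(),
      effect_sun = numeric(), effect_shade = numeric()
    )
  }
  if (is.null(pathCoeffs)) {
    pathCoeffs <- data.frame(
      from = character(), to = character(),
      coef_sun = numeric(), coef_shade = numeric()
    )
  }
  new("SimTruth",
    qtl = qtl, pathCoeffs = pathCoeffs, varComps = varComps,
    treatmentEffects = treatmentEffects, shelfSd = shelfSd
  )
}

#' Default demonstration truth for the four shade-avoidance traits
#'
#' Treatment main effects follow the reported population-level shade
#' responses of the four traits on the transformed scale (BD -0.58, IG +0.27,
#' RB -0.78, IB -0.15 sd); intercepts likewise. Variance components and path
#' coefficients are package defaults chosen to give moderate heritability and
#' a clear developmental cascade; two planted QTL give each downstream stage
#' a recovery target: a plasticity QTL on BD with an allelic series across
#' families, and a direct RB QTL.
#'
#' @param map a \linkS4class{GeneticMap} (QTL markers are picked from it).
#' @param families family ids the per-family effects are generated for.
#' @return a \linkS4class{SimTruth}.
#' @export
demoTruth <- function(map, families = namFamilies()) {
  m <- markerTable(map)
  nf <- length(families)
  ## BD plasticity QTL: allelic series, effect only in shade
  q1 <- m$marker_id[ceiling(nrow(m) * 0.25)]
  ## RB QTL with equal effect in both environments (no plasticity)
  q2 <- m$marker_id[ceiling(nrow(m) * 0.75)]
  series <- rep_len(c(0.5, 0.25, 0, -0.25, 0.5, 0, 0.25), nf)
  qtl <- rbind(
    data.frame(
      marker_id = q1, trait = "BD", family_id = families,
      effect_sun = 0, effect_shade = series
    ),
    data.frame(
      marker_id = q2, trait = "RB", family_id = families,
      effect_sun = 0.4, effect_shade = 0.4
    )
  )
  pathCoeffs <- data.frame(
    from = c("BD", "BD", "RB", "IG"),
    to = c("RB", "IG", "IB", "IB"),
    coef_sun = c(0.4, -0.3, 0.5, 0.3),
    coef_shade = c(0.6, -0.4, 0.5, 0.3)
  )
  varComps <- data.frame(
    trait = sarnamTraits(),
    sigma2_G = c(0.4, 0.3, 0.25, 0.25),
    sigma2_GxE = c(0.05, 0.05, 0.05, 0.08),
    sigma2_e = c(0.5, 0.6, 0.6, 0.6)
  )
  treatmentEffects <- data.frame(
    trait = sarnamTraits(),
    intercept = c(0.57, 0.86, 0.02, 0.38),
    shade_effect = c(-0.58, -0.78, 0.27, -0.15)
  )
  makeSimTruth(qtl, pathCoeffs, varComps, treatmentEffects, shelfSd = 0.1)
}

#' Simulate phenotype records from a NAM panel and a truth object
#'
#' Latent trait values are built per line and environment in developmental
#' order (BD, RB, IG, IB): treatment main effect + QTL direct effects x
#' dosage + path-transmitted contributions from earlier latent traits + a
#' line-level deviation (shared genetic component with variance sigma2_G plus
#' an independent per-environment component with variance sigma2_GxE,
#' matching the RIL and RIL:TRT random effects of the downstream mixed
#' model). Observed replicates add a shelf (block) effect and residual noise
#' with variance sigma2_e.
#'
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param truth a \linkS4class{SimTruth}.
#' @param repsPerLine replicates per line per treatment.
#' @param nShelves shelves (blocks) per treatment.
#' @param seed integer seed.
#' @param nExperiments experiments; shelves are nested in experiments.
#' @return long-format data.frame(line_id, family_id, treatment, shelf,
#'   experiment, trait, value).
#' @export
simulatePhenotypes <- function(genotypes, truth, repsPerLine = 4L,
                               nShelves = 3L, seed = 1L, nExperiments = 1L) {
  traits <- sarnamTraits()
  pc <- truth@pathCoeffs
  if (nrow(pc)) {
    io <- match(pc$from, traits)
    jo <- match(pc$to, traits)
    if (any(io >= jo)) invalidArg("cyclic or out-of-order path specification")
  }
  mt <- markerTable(genotypes)
  if (nrow(truth@qtl) && !all(truth@qtl$marker_id %in% mt$marker_id)) {
    invalidArg(
      "truth references markers absent from the map: %s",
      paste(setdiff(truth@qtl$marker_id, mt$marker_id), collapse = ", ")
    )
  }
  if (!all(truth@qtl$trait %in% traits) ||
      !all(truth@varComps$trait %in% traits)) {
    invalidArg("truth references unknown traits")
  }
  vc <- truth@varComps[match(traits, truth@varComps$trait), ]
  te <- truth@treatmentEffects[
    match(traits, truth@treatmentEffects$trait),
  ]
  envs <- c("sun", "shade")
  withSeed(seed, {
    shelfEff <- matrix(
      rnorm(2 * nShelves * nExperiments, 0, truth@shelfSd),
      nrow = 2, dimnames = list(envs, NULL)
    )
    out <- vector("list", length(genotypes@dosages))
    for (f in seq_along(genotypes@dosages)) {
      fam <- names(genotypes@dosages)[f]
      G <- genotypes@dosages[[f]]
      n <- nrow(G)
      ## latent[line, trait, env]
      latent <- array(0, c(n, length(traits), 2),
        dimnames = list(rownames(G), traits, envs)
      )
      for (t in seq_along(traits)) {
        tr <- traits[t]
        g <- rnorm(n, 0, sqrt(vc$sigma2_G[t]))
        for (e in 1:2) {
          ge <- rnorm(n, 0, sqrt(vc$sigma2_GxE[t]))
          val <- te$intercept[t] +
            (if (envs[e] == "shade") te$shade_effect[t] else 0) + g + ge
          qrows <- truth@qtl[
            truth@qtl$trait == tr & truth@qtl$family_id == fam, ,
            drop = FALSE
          ]
          if (nrow(qrows)) {
            eff <- if (envs[e] == "shade") qrows$effect_shade else
              qrows$effect_sun
            val <- val + drop(G[, qrows$marker_id, drop = FALSE] %*% eff)
          }
          prows <- pc[pc$to == tr, , drop = FALSE]
          if (nrow(prows)) {
            co <- if (envs[e] == "shade") prows$coef_shade else prows$coef_sun
            up <- matrix(latent[, prows$from, e], nrow = n)
            val <- val + drop(up %*% co)
          }
          latent[, t, e] <- val
        }
      }
      recs <- expand.grid(
        rep = seq_len(repsPerLine), line = seq_len(n),
        env = 1:2, trait = seq_along(traits),
        KEEP.OUT.ATTRS = FALSE
      )
      shelfIdx <- ((recs$rep + recs$line - 2L) %% (nShelves * nExperiments)) +
        1L
      experiment <- ((shelfIdx - 1L) %/% nShelves) + 1L
      shelf <- ((shelfIdx - 1L) %% nShelves) + 1L
      value <- latent[cbind(recs$line, recs$trait, recs$env)] +
        shelfEff[cbind(recs$env, shelfIdx)] +
        rnorm(nrow(recs), 0, rep(sqrt(vc$sigma2_e), each = 1)[recs$trait])
      out[[f]] <- data.frame(
        line_id = rownames(G)[recs$line], family_id = fam,
        treatment = envs[recs$env], shelf = shelf, experiment = experiment,
        trait = traits[recs$trait], value = value
      )
    }
    do.call(rbind, out)
  })
}

#' Validate a long-format phenotype table
#'
#' @param records data.frame as produced by \code{\link{simulatePhenotypes}}.
#' @return invisibly, the records.
#' @export
validatePhenotypes <- function(records) {
  need <- c(
    "line_id", "family_id", "treatment", "shelf", "experiment",
    "trait", "value"
  )
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stopWithClass(
      "sarnamMissingColumn", "phenotype table lacks column(s): %s",
      paste(miss, collapse = ", ")
    )
  }
  bad <- setdiff(unique(records$treatment), c("sun", "shade"))
  if (length(bad)) {
    stopWithClass(
      "sarnamUnknownTreatment", "unknown treatment label(s): %s",
      paste(bad, collapse = ", ")
    )
  }
  invisible(records)
}
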