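#' Configuration for QTL scans
#'
#' @param backgroundExclusionCM half-width (cM) of the window around the test
#'   marker excluded from the background kinship (default 10, as in the
#'   source protocol).
#' @param pruneCorrelation adjacent-marker correlation above which the later
#'   marker is dropped when building the scan set (default 0.99).
#' @param nPermutations permutations for the genome-wide threshold
#'   (default 1000).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param dfRule degrees of freedom of the joint chi-square test:
#'   \code{"segregating-families"} (default; df = number of families where
#'   the test marker segregates) or \code{"fixed:<k>"} (e.g. "fixed:6" to
#'   mirror the 6-df convention used with 7 families).
#' @param maxQtl maximum QTL accepted by the stepwise search.
#' @param h2Grid grid of variance ratios h2 = tau2/(tau2 + sigma2) profiled
#'   in the background LMM.
#' @param seed master seed for permutations (child seeds counter-derived).
#' @param ciAlpha alpha for the confidence-interval rule (nominal 0.05 by
#'   default; set to the permutation threshold's p if preferred).
#' @return a validated list of class \code{ScanConfig}.
#' @export
scanConfig <- function(backgroundExclusionCM = 10, pruneCorrelation = 0.99,
                       nPermutations = 1000L, alpha = 0.05,
                       dfRule = "segregating-families", maxQtl = 10L,
                       h2Grid = seq(0, 0.95, by = 0.05), seed = 1L,
                       ciAlpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) invalidArg("alpha must be in (0, 1)")
  if (pruneCorrelation <= 0 || pruneCorrelation > 1) {
    invalidArg("pruneCorrelation must be in (0, 1]")
  }
  if (!identical(dfRule, "segregating-families") &&
      !grepl("^fixed:[0-9]+$", dfRule)) {
    invalidArg("dfRule must be 'segregating-families' or 'fixed:<k>'")
  }
  structure(
    list(
      backgroundExclusionCM = backgroundExclusionCM,
      pruneCorrelation = pruneCorrelation,
      nPermutations = as.integer(nPermutations), alpha = alpha,
      dfRule = dfRule, maxQtl = as.integer(maxQtl), h2Grid = h2Grid,
      seed = as.integer(seed), ciAlpha = ciAlpha
    ),
    class = "ScanConfig"
  )
}

#' Prune highly correlated adjacent markers
#'
#' Walks each chromosome in map order and drops the later member of any
#' retained adjacent pair whose pooled-across-families dosage correlation
#' exceeds the threshold (dosages are centred within family before pooling so
#' family structure does not inflate the correlation). The result is
#' idempotent: re-pruning a pruned set changes nothing.
#'
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param threshold correlation threshold (default 0.99).
#' @return character vector of retained marker ids, in map order.
#' @export
pruneMarkers <- function(genotypes, threshold = 0.99) {
  m <- markerTable(genotypes)
  if (nrow(m) < 2) return(m$marker_id)
  pooled <- do.call(rbind, lapply(genotypes@dosages, function(d) {
    sweep(d, 2, colMeans(d))
  }))
  keep <- logical(nrow(m))
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    last <- idx[1]
    keep[last] <- TRUE
    for (j in idx[-1]) {
      r <- suppressWarnings(cor(pooled[, last], pooled[, j]))
      if (is.na(r) || abs(r) <= threshold) {
        keep[j] <- TRUE
        last <- j
      }
    }
  }
  m$marker_id[keep]
}

## kinship from all markers farther than exclCM from marker j (other
## chromosomes always retained); K = ZZ'/m over centred dosages
.kinshipExcluding <- function(G, mapdf, j, exclCM) {
  keep <- mapdf$chrom != mapdf$chrom[j] |
    abs(mapdf$pos_cM - mapdf$pos_cM[j]) > exclCM
  keep[j] <- FALSE
  if (!any(keep)) {
    degenerateInput("no markers remain after %g cM exclusion", exclCM)
  }
  Z <- sweep(G[, keep, drop = FALSE], 2, colMeans(G[, keep, drop = FALSE]))
  tcrossprod(Z) / sum(keep)
}

#' Background kinship matrices around a test marker
#'
#' Per family, the genomic-relationship matrix built from centred dosages of
#' all markers farther than \code{exclusionCM} from the test marker; only the
#' window on the test chromosome is removed, all other chromosomes are kept.
#'
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param testMarker marker id.
#' @param exclusionCM exclusion half-width in cM (default 10).
#' @return named list of symmetric PSD matrices, one per family.
#' @export
backgroundModel <- function(genotypes, testMarker, exclusionCM = 10) {
  m <- markerTable(genotypes)
  j <- match(testMarker, m$marker_id)
  if (is.na(j)) keyingError("test marker '%s' not in map", testMarker)
  lapply(genotypes@dosages, .kinshipExcluding, mapdf = m, j = j,
    exclCM = exclusionCM)
}

## profile the variance ratio on a grid for one family and one test marker.
## Yr, X0r, x1r are eigen-rotated; returns per-column max log-likelihoods of
## null (without marker) and full models plus marker effect/se at the best h2.
.profileFamily <- function(Yr, X0r, x1r, dvals, grid, wantEffects) {
  n <- nrow(Yr)
  P <- ncol(Yr)
  bestN <- rep(-Inf, P)
  bestF <- rep(-Inf, P)
  beta <- se <- rep(NA_real_, P)
  for (h2 in grid) {
    v <- h2 * dvals + (1 - h2)
    sw <- 1 / sqrt(v)
    Yw <- Yr * sw
    X0w <- X0r * sw
    cst <- -0.5 * sum(log(v)) - n / 2 * (log(2 * pi) + 1)
    yss <- colSums(Yw^2)
    q0 <- qr(X0w)
    f0 <- qr.qty(q0, Yw)[seq_len(q0$rank), , drop = FALSE]
    rss0 <- pmax(yss - colSums(f0^2), 1e-12)
    ll0 <- cst - n / 2 * log(rss0 / n)
    X1w <- cbind(X0w, x1r * sw)
    q1 <- qr(X1w)
    f1 <- qr.qty(q1, Yw)[seq_len(q1$rank), , drop = FALSE]
    rss1 <- pmax(yss - colSums(f1^2), 1e-12)
    ll1 <- cst - n / 2 * log(rss1 / n)
    bestN <- pmax(bestN, ll0)
    upd <- ll1 > bestF
    if (wantEffects && any(upd) && q1$rank == ncol(X1w)) {
      cf <- qr.coef(q1, Yw[, upd, drop = FALSE])
      xtxi <- tryCatch(solve(crossprod(X1w))[ncol(X1w), ncol(X1w)],
        error = function(e) NA_real_)
      beta[upd] <- cf[ncol(X1w), ]
      se[upd] <- sqrt(rss1[upd] / n * xtxi)
    }
    bestF <- pmax(bestF, ll1)
  }
  list(lr = 2 * pmax(bestF - bestN, 0), beta = beta, se = se)
}

.jointDf <- function(segCounts, dfRule) {
  if (identical(dfRule, "segregating-families")) {
    segCounts
  } else {
    rep(as.integer(sub("^fixed:", "", dfRule)), length(segCounts))
  }
}

.negLog10FromLr <- function(lr, df) {
  out <- numeric(length(lr))
  pos <- df > 0
  out[pos] <- -pchisq(lr[pos], df[pos], lower.tail = FALSE, log.p = TRUE) /
    log(10)
  out
}

## core scan over a phenotype matrix. Y: lines x P with rownames covering all
## genotype lines. Returns per-marker joint statistics for every column.
.scanCore <- function(Y, genotypes, config, currentQtl = character(),
                      covariates = NULL, markers = NULL,
                      wantEffects = FALSE, bgCache = NULL) {
  m <- markerTable(genotypes)
  if (is.null(markers)) markers <- m$marker_id
  testIdx <- match(markers, m$marker_id)
  if (anyNA(testIdx)) {
    keyingError("markers not in map: %s",
      paste(markers[is.na(testIdx)], collapse = ", "))
  }
  fams <- familyIds(genotypes)
  P <- ncol(Y)
  M <- length(markers)
  lrFam <- array(0, c(M, P, length(fams)))
  segMat <- matrix(FALSE, M, length(fams))
  effFam <- seFam <- if (wantEffects) {
    array(NA_real_, c(M, P, length(fams)))
  } else {
    NULL
  }
  if (is.null(bgCache)) bgCache <- new.env(parent = emptyenv())
  for (f in seq_along(fams)) {
    G <- genotypes@dosages[[fams[f]]]
    miss <- setdiff(rownames(G), rownames(Y))
    if (length(miss)) {
      keyingError("family %s lines missing from phenotype: %s", fams[f],
        paste(utils::head(miss, 5), collapse = ", "))
    }
    Yf <- Y[rownames(G), , drop = FALSE]
    ok <- rowSums(is.na(Yf)) == 0
    Yf <- Yf[ok, , drop = FALSE]
    Gf <- G[ok, , drop = FALSE]
    Xbase <- cbind(`(Intercept)` = rep(1, nrow(Gf)))
    if (length(currentQtl)) {
      Xbase <- cbind(Xbase, Gf[, currentQtl, drop = FALSE])
    }
    if (!is.null(covariates)) {
      cmiss <- setdiff(rownames(Gf), rownames(covariates))
      if (length(cmiss)) {
        keyingError("covariate rows missing for lines: %s",
          paste(utils::head(cmiss, 5), collapse = ", "))
      }
      Xbase <- cbind(Xbase, covariates[rownames(Gf), , drop = FALSE])
    }
    for (k in seq_len(M)) {
      j <- testIdx[k]
      x <- Gf[, j]
      if (sd(x) < 1e-9) next # monomorphic in this family: LR 0, no df
      segMat[k, f] <- TRUE
      key <- paste(fams[f], j, sep = ":")
      if (is.null(bgCache[[key]])) {
        K <- .kinshipExcluding(Gf, m, j, config$backgroundExclusionCM)
        eig <- eigen(K, symmetric = TRUE)
        bgCache[[key]] <- list(U = eig$vectors, d = pmax(eig$values, 0))
      }
      bg <- bgCache[[key]]
      pr <- .profileFamily(
        crossprod(bg$U, Yf), crossprod(bg$U, Xbase),
        drop(crossprod(bg$U, x)), bg$d, config$h2Grid, wantEffects
      )
      lrFam[k, , f] <- pr$lr
      if (wantEffects) {
        effFam[k, , f] <- pr$beta
        seFam[k, , f] <- pr$se
      }
    }
  }
  jointLR <- rowSums(lrFam, dims = 2)
  df <- .jointDf(rowSums(segMat), config$dfRule)
  negLog10P <- matrix(
    .negLog10FromLr(jointLR, rep(df, P)), M, P
  )
  list(
    markers = markers, chrom = m$chrom[testIdx], pos_bp = m$pos_bp[testIdx],
    pos_cM = m$pos_cM[testIdx], families = fams, lrFam = lrFam,
    segMat = segMat, jointLR = jointLR, df = df, negLog10P = negLog10P,
    effFam = effFam, seFam = seFam, bgCache = bgCache
  )
}

#' Joint multi-family QTL scan
#'
#' Per family, fits a Haley-Knott linear mixed model at each test marker:
#' fixed effects are intercept, any conditioning (current QTL) dosages and
#' optional line-level covariates, plus the test-marker dosage; the random
#' effect has covariance tau2 K + sigma2 I with K the background kinship
#' excluding the window around the test marker, and the variance ratio
#' profiled on a fixed grid. The family likelihood-ratio compares the full
#' model to the null omitting only the test marker; the joint LR sums family
#' LRs and is referred to a chi-square whose df follows the configured rule
#' (families where the marker is monomorphic contribute zero LR and, under
#' the default rule, no df).
#'
#' @param phenotype named numeric vector, one value per line.
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param config a \code{\link{scanConfig}}.
#' @param currentQtl marker ids conditioned on as fixed effects.
#' @param covariates optional numeric matrix of line-level covariates
#'   (rownames = line ids), e.g. earlier-trait effects for path scans.
#' @param markers marker ids to test (default: all; typically the pruned set).
#' @return data.frame with one row per tested marker: marker_id, chrom,
#'   pos_bp, per-family effect/se/LR columns, jointLR, df, negLog10P.
#' @export
scanJoint <- function(phenotype, genotypes, config = scanConfig(),
                      currentQtl = character(), covariates = NULL,
                      markers = NULL) {
  Y <- matrix(phenotype, ncol = 1, dimnames = list(names(phenotype), NULL))
  sc <- .scanCore(Y, genotypes, config, currentQtl, covariates, markers,
    wantEffects = TRUE)
  out <- data.frame(
    marker_id = sc$markers, chrom = sc$chrom, pos_bp = sc$pos_bp
  )
  for (f in seq_along(sc$families)) {
    fam <- sc$families[f]
    out[[paste0("eff_", fam)]] <- sc$effFam[, 1, f]
    out[[paste0("se_", fam)]] <- sc$seFam[, 1, f]
    out[[paste0("lr_", fam)]] <- sc$lrFam[, 1, f]
  }
  out$jointLR <- sc$jointLR[, 1]
  out$df <- sc$df
  out$negLog10P <- sc$negLog10P[, 1]
  out
}

## permute phenotype values within each family; returns a lines x nPerm matrix
.permutedPhenotypeMatrix <- function(phenotype, genotypes, nPerm, seed) {
  fams <- familyIds(genotypes)
  Y <- matrix(NA_real_, length(phenotype), nPerm,
    dimnames = list(names(phenotype), NULL))
  for (i in seq_len(nPerm)) {
    withSeed(childSeed(seed, i), {
      for (fam in fams) {
        ln <- rownames(genotypes@dosages[[fam]])
        Y[ln, i] <- phenotype[sample(ln)]
      }
    })
  }
  Y
}

#' Genome-wide permutation threshold
#'
#' Shuffles the line-to-genotype assignment independently within each family
#' (phenotypes fixed), rescans all markers per permutation, records the
#' maximum -log10 p, and returns the empirical (1 - alpha) quantile (type-7
#' interpolation). Permutation seeds are counter-derived from the config
#' master seed, so thresholds are reproducible.
#'
#' When phenotype-side covariates are supplied they are shuffled jointly with
#' the phenotype (the permutation reassigns whole lines to genotypes).
#'
#' @inheritParams scanJoint
#' @param returnMaxima if TRUE, return the per-permutation maxima as an
#'   attribute.
#' @return threshold on the -log10 p scale.
#' @export
permutationThreshold <- function(phenotype, genotypes, config = scanConfig(),
                                 currentQtl = character(), covariates = NULL,
                                 markers = NULL, returnMaxima = FALSE) {
  if (config$nPermutations < 100) {
    invalidArg("need >= 100 permutations for a usable threshold")
  }
  if (is.null(covariates)) {
    Y <- .permutedPhenotypeMatrix(phenotype, genotypes,
      config$nPermutations, config$seed)
    sc <- .scanCore(Y, genotypes, config, currentQtl, NULL, markers)
    maxima <- apply(sc$negLog10P, 2, max)
  } else {
    maxima <- vapply(seq_len(config$nPermutations), function(i) {
      permNames <- names(phenotype)
      withSeed(childSeed(config$seed, i), {
        for (fam in familyIds(genotypes)) {
          ln <- rownames(genotypes@dosages[[fam]])
          permNames[match(ln, names(phenotype))] <- sample(ln)
        }
      })
      yp <- setNames(phenotype, permNames)
      cp <- covariates
      rownames(cp) <- permNames[match(rownames(covariates),
        names(phenotype))]
      max(scanJoint(yp, genotypes, config, currentQtl, cp,
        markers)$negLog10P)
    }, numeric(1))
  }
  thr <- unname(quantile(maxima, 1 - config$alpha, type = 7))
  if (returnMaxima) attr(thr, "maxima") <- maxima
  thr
}

#' Forward-stepwise multi-QTL search
#'
#' Repeatedly scans the marker set conditioning on the accepted QTL and adds
#' the marker with the largest -log10 p exceeding the entry threshold (ties
#' broken toward the lower chromosome/bp), until nothing exceeds the
#' threshold or \code{maxQtl} is reached. Per-family effects of each accepted
#' QTL are re-estimated conditioning on the other accepted QTL, and each
#' QTL's SNP PVE is the incremental variance it explains relative to the
#' total phenotypic variance of the scan phenotype.
#'
#' @inheritParams scanJoint
#' @param threshold entry threshold on the -log10 p scale; computed by
#'   \code{\link{permutationThreshold}} when NULL.
#' @param trait label stored in the model.
#' @return a \linkS4class{QtlModel}.
#' @export
stepwiseScan <- function(phenotype, genotypes, config = scanConfig(),
                         covariates = NULL, markers = NULL, threshold = NULL,
                         trait = "trait") {
  if (is.null(threshold)) {
    threshold <- permutationThreshold(phenotype, genotypes, config,
      character(), covariates, markers)
  }
  log <- sprintf(
    "entry threshold %.4f (-log10 p), df rule '%s', exclusion %g cM",
    threshold, config$dfRule, config$backgroundExclusionCM
  )
  accepted <- character()
  repeat {
    sc <- scanJoint(phenotype, genotypes, config, accepted, covariates,
      markers)
    cand <- sc[!(sc$marker_id %in% accepted), ]
    if (!nrow(cand)) break
    top <- max(cand$negLog10P)
    if (!(top > threshold)) break
    hits <- cand[cand$negLog10P >= top - 1e-12, ]
    hits <- hits[order(hits$chrom, hits$pos_bp), ]
    pick <- hits$marker_id[1]
    if (nrow(hits) > 1) {
      log <- c(log, sprintf("tie at -log10 p %.4f broken toward %s",
        top, pick))
    }
    accepted <- c(accepted, pick)
    log <- c(log, sprintf("step %d: accepted %s (-log10 p %.4f)",
      length(accepted), pick, top))
    if (length(accepted) >= config$maxQtl) {
      log <- c(log, "maxQtl reached before the scan was exhausted")
      break
    }
  }
  m <- markerTable(genotypes)
  effects <- data.frame(
    marker_id = character(), family_id = character(),
    estimate = numeric(), se = numeric()
  )
  qtl <- data.frame(
    marker_id = character(), chrom = integer(), pos_bp = integer(),
    negLog10P = numeric(), snpPve = numeric(),
    ciLeft = character(), ciRight = character()
  )
  for (q in accepted) {
    sq <- scanJoint(phenotype, genotypes, config, setdiff(accepted, q),
      covariates, markers = q)
    fams <- familyIds(genotypes)
    effects <- rbind(effects, data.frame(
      marker_id = q, family_id = fams,
      estimate = as.numeric(sq[1, paste0("eff_", fams)]),
      se = as.numeric(sq[1, paste0("se_", fams)])
    ))
    qtl <- rbind(qtl, data.frame(
      marker_id = q, chrom = m$chrom[m$marker_id == q],
      pos_bp = m$pos_bp[m$marker_id == q], negLog10P = sq$negLog10P[1],
      snpPve = .snpPve(phenotype, genotypes, accepted, q),
      ciLeft = NA_character_, ciRight = NA_character_
    ))
  }
  new("QtlModel",
    trait = trait, qtl = qtl, effects = effects,
    threshold = as.numeric(threshold), config = unclass(config), log = log
  )
}

## incremental variance explained by `target` among `accepted`, as a percent
## of the total phenotypic variance of the scan phenotype (pooled families,
## plain Haley-Knott OLS)
.snpPve <- function(phenotype, genotypes, accepted, target) {
  rssW <- rssWo <- tss <- 0
  for (fam in familyIds(genotypes)) {
    G <- genotypes@dosages[[fam]]
    y <- phenotype[rownames(G)]
    ok <- !is.na(y)
    y <- y[ok]
    X <- cbind(1, G[ok, accepted, drop = FALSE])
    Xwo <- cbind(1, G[ok, setdiff(accepted, target), drop = FALSE])
    rssW <- rssW + sum(lm.fit(X, y)$residuals^2)
    rssWo <- rssWo + sum(lm.fit(Xwo, y)$residuals^2)
    tss <- tss + sum((y - mean(y))^2)
  }
  100 * max(rssWo - rssW, 0) / tss
}

#' TASSEL-style QTL confidence interval
#'
#' For each direction from the accepted peak, flanking markers of the full
#' (unpruned) set are added one at a time as fixed covariates at increasing
#' distance, and the peak retested; the bound on that side is the nearest
#' added-marker position at which the peak's p-value is still <= alpha
#' (single outward pass, no iteration). If no such marker exists before the
#' chromosome end, the bound is the terminal marker; a peak at the chromosome
#' end is its own bound on that side.
#'
#' @param peakMarker accepted QTL marker id.
#' @param phenotype named phenotype vector.
#' @param genotypes the full-marker \linkS4class{NamGenotypes}.
#' @param config a \code{\link{scanConfig}} (its \code{ciAlpha} is the rule's
#'   alpha).
#' @param otherQtl other accepted QTL kept in the model during retests.
#' @param covariates optional line-level covariates.
#' @return list(left, right) of bound marker ids.
#' @export
confidenceInterval <- function(peakMarker, phenotype, genotypes,
                               config = scanConfig(),
                               otherQtl = character(), covariates = NULL) {
  m <- markerTable(genotypes)
  j <- match(peakMarker, m$marker_id)
  if (is.na(j)) keyingError("peak marker '%s' not in map", peakMarker)
  ch <- m$chrom[j]
  alpha <- config$ciAlpha
  oneSide <- function(direction) {
    if (direction < 0) {
      cand <- which(m$chrom == ch & m$pos_bp < m$pos_bp[j])
      cand <- cand[order(m$pos_bp[cand], decreasing = TRUE)]
    } else {
      cand <- which(m$chrom == ch & m$pos_bp > m$pos_bp[j])
      cand <- cand[order(m$pos_bp[cand])]
    }
    if (!length(cand)) return(peakMarker) # peak at chromosome end
    for (c in cand) {
      sq <- scanJoint(phenotype, genotypes, config,
        currentQtl = c(otherQtl, m$marker_id[c]), covariates,
        markers = peakMarker)
      p <- 10^(-sq$negLog10P[1])
      if (p <= alpha) return(m$marker_id[c])
    }
    m$marker_id[cand[length(cand)]] # terminal marker
  }
  list(left = oneSide(-1), right = oneSide(+1))
}

#' Add confidence intervals to a fitted QtlModel
#'
#' @param model a \linkS4class{QtlModel}.
#' @param phenotype named phenotype vector used for the scan.
#' @param genotypes full-marker \linkS4class{NamGenotypes}.
#' @param config a \code{\link{scanConfig}}.
#' @param covariates optional line-level covariates.
#' @return the model with \code{ciLeft}/\code{ciRight} filled in.
#' @export
addConfidenceIntervals <- function(model, phenotype, genotypes,
                                   config = scanConfig(), covariates = NULL) {
  q <- model@qtl
  for (i in seq_len(nrow(q))) {
    ci <- confidenceInterval(q$marker_id[i], phenotype, genotypes, config,
      otherQtl = setdiff(q$marker_id, q$marker_id[i]), covariates)
    q$ciLeft[i] <- ci$left
    q$ciRight[i] <- ci$right
  }
  model@qtl <- q
  model
}
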