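nam <- toyNam(nFam = 3, nLines = 100, nChrom = 2, nMarkers = 15, seed = 42)

test_that("marker pruning drops duplicates, keeps independents, idempotent", {
  geno <- nam$geno
  ## duplicate a marker column: exactly one of the pair survives
  m <- markerTable(geno)
  dup <- geno
  for (f in familyIds(geno)) {
    dup@dosages[[f]][, 2] <- dup@dosages[[f]][, 1]
  }
  kept <- pruneMarkers(dup, 0.99)
  expect_equal(sum(m$marker_id[1:2] %in% kept), 1)
  expect_equal(kept[1], m$marker_id[1]) # later member dropped

  ## mutually independent markers (one marker per chromosome): none dropped
  mapU <- makeMap(6, 2, 1000, seed = 3)
  genoU <- simulateNam(mapU, c("A", "B"), 300, seed = 4)
  expect_equal(
    length(pruneMarkers(genoU, 0.99)), nrow(markerTable(mapU))
  )

  ## idempotence on a dense map
  mapD <- makeMap(1, 60, 30, seed = 5)
  genoD <- simulateNam(mapD, c("A", "B"), 150, seed = 6)
  k1 <- pruneMarkers(genoD, 0.99)
  sub <- genoD
  keep <- markerTable(genoD)$marker_id %in% k1
  sub@map@markers <- sub@map@markers[keep, ]
  sub@dosages <- lapply(sub@dosages, function(d) d[, k1, drop = FALSE])
  expect_identical(pruneMarkers(sub, 0.99), k1)
  expect_lt(length(k1), 60)
})

test_that("background kinship honours the exclusion window and is PSD", {
  geno <- nam$geno
  m <- markerTable(geno)
  test <- m$marker_id[5] # on chromosome 1

  ## huge exclusion: K equals leave-one-chromosome-out kinship
  Kl <- backgroundModel(geno, test, exclusionCM = 1e6)
  f <- familyIds(geno)[1]
  G <- dosageMatrix(geno, f)
  other <- m$marker_id[m$chrom != 1]
  Z <- sweep(G[, other], 2, colMeans(G[, other]))
  expect_equal(Kl[[f]], tcrossprod(Z) / length(other), tolerance = 1e-12)

  ## exclusion 0: all markers except (those co-located with) the test marker
  K0 <- backgroundModel(geno, test, exclusionCM = 0)
  others <- setdiff(m$marker_id, test)
  Z0 <- sweep(G[, others], 2, colMeans(G[, others]))
  expect_equal(K0[[f]], tcrossprod(Z0) / length(others), tolerance = 1e-12)

  ## PSD
  ev <- eigen(Kl[[f]], symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)

  ## degenerate: nothing left
  map1 <- makeMap(1, 3, 10)
  geno1 <- simulateNam(map1, "A", 20, seed = 1)
  expect_error(
    backgroundModel(geno1, markerTable(map1)$marker_id[2], exclusionCM = 50),
    class = "sarnamDegenerateInput"
  )
})

test_that("joint LR sums family LRs; single family is its own joint test", {
  geno <- nam$geno
  mk <- markerTable(geno)$marker_id[4]
  y <- plantPhenotype(geno, mk, c(0.5, 0.3, 0), seed = 2)
  cfg <- scanConfig(nPermutations = 100)
  sc <- scanJoint(y, geno, cfg)
  fams <- familyIds(geno)
  expect_equal(
    sc$jointLR, rowSums(as.matrix(sc[paste0("lr_", fams)])),
    tolerance = 1e-8
  )
  expect_true(all(sc$jointLR >= 0))

  geno1 <- geno
  geno1@dosages <- geno1@dosages[1]
  y1 <- y[rownames(dosageMatrix(geno1, fams[1]))]
  sc1 <- scanJoint(y1, geno1, cfg)
  expect_equal(sc1$jointLR, sc1$lr_A, tolerance = 1e-12)

  ## keying error lists offending lines
  expect_error(scanJoint(y[-(1:3)], geno, cfg), class = "sarnamKeyingError")
})

test_that("scan statistics are invariant to phenotype shift and allele flip", {
  geno <- nam$geno
  mk <- markerTable(geno)$marker_id[7]
  y <- plantPhenotype(geno, mk, c(0.5, 0.5, 0.5), seed = 3)
  cfg <- scanConfig()
  sc <- scanJoint(y, geno, cfg)
  scShift <- scanJoint(y + 5, geno, cfg)
  expect_equal(sc$jointLR, scShift$jointLR, tolerance = 1e-6)

  flip <- geno
  flip@dosages <- lapply(flip@dosages, function(d) 1 - d)
  scFlip <- scanJoint(y, flip, cfg)
  expect_equal(sc$jointLR, scFlip$jointLR, tolerance = 1e-6)
  expect_equal(sc$eff_A, -scFlip$eff_A, tolerance = 1e-6)
})

test_that("under the global null the joint LR has chi-square moments", {
  ## no QTL, no background: mean joint LR ~ df (markers on one chromosome
  ## per family scanned many times via replicate phenotype columns)
  mapN <- makeMap(4, 10, 400, seed = 8) # wide spacing: weak background
  genoN <- simulateNam(mapN, c("A", "B"), 120, seed = 9)
  lines <- lineIds(genoN)
  nRep <- 25
  Y <- withSeed(17, matrix(rnorm(length(lines) * nRep), length(lines), nRep,
    dimnames = list(lines, NULL)))
  cfg <- scanConfig()
  sc <- sarnam:::.scanCore(Y, genoN, cfg)
  lr <- as.vector(sc$jointLR)
  df <- rep(sc$df, nRep)
  ## E[LR] = df; average over 40 markers x 25 replicates
  expect_lt(abs(mean(lr) - mean(df)), 0.1 * mean(df))
})

test_that("LMM with tau2 = 0 reduces to OLS and the textbook LR", {
  geno <- nam$geno
  mk <- markerTable(geno)$marker_id[4]
  y <- plantPhenotype(geno, mk, c(0.4, 0.2, 0.1), seed = 5)
  cfg0 <- scanConfig(h2Grid = 0) # force tau2 = 0
  sc <- scanJoint(y, geno, cfg0, markers = mk)
  fams <- familyIds(geno)
  lrs <- vapply(fams, function(f) {
    G <- dosageMatrix(geno, f)
    olsLrOracle(y[rownames(G)], G[, mk])
  }, numeric(1))
  expect_equal(as.numeric(sc[1, paste0("lr_", fams)]), unname(lrs),
    tolerance = 1e-2)
})

test_that("permutation threshold is reproducible and respects its contract", {
  geno <- nam$geno
  y <- plantPhenotype(geno, markerTable(geno)$marker_id[1], c(0, 0, 0),
    seed = 6)
  cfg <- scanConfig(nPermutations = 100, seed = 123)
  t1 <- permutationThreshold(y, geno, cfg, returnMaxima = TRUE)
  t2 <- permutationThreshold(y, geno, cfg)
  expect_equal(as.numeric(t1), as.numeric(t2))
  maxima <- attr(t1, "maxima")
  ## alpha = 1 boundary: the minimum of per-permutation maxima
  cfgA <- scanConfig(nPermutations = 100, seed = 123, alpha = 1 - 1e-12)
  tMin <- permutationThreshold(y, geno, cfgA)
  expect_equal(as.numeric(tMin), min(maxima), tolerance = 1e-6)
  ## permutations preserve per-family sample sizes
  Y <- sarnam:::.permutedPhenotypeMatrix(y, geno, 5, 99)
  for (f in familyIds(geno)) {
    ln <- rownames(dosageMatrix(geno, f))
    for (j in 1:5) {
      expect_equal(sort(unname(Y[ln, j])), sort(unname(y[ln])))
    }
  }
  expect_error(
    permutationThreshold(y, geno, scanConfig(nPermutations = 10)),
    class = "sarnamInvalidArgument"
  )
})

test_that("stepwise search recovers two planted unlinked QTL in order", {
  ## 7 families x 150 lines (the scale at which ordering 0.5 vs 0.4 sd
  ## effects is reliable); replicate count reduced for runtime
  mapS <- makeMap(2, 10, 100, seed = 20)
  genoS <- simulateNam(mapS, namFamilies(), 150, seed = 21)
  m <- markerTable(mapS)
  q1 <- m$marker_id[3] # chromosome 1
  q2 <- m$marker_id[16] # chromosome 2
  hits <- 0
  nRep <- 15
  for (i in seq_len(nRep)) {
    y <- plantPhenotype(genoS, q1, c(0.5, 0.5, 0.5), sdNoise = 0, seed = 0) *
      0
    withSeed(300 + i, {
      for (f in familyIds(genoS)) {
        G <- dosageMatrix(genoS, f)
        y[rownames(G)] <- 0.5 * G[, q1] + 0.4 * G[, q2] +
          rnorm(nrow(G), 0, 0.5)
      }
    })
    mod <- stepwiseScan(y, genoS, scanConfig(maxQtl = 5), threshold = 3,
      trait = "sim")
    q <- qtlTable(mod)
    near <- function(target, found) {
      any(abs(m$pos_bp[match(found, m$marker_id)] -
        m$pos_bp[m$marker_id == target]) <=
        diff(m$pos_bp[1:2]) &
        m$chrom[match(found, m$marker_id)] ==
          m$chrom[m$marker_id == target])
    }
    if (nrow(q) >= 2 && near(q1, q$marker_id) && near(q2, q$marker_id) &&
        near(q1, q$marker_id[1])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 0.9 * nRep)
})

test_that("conditioning on a true QTL removes its peak", {
  geno <- nam$geno
  m <- markerTable(geno)
  mk <- m$marker_id[8]
  y <- plantPhenotype(geno, mk, c(0.6, 0.6, 0.6), seed = 31)
  cfg <- scanConfig()
  sc <- scanJoint(y, geno, cfg)
  expect_equal(sc$marker_id[which.max(sc$negLog10P)], mk)
  scCond <- scanJoint(y, geno, cfg, currentQtl = mk)
  expect_lt(scCond$negLog10P[scCond$marker_id == mk], 0.5)
  expect_lt(max(scCond$negLog10P), 3)
})

test_that("confidence intervals behave at boundaries and cover the truth", {
  geno <- nam$geno
  m <- markerTable(geno)
  ## strong QTL: tight CI that contains (or abuts) the true marker
  mk <- m$marker_id[8]
  cover <- 0
  nRep <- 12
  for (i in seq_len(nRep)) {
    y <- plantPhenotype(geno, mk, c(0.9, 0.9, 0.9), sdNoise = 0.4,
      seed = 400 + i)
    sc <- scanJoint(y, geno, scanConfig())
    peak <- sc$marker_id[which.max(sc$negLog10P)]
    ci <- confidenceInterval(peak, y, geno, scanConfig())
    lo <- m$pos_bp[m$marker_id == ci$left]
    hi <- m$pos_bp[m$marker_id == ci$right]
    tb <- m$pos_bp[m$marker_id == mk]
    if (lo <= tb && tb <= hi) cover <- cover + 1
  }
  expect_gte(cover, 0.9 * nRep)

  ## peak at chromosome end: one-sided with the peak as its own bound
  mkEnd <- m$marker_id[1]
  yE <- plantPhenotype(geno, mkEnd, c(1, 1, 1), sdNoise = 0.3, seed = 77)
  ciE <- confidenceInterval(mkEnd, yE, geno, scanConfig())
  expect_identical(ciE$left, mkEnd)
})

test_that("the df rule distinguishes segregating and fixed conventions", {
  geno <- nam$geno
  m <- markerTable(geno)
  mono <- geno
  ## make marker 3 monomorphic in family A
  mono@dosages[["A"]][, 3] <- 0
  y <- plantPhenotype(mono, m$marker_id[3], c(0, 0.5, 0.5), seed = 51)
  scSeg <- scanJoint(y, mono, scanConfig(), markers = m$marker_id[3])
  expect_equal(scSeg$df, 2)
  expect_equal(scSeg$lr_A, 0)
  scFix <- scanJoint(y, mono, scanConfig(dfRule = "fixed:6"),
    markers = m$marker_id[3])
  expect_equal(scFix$df, 6)
  expect_gt(scSeg$negLog10P, scFix$negLog10P) # fewer df, same LR
})
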