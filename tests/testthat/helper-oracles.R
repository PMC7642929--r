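## Independent oracles used across the suite. None of these call the
## package's own estimation code paths.

## Dense grid-search REML oracle for the two-random-effect plasticity model
## value ~ [shelf +] treatment (fixed) + line + line:treatment (random).
## Profiles sigma2_e analytically and searches the variance ratios
## (gamma1, gamma2) = (s2G/s2e, s2GxE/s2e) on an iteratively refined grid.
remlOracle <- function(d, nZoom = 4, gridN = 13, gmax = 5) {
  d$treatment <- factor(d$treatment, levels = c("sun", "shade"))
  d$shelfF <- factor(paste(d$experiment, d$shelf, sep = ":"))
  X <- if (nlevels(d$shelfF) > 1) {
    model.matrix(~ shelfF + treatment, d)
  } else {
    model.matrix(~treatment, d)
  }
  Z1 <- model.matrix(~ 0 + factor(line_id), d)
  Z2 <- model.matrix(~ 0 + factor(line_id):treatment, d)
  y <- d$value
  n <- length(y)
  p <- ncol(X)
  K1 <- tcrossprod(Z1)
  K2 <- tcrossprod(Z2)
  restLL <- function(g1, g2) {
    V0 <- g1 * K1 + g2 * K2 + diag(n)
    cv <- chol(V0)
    Vi <- chol2inv(cv)
    XtVX <- crossprod(X, Vi %*% X)
    b <- solve(XtVX, crossprod(X, Vi %*% y))
    r <- y - X %*% b
    q <- drop(crossprod(r, Vi %*% r))
    s2e <- q / (n - p)
    -0.5 * ((n - p) * log(s2e) + 2 * sum(log(diag(cv))) +
      determinant(XtVX)$modulus[1] + (n - p))
  }
  lo1 <- lo2 <- 0
  hi1 <- hi2 <- gmax
  best <- c(0, 0)
  for (z in seq_len(nZoom)) {
    g1s <- seq(lo1, hi1, length.out = gridN)
    g2s <- seq(lo2, hi2, length.out = gridN)
    ll <- outer(g1s, g2s, Vectorize(restLL))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(g1s[ij[1]], g2s[ij[2]])
    st1 <- diff(g1s[1:2])
    st2 <- diff(g2s[1:2])
    lo1 <- max(0, best[1] - st1)
    hi1 <- best[1] + st1
    lo2 <- max(0, best[2] - st2)
    hi2 <- best[2] + st2
  }
  V0 <- best[1] * K1 + best[2] * K2 + diag(n)
  Vi <- chol2inv(chol(V0))
  XtVX <- crossprod(X, Vi %*% X)
  b <- solve(XtVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  s2e <- drop(crossprod(r, Vi %*% r)) / (n - p)
  list(sigma2_G = best[1] * s2e, sigma2_GxE = best[2] * s2e, sigma2_e = s2e)
}

## closed-form balanced-design BLUPs given variance components:
## G: shrink line means; GxE contrast: shrink per-line (shade - sun)
## deviations. Exact under balance.
balancedBlupOracle <- function(d, s2G, s2GxE, s2e) {
  r <- nrow(d) / (length(unique(d$line_id)) * 2) # reps per line x trt
  lineMeans <- tapply(d$value, d$line_id, mean)
  gShrink <- s2G / (s2G + s2GxE / 2 + s2e / (2 * r))
  g <- gShrink * (lineMeans - mean(lineMeans))
  cellMeans <- tapply(d$value, list(d$line_id, d$treatment), mean)
  dev <- cellMeans[, "shade"] - cellMeans[, "sun"]
  dShrink <- (2 * s2GxE) / (2 * s2GxE + 2 * s2e / r)
  gxe <- dShrink * (dev - mean(dev))
  list(G = g, GxE = gxe[names(g)])
}

## textbook F-test oracle for a single-marker OLS Haley-Knott regression;
## returns the ML likelihood-ratio statistic 2(l1 - l0)
olsLrOracle <- function(y, x, X0 = NULL) {
  X0 <- if (is.null(X0)) matrix(1, length(y)) else cbind(1, X0)
  r0 <- lm.fit(X0, y)$residuals
  r1 <- lm.fit(cbind(X0, x), y)$residuals
  length(y) * (log(sum(r0^2)) - log(sum(r1^2)))
}

## small NAM fixture shared across tests
toyNam <- function(nFam = 3, nLines = 100, nChrom = 2, nMarkers = 20,
                   lenCM = 100, seed = 42) {
  map <- makeMap(nChrom, nMarkers, lenCM, seed = seed)
  geno <- simulateNam(map, LETTERS[seq_len(nFam)], nLines, seed = seed + 1)
  list(map = map, geno = geno)
}

## phenotype with planted per-family additive effects at one marker
plantPhenotype <- function(geno, marker, effects, sdNoise = 0.5, seed = 1) {
  fams <- familyIds(geno)
  withSeed(seed, {
    unlist(lapply(seq_along(fams), function(i) {
      G <- dosageMatrix(geno, fams[i])
      setNames(
        G[, marker] * effects[i] + rnorm(nrow(G), 0, sdNoise),
        rownames(G)
      )
    }))
  })
}

## internal helpers reached through the namespace in tests
withSeed <- sarnam:::withSeed
childSeed <- sarnam:::childSeed
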