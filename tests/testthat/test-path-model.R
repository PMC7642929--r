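## cascading fixture with known coefficients; returns per-line data for one
## group plus the truth
cascadeData <- function(n = 400, a = 0.5, bRB = 0.4, bIG = -0.3, cRB = 0.5,
                        cIG = 0.3, directIB = 0, seed = 1, sdE = 0.7) {
  withSeed(seed, {
    q <- rbinom(n, 1, 0.5)
    BD <- a * q + rnorm(n, 0, sdE)
    RB <- bRB * BD + rnorm(n, 0, sdE)
    IG <- bIG * BD + rnorm(n, 0, sdE)
    IB <- cRB * RB + cIG * IG + directIB * q + rnorm(n, 0, sdE)
    data.frame(Q = q, BD = BD, RB = RB, IG = IG, IB = IB)
  })
}

test_that("saturated path models reproduce the observed moments exactly", {
  d <- cascadeData(seed = 3)
  fit <- fitPathModel(list(sun = d, shade = cascadeData(seed = 4)),
    pathSpec("Q"))
  fi <- fitIndices(fit)
  expect_lt(max(fi$chisq), 1e-8)
  expect_equal(fi$cfi, rep(1, nrow(fi)))
  expect_equal(fi$rmsea, rep(0, nrow(fi)))
  expect_lt(max(fi$srmr), 1e-8)
  expect_equal(fi$df[fi$group != "all"], c(0, 0))
})

test_that("edge coefficients equal per-equation OLS to 1e-10", {
  d <- cascadeData(seed = 5)
  fit <- fitPathGroup(d, pathSpec("Q"), group = "g")
  co <- pathCoefficients(fit)
  ref <- lm(IB ~ Q + BD + RB + IG, d)
  for (p in c("Q", "BD", "RB", "IG")) {
    expect_equal(
      co$estimate[co$lhs == "IB" & co$op == "~" & co$rhs == p],
      unname(coef(ref)[p]),
      tolerance = 1e-10
    )
  }
  ## standard errors and p-values come from the same OLS
  sm <- summary(ref)$coefficients
  expect_equal(
    co$se[co$lhs == "IB" & co$op == "~" & co$rhs == "RB"],
    unname(sm["RB", "Std. Error"]), tolerance = 1e-10
  )
})

test_that("implied covariance follows Wright's path tracing on a chain", {
  ## x -> m -> y with coefficients (a, b): cov(x, y) = a b var(x)
  n <- 500
  d <- withSeed(11, {
    x <- rnorm(n)
    m <- 0.7 * x + rnorm(n, 0, 0.5)
    y <- 0.4 * m + rnorm(n, 0, 0.5)
    data.frame(Q = x, BD = m, RB = y)
  })
  spec <- new("PathSpec",
    traits = c("BD", "RB"),
    edges = data.frame(from = "BD", to = "RB"),
    qtlEdges = data.frame(qtl = "Q", trait = "BD")
  )
  f <- sarnam:::.fitOneGroup(d, spec, "g")
  a <- f$B["BD", "Q"]
  b <- f$B["RB", "BD"]
  expect_equal(f$sigma["Q", "RB"], a * b * var(d$Q), tolerance = 1e-10)
})

test_that("multi-group fitting with identical data gives identical tables", {
  d <- cascadeData(seed = 7)
  fit <- fitPathModel(list(sun = d, shade = d), pathSpec("Q"))
  co <- pathCoefficients(fit)
  s <- co[co$group == "sun", c("lhs", "op", "rhs", "estimate", "se", "p")]
  h <- co[co$group == "shade", c("lhs", "op", "rhs", "estimate", "se", "p")]
  expect_equal(s, h, ignore_attr = TRUE)
})

test_that("backward elimination keeps true structure, drops noise edges", {
  ## fixed point: everything significant in one group -> nothing removed
  dS <- cascadeData(n = 600, directIB = 0.6, seed = 9, sdE = 0.4)
  dH <- cascadeData(n = 600, directIB = 0.6, seed = 10, sdE = 0.4)
  specTight <- new("PathSpec",
    traits = sarnamTraits(),
    edges = data.frame(
      from = c("BD", "BD", "RB", "IG"), to = c("RB", "IG", "IB", "IB")
    ),
    qtlEdges = data.frame(qtl = "Q", trait = c("BD", "IB"))
  )
  red <- backwardEliminate(specTight, dS, dH, alpha = 0.01)
  expect_length(red$trace, 0)
  expect_equal(nrow(red$spec@edges), 4)

  ## a pure-noise QTL edge is removed (replicated)
  removed <- 0
  nRep <- 25
  for (i in seq_len(nRep)) {
    ## Q has no effect anywhere: a = 0
    d1 <- cascadeData(n = 300, a = 0, seed = 500 + i)
    d2 <- cascadeData(n = 300, a = 0, seed = 900 + i)
    red <- backwardEliminate(
      new("PathSpec",
        traits = c("BD", "RB"),
        edges = data.frame(from = "BD", to = "RB"),
        qtlEdges = data.frame(qtl = "Q", trait = c("BD", "RB"))
      ),
      d1, d2,
      alpha = 0.01
    )
    if (!("RB" %in% red$spec@qtlEdges$trait) &&
        !("BD" %in% red$spec@qtlEdges$trait)) {
      removed <- removed + 1
    }
  }
  expect_gte(removed, 0.95 * nRep)

  ## a term significant in only one group is retained
  dSun <- cascadeData(n = 500, directIB = 0, seed = 21)
  dShade <- cascadeData(n = 500, directIB = 0.8, seed = 22)
  red2 <- backwardEliminate(pathSpec("Q"), dSun, dShade, alpha = 0.01)
  expect_true(any(red2$spec@qtlEdges$trait == "IB"))
})

test_that("mediation decomposition obeys the product and total rules", {
  ## chain QTL -> BD -> RB with a = 0.5, b = 0.4, no direct edge:
  ## coefficients planted exactly through a constructed fit
  d <- cascadeData(n = 2000, a = 0.5, bRB = 0.4, seed = 31, sdE = 0.5)
  spec <- new("PathSpec",
    traits = c("BD", "RB"),
    edges = data.frame(from = "BD", to = "RB"),
    qtlEdges = data.frame(qtl = "Q", trait = "BD")
  )
  fit <- fitPathModel(list(sun = d, shade = d), spec)
  dec <- decomposeEffects(fit, "Q", "RB")
  sun <- dec[dec$group == "sun", ]
  expect_equal(sun$estimate[sun$component == "direct"], 0)
  a <- fit@coefficients$estimate[
    fit@coefficients$group == "sun" & fit@coefficients$lhs == "BD" &
      fit@coefficients$rhs == "Q"
  ]
  b <- fit@coefficients$estimate[
    fit@coefficients$group == "sun" & fit@coefficients$lhs == "RB" &
      fit@coefficients$rhs == "BD"
  ]
  expect_equal(sun$estimate[sun$component == "indirect_total"], a * b,
    tolerance = 1e-12)
  expect_equal(
    sun$estimate[sun$component == "total"],
    impliedTotalEffect(fit, "sun", "Q", "RB"),
    tolerance = 1e-12
  )
  ## exact arithmetic case a = 0.5, b = 0.4 -> indirect 0.20
  fit@coefficients$estimate[
    fit@coefficients$op == "~" & fit@coefficients$lhs == "BD" &
      fit@coefficients$rhs == "Q"
  ] <- 0.5
  fit@coefficients$estimate[
    fit@coefficients$op == "~" & fit@coefficients$lhs == "RB" &
      fit@coefficients$rhs == "BD"
  ] <- 0.4
  dec2 <- decomposeEffects(fit, "Q", "RB")
  s2 <- dec2[dec2$group == "sun", ]
  expect_equal(s2$estimate[s2$component == "indirect_total"], 0.2)
  expect_equal(s2$estimate[s2$component == "total"], 0.2)

  ## sun 0.2 vs shade 0.5 -> environment difference 0.3
  fit@coefficients$estimate[
    fit@coefficients$group == "shade" & fit@coefficients$op == "~" &
      fit@coefficients$lhs == "BD" & fit@coefficients$rhs == "Q"
  ] <- 1.25
  dec3 <- decomposeEffects(fit, "Q", "RB")
  expect_equal(
    dec3$estimate[dec3$group == "shade-sun" & dec3$component == "total"],
    0.5 - 0.2,
    tolerance = 1e-12
  )
})

test_that("two-mediator decomposition matches the reduced-form oracle", {
  d <- cascadeData(n = 800, directIB = 0.3, seed = 41)
  fit <- fitPathModel(list(sun = d, shade = cascadeData(
    n = 800, directIB = 0.1, seed = 42
  )), pathSpec("Q"))
  for (g in c("sun", "shade")) {
    for (tr in c("BD", "RB", "IG", "IB")) {
      dec <- decomposeEffects(fit, "Q", tr)
      tot <- dec$estimate[dec$group == g & dec$component == "total"]
      expect_equal(tot, impliedTotalEffect(fit, g, "Q", tr),
        tolerance = 1e-10)
      dir <- dec$estimate[dec$group == g & dec$component == "direct"]
      ind <- dec$estimate[dec$group == g & dec$component == "indirect_total"]
      expect_equal(tot, dir + ind, tolerance = 1e-12)
    }
  }
  ## reduced-form regression on the fitted implied covariance: coefficient of
  ## IB on Q equals total effect (Q exogenous, single instrument)
  f <- sarnam:::.fitOneGroup(d, pathSpec("Q"), "sun")
  dec <- decomposeEffects(fit, "Q", "IB")
  expect_equal(
    f$sigma["IB", "Q"] / f$sigma["Q", "Q"],
    dec$estimate[dec$group == "sun" & dec$component == "total"],
    tolerance = 1e-10
  )
})

test_that("disconnected QTL yield an all-zero flagged decomposition", {
  d <- cascadeData(seed = 51)
  spec <- new("PathSpec",
    traits = c("BD", "RB"),
    edges = data.frame(from = character(), to = character()),
    qtlEdges = data.frame(qtl = "Q", trait = "BD")
  )
  fit <- fitPathModel(list(sun = d, shade = d), spec)
  dec <- decomposeEffects(fit, "Q", "RB")
  expect_true(all(dec$disconnected))
  expect_true(all(dec$estimate == 0))
})

test_that("elimination order is stable under term input order", {
  d1 <- cascadeData(n = 400, seed = 61)
  d2 <- cascadeData(n = 400, seed = 62)
  spec <- pathSpec("Q")
  specRev <- new("PathSpec",
    traits = spec@traits,
    edges = spec@edges[rev(seq_len(nrow(spec@edges))), ],
    qtlEdges = spec@qtlEdges[rev(seq_len(nrow(spec@qtlEdges))), ]
  )
  r1 <- backwardEliminate(spec, d1, d2, alpha = 0.01)
  r2 <- backwardEliminate(specRev, d1, d2, alpha = 0.01)
  key <- function(s) {
    sort(c(
      sprintf("%s~%s", s@edges$to, s@edges$from),
      sprintf("%s~%s", s@qtlEdges$trait, s@qtlEdges$qtl)
    ))
  }
  expect_identical(key(r1$spec), key(r2$spec))
})

test_that("conditional path scans remove mediated peaks, keep direct ones", {
  ## QTL affects BD only; BD -> RB edge transmits it. The RB scan with BD
  ## effects as covariates must lose the peak; a planted direct RB effect
  ## must survive conditioning.
  mapP <- makeMap(1, 12, 100, seed = 70)
  genoP <- simulateNam(mapP, c("A", "B", "C"), 130, seed = 71)
  m <- markerTable(mapP)
  mk <- m$marker_id[6]
  lines <- lineIds(genoP)
  mkDirect <- m$marker_id[11]
  buildLineEffects <- function(seed, direct = 0) {
    withSeed(seed, {
      le <- NULL
      for (f in familyIds(genoP)) {
        G <- dosageMatrix(genoP, f)
        bdG <- rnorm(nrow(G), 0, 0.3)
        bdGxE <- 0.5 * G[, mk] + rnorm(nrow(G), 0, 0.3)
        rbGxE <- 0.6 * bdGxE + direct * G[, mkDirect] +
          rnorm(nrow(G), 0, 0.2)
        le <- rbind(le, data.frame(
          line_id = rep(rownames(G), 2), family_id = f,
          trait = rep(c("BD", "RB"), each = nrow(G)),
          G_effect = c(bdG, rnorm(nrow(G), 0, 0.3)),
          GxE_effect = c(bdGxE, rbGxE)
        ))
      }
      le
    })
  }
  le <- buildLineEffects(81, direct = 0.5)
  cfg <- scanConfig()
  ## BD scan has no earlier traits: identical to the unconditional scan
  expect_message(
    scBD <- qtlPathScan("BD", le, genoP, cfg, traits = c("BD", "RB")),
    "without covariates"
  )
  phenBD <- setNames(
    le$GxE_effect[le$trait == "BD"], le$line_id[le$trait == "BD"]
  )
  expect_equal(scBD$jointLR, scanJoint(phenBD, genoP, cfg)$jointLR,
    tolerance = 1e-10)
  expect_equal(scBD$marker_id[which.max(scBD$negLog10P)], mk)

  ## conditional RB scan: mediated peak gone, direct peak retained
  scRB <- qtlPathScan("RB", le, genoP, cfg, traits = c("BD", "RB"))
  expect_lt(scRB$negLog10P[scRB$marker_id == mk], 2)
  expect_equal(scRB$marker_id[which.max(scRB$negLog10P)], mkDirect)
  expect_gt(scRB$negLog10P[scRB$marker_id == mkDirect], 3)
})
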