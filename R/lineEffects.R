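#' Inflorescence growth rate from first/last height measurements
#'
#' @param heightFirst height at the first measurement (cm).
#' @param heightLast height at the last measurement (cm).
#' @param daysBetween days between the two measurements (> 0).
#' @return growth rate in cm/day.
#' @examples
#' deriveGrowthRate(5, 19, 7) # 2
#' @export
deriveGrowthRate <- function(heightFirst, heightLast, daysBetween) {
  if (any(daysBetween <= 0)) invalidArg("daysBetween must be > 0")
  (heightLast - heightFirst) / daysBetween
}

#' Box-Cox + z transform of a trait
#'
#' The Box-Cox exponent is chosen by profile maximum likelihood on the grid
#' lambda in [-2, 2] step 0.05; exact ties are broken toward lambda = 1.
#' Non-positive values trigger an automatic shift. The transformed values are
#' then standardised to mean 0, sd 1.
#'
#' @param values numeric vector (>= 10 finite values).
#' @param trait optional trait label stored with the transform.
#' @return list with elements \code{transform} (trait, lambda, shift, zMean,
#'   zSd) and \code{values} (the transformed vector).
#' @export
fitTransform <- function(values, trait = NA_character_) {
  x <- values[is.finite(values)]
  if (length(x) < 10) invalidArg("need >= 10 finite values")
  if (sd(x) == 0) degenerateInput("constant input: transform undefined")
  shift <- if (min(x) <= 0) -min(x) + 0.001 * diff(range(x)) else 0
  y <- x + shift
  grid <- seq(-2, 2, by = 0.05)
  slog <- sum(log(y))
  n <- length(y)
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    -n / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * slog
  }, numeric(1))
  best <- which(ll > max(ll) - 1e-10)
  lambda <- grid[best[which.min(abs(grid[best] - 1))]]
  zf <- boxcoxApply(values + shift, lambda)
  zMean <- mean(zf, na.rm = TRUE)
  zSd <- sd(zf, na.rm = TRUE)
  list(
    transform = list(
      trait = trait, boxcox_lambda = lambda, shift = shift,
      z_mean = zMean, z_sd = zSd
    ),
    values = (zf - zMean) / zSd
  )
}

boxcoxApply <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Apply or invert a fitted trait transform
#'
#' @param transform the \code{transform} element returned by
#'   \code{\link{fitTransform}}.
#' @param values raw (for apply) or transformed (for invert) values.
#' @return transformed / back-transformed values.
#' @export
applyTransform <- function(transform, values) {
  z <- boxcoxApply(values + transform$shift, transform$boxcox_lambda)
  (z - transform$z_mean) / transform$z_sd
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform, values) {
  z <- values * transform$z_sd + transform$z_mean
  lam <- transform$boxcox_lambda
  y <- if (abs(lam) < 1e-12) exp(z) else (z * lam + 1)^(1 / lam)
  y - transform$shift
}

#' Fit the per-family plasticity mixed model
#'
#' Fits, by REML, the observation model
#' \deqn{P = SHELF + TRT + RIL + RIL:TRT + e}
#' with shelf (spatial block, experiment absorbed by concatenation) and
#' treatment as fixed effects and line (RIL) and line-by-treatment as
#' independent random effects. Returns the variance components with PVE and
#' CV_p, and the per-line BLUPs: the genotype main effect (G) and the
#' plasticity effect (GxE), parameterised as the shade-minus-sun line
#' deviation so a positive value means a larger trait value in shade.
#'
#' @param records long-format phenotype table.
#' @param trait trait to fit.
#' @param familyId family to fit.
#' @return list with \code{varComps} (sigma2_G, sigma2_GxE, sigma2_e,
#'   fixedEffects, G_PVE, GxE_PVE, CV_p) and \code{lineEffects}
#'   (data.frame line_id, family_id, trait, G_effect, GxE_effect).
#' @export
fitLineEffects <- function(records, trait, familyId) {
  validatePhenotypes(records)
  d <- records[records$trait == trait & records$family_id == familyId, ]
  if (!nrow(d)) keyingError("no records for trait %s in family %s",
    trait, familyId)
  if (length(unique(d$treatment)) < 2) {
    invalidArg("both treatment levels required")
  }
  if (!any(duplicated(d[c("line_id", "treatment")]))) {
    stopWithClass(
      "sarnamConfounding",
      "single replicate per line x treatment: residual variance unidentifiable"
    )
  }
  d$treatment <- factor(d$treatment, levels = c("sun", "shade"))
  d$shelfF <- factor(paste(d$experiment, d$shelf, sep = ":"))
  d$lineF <- factor(d$line_id)
  form <- if (nlevels(d$shelfF) > 1) {
    value ~ shelfF + treatment + (1 | lineF) + (1 | lineF:treatment)
  } else {
    value ~ treatment + (1 | lineF) + (1 | lineF:treatment)
  }
  fit <- tryCatch(
    lme4::lmer(
      form, data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    ),
    error = function(e) estimationError("mixed model failed: %s",
      conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2G <- vc$vcov[vc$grp == "lineF"]
  s2GxE <- vc$vcov[vc$grp == "lineF:treatment"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  tot <- s2G + s2GxE + s2e
  fe <- summary(fit)$coefficients
  plasticity <- fe["treatmentshade", "Estimate"]
  cvp <- if (abs(plasticity) > 0) sqrt(s2GxE) / abs(plasticity) else NA_real_
  re <- lme4::ranef(fit)
  g <- re$lineF[, 1]
  names(g) <- rownames(re$lineF)
  gxe <- re$`lineF:treatment`
  key <- do.call(rbind, strsplit(rownames(gxe), ":"))
  u <- setNames(gxe[, 1], paste(key[, 1], key[, 2]))
  lines <- levels(d$lineF)
  getU <- function(env) {
    v <- u[paste(lines, env)]
    v[is.na(v)] <- 0
    v
  }
  lineEffects <- data.frame(
    line_id = lines, family_id = familyId, trait = trait,
    G_effect = as.numeric(g[lines]),
    GxE_effect = as.numeric(getU("shade") - getU("sun"))
  )
  varComps <- list(
    trait = trait, family_id = familyId,
    sigma2_G = s2G, sigma2_GxE = s2GxE, sigma2_e = s2e,
    fixedEffects = data.frame(
      term = rownames(fe), estimate = fe[, "Estimate"], se = fe[, "Std. Error"],
      row.names = NULL
    ),
    G_PVE = s2G / tot, GxE_PVE = s2GxE / tot, CV_p = cvp
  )
  list(varComps = varComps, lineEffects = lineEffects)
}

#' Fit line effects for every family and trait
#'
#' @param records long-format phenotype table.
#' @param traits traits to fit (default all four).
#' @param transform if TRUE, Box-Cox + z transform each trait (pooled across
#'   families) before fitting, as in the source protocol.
#' @return list with \code{lineEffects} (stacked table) and \code{varComps}
#'   (list per trait/family).
#' @export
fitAllLineEffects <- function(records, traits = sarnamTraits(),
                              transform = TRUE) {
  validatePhenotypes(records)
  fams <- unique(records$family_id)
  le <- list()
  vcs <- list()
  for (tr in traits) {
    sub <- records[records$trait == tr, ]
    if (transform) {
      ft <- fitTransform(sub$value, tr)
      sub$value <- ft$values
    }
    for (fam in fams) {
      fit <- fitLineEffects(sub, tr, fam)
      le[[paste(tr, fam)]] <- fit$lineEffects
      vcs[[paste(tr, fam)]] <- fit$varComps
    }
  }
  list(lineEffects = do.call(rbind, c(le, make.row.names = FALSE)),
    varComps = vcs)
}

#' Proportion of variance explained by the random effects
#'
#' @param sigma2G,sigma2GxE,sigma2e variance components.
#' @return list(G_PVE, GxE_PVE): each component divided by the total
#'   phenotypic variance (G + GxE + residual).
#' @export
computePve <- function(sigma2G, sigma2GxE, sigma2e) {
  tot <- sigma2G + sigma2GxE + sigma2e
  if (tot <= 0) degenerateInput("all variance components are zero")
  list(G_PVE = sigma2G / tot, GxE_PVE = sigma2GxE / tot)
}

#' Coefficient of genetic variation in plasticity
#'
#' CV_p = sigma_GxE / |mu_plasticity|: the standard deviation (not variance)
#' of the line-by-treatment effect divided by the absolute population-mean
#' plasticity (the shade-minus-sun treatment effect).
#'
#' @param sigmaGxE standard deviation of the GxE random effect (>= 0).
#' @param meanPlasticity population mean plasticity (non-zero).
#' @return CV_p.
#' @export
computeCvp <- function(sigmaGxE, meanPlasticity) {
  if (sigmaGxE < 0) invalidArg("sigmaGxE must be >= 0")
  if (meanPlasticity == 0) {
    stopWithClass("sarnamUndefinedStatistic",
      "CV_p undefined for zero mean plasticity")
  }
  sigmaGxE / abs(meanPlasticity)
}
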