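#' Construct a path-model specification
#'
#' Directed trait-to-trait edges are restricted to the developmental order
#' (default BD -> RB -> IG -> IB); QTL enter as exogenous variables with
#' candidate direct edges onto traits.
#'
#' @param qtlMarkers character vector of QTL (dosage) variable names.
#' @param traits trait order.
#' @param edges data.frame(from, to); NULL = all earlier-to-later pairs.
#' @param qtlEdges data.frame(qtl, trait); NULL = all QTL x trait pairs.
#' @return a \linkS4class{PathSpec}.
#' @export
pathSpec <- function(qtlMarkers = character(), traits = sarnamTraits(),
                     edges = NULL, qtlEdges = NULL) {
  if (is.null(edges)) {
    idx <- which(
      outer(seq_along(traits), seq_along(traits), "<"),
      arr.ind = TRUE
    )
    edges <- data.frame(from = traits[idx[, 1]], to = traits[idx[, 2]])
  }
  if (is.null(qtlEdges)) {
    qtlEdges <- expand.grid(
      qtl = qtlMarkers, trait = traits,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  }
  new("PathSpec", traits = traits, edges = edges, qtlEdges = qtlEdges)
}

## parents of a trait under a spec: list(traits=..., qtl=...)
.parentsOf <- function(spec, trait) {
  list(
    traits = spec@edges$from[spec@edges$to == trait],
    qtl = spec@qtlEdges$qtl[spec@qtlEdges$trait == trait]
  )
}

.specQtl <- function(spec) unique(spec@qtlEdges$qtl)

## fit one group: per-equation OLS, implied covariance by the recursive
## system, ML discrepancy and fit indices. Covariances use the (n-1)
## denominator throughout so a saturated model reproduces S exactly.
.fitOneGroup <- function(data, spec, group) {
  qtlVars <- .specQtl(spec)
  vars <- c(qtlVars, spec@traits)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    keyingError("group %s: missing variable(s) %s", group,
      paste(miss, collapse = ", "))
  }
  data <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(data)
  nFree <- length(qtlVars) * (length(qtlVars) + 1) / 2 +
    nrow(spec@edges) + nrow(spec@qtlEdges) + length(spec@traits)
  if (n < 5 * max(nFree, 1)) {
    invalidArg("group %s: %d complete cases < 5 x %d free parameters",
      group, n, nFree)
  }
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  psi <- matrix(0, p, p, dimnames = list(vars, vars))
  S <- cov(data)
  if (length(qtlVars)) {
    psi[qtlVars, qtlVars] <- S[qtlVars, qtlVars]
  }
  coefs <- list()
  vcovs <- list()
  for (tr in spec@traits) {
    pa <- .parentsOf(spec, tr)
    parents <- c(pa$qtl, pa$traits)
    if (length(parents)) {
      X <- as.matrix(cbind(1, data[parents]))
      if (qr(X)$rank < ncol(X)) {
        estimationError("group %s, equation %s: singular design among {%s}",
          group, tr, paste(parents, collapse = ", "))
      }
      fit <- lm(
        reformulate(sprintf("`%s`", parents), response = sprintf("`%s`", tr)),
        data = data
      )
      sm <- summary(fit)$coefficients
      est <- coef(fit)[-1]
      B[tr, parents] <- est
      psi[tr, tr] <- sum(fit$residuals^2) / (n - 1)
      coefs[[tr]] <- data.frame(
        group = group, lhs = tr, op = "~", rhs = parents,
        estimate = unname(est), se = unname(sm[-1, "Std. Error"]),
        p = unname(sm[-1, "Pr(>|t|)"])
      )
      V <- vcov(fit)[-1, -1, drop = FALSE]
      dimnames(V) <- list(parents, parents)
      vcovs[[tr]] <- V
    } else {
      psi[tr, tr] <- var(data[[tr]])
      vcovs[[tr]] <- matrix(0, 0, 0)
    }
    coefs[[paste0(tr, ".var")]] <- data.frame(
      group = group, lhs = tr, op = "~~", rhs = tr,
      estimate = psi[tr, tr], se = NA_real_, p = NA_real_
    )
  }
  Ib <- solve(diag(p) - B)
  sigma <- Ib %*% psi %*% t(Ib)
  dimnames(sigma) <- list(vars, vars)
  fml <- function(sig) {
    as.numeric(
      determinant(sig)$modulus - determinant(S)$modulus +
        sum(diag(S %*% solve(sig))) - p
    )
  }
  chisq <- max((n - 1) * fml(sigma), 0)
  df <- p * (p + 1) / 2 - nFree
  chisqB <- max((n - 1) * fml(diag(diag(S), p)), 0)
  dfB <- p * (p + 1) / 2 - p
  dS <- sqrt(diag(S))
  res <- (S - sigma) / tcrossprod(dS)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  list(
    coefficients = do.call(rbind, c(coefs, make.row.names = FALSE)),
    chisq = chisq, df = df, chisqB = chisqB, dfB = dfB, n = n,
    srmr = srmr, B = B, psi = psi, sigma = sigma, S = S, vcovs = vcovs,
    data = data
  )
}

.cfi <- function(chisq, df, chisqB, dfB) {
  num <- max(chisq - df, 0)
  den <- max(chisq - df, chisqB - dfB, 0)
  if (den == 0) 1 else max(0, min(1, 1 - num / den))
}

.rmsea <- function(chisq, df, n) {
  if (df <= 0 || n <= 1) return(0)
  sqrt(max(0, (chisq - df) / (df * (n - 1))))
}

#' Fit a recursive path model to one group
#'
#' Every endogenous trait is regressed on its parent set by ordinary least
#' squares (for recursive observed-variable systems with independent errors
#' this coincides with maximum likelihood); the implied covariance is
#' assembled by path tracing over the recursive system, and the model
#' chi-square is (n - 1) times the ML discrepancy between implied and
#' observed covariances. CFI is computed against the independence model,
#' RMSEA from (chisq - df)/(df (n - 1)) floored at zero, and SRMR as the root
#' mean square of standardized residual covariances.
#'
#' @param data data.frame of per-line trait values and QTL dosages.
#' @param spec a \linkS4class{PathSpec}.
#' @param group group label.
#' @return a \linkS4class{PathFit}.
#' @export
fitPathGroup <- function(data, spec, group = "group1") {
  fitPathModel(setNames(list(data), group), spec)
}

#' Fit a multi-group (sun/shade) path model
#'
#' Groups are fitted independently (no cross-group equality constraints);
#' multi-group fit indices pool chi-squares and degrees of freedom across
#' groups.
#'
#' @param dataByGroup named list of data.frames, e.g. list(sun = ...,
#'   shade = ...).
#' @param spec a \linkS4class{PathSpec}.
#' @return a \linkS4class{PathFit}.
#' @export
fitPathModel <- function(dataByGroup, spec) {
  stopifnot(length(names(dataByGroup)) == length(dataByGroup))
  fits <- lapply(names(dataByGroup), function(g) {
    .fitOneGroup(dataByGroup[[g]], spec, g)
  })
  names(fits) <- names(dataByGroup)
  fi <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(
      group = g, chisq = f$chisq, df = f$df, n = f$n,
      cfi = .cfi(f$chisq, f$df, f$chisqB, f$dfB),
      rmsea = .rmsea(f$chisq, f$df, f$n), srmr = f$srmr
    )
  }))
  if (length(fits) > 1) {
    chisq <- sum(fi$chisq)
    df <- sum(fi$df)
    n <- sum(fi$n)
    chisqB <- sum(vapply(fits, `[[`, numeric(1), "chisqB"))
    dfB <- sum(vapply(fits, `[[`, numeric(1), "dfB"))
    fi <- rbind(fi, data.frame(
      group = "all", chisq = chisq, df = df, n = n,
      cfi = .cfi(chisq, df, chisqB, dfB), rmsea = .rmsea(chisq, df, n),
      srmr = mean(fi$srmr)
    ))
  }
  new("PathFit",
    spec = spec,
    coefficients = do.call(rbind, c(lapply(fits, `[[`, "coefficients"),
      make.row.names = FALSE)),
    fitIndices = fi,
    vcovs = lapply(fits, `[[`, "vcovs"),
    data = lapply(fits, `[[`, "data")
  )
}

#' Backward elimination of non-significant path terms
#'
#' Repeatedly refits the sun and shade groups and, among terms that are
#' non-significant (p > alpha) in BOTH groups, drops the single term with the
#' largest minimum-across-groups p-value, until every remaining term is
#' significant in at least one group. An empty model is a legal fixed point.
#'
#' @param spec initial \linkS4class{PathSpec} (all QTL and all earlier-trait
#'   edges).
#' @param dataSun,dataShade per-line data for the two groups.
#' @param alpha retention threshold (default 0.01).
#' @return list(spec, fit, trace): the reduced spec, the final
#'   \linkS4class{PathFit}, and the elimination trace.
#' @export
backwardEliminate <- function(spec, dataSun, dataShade, alpha = 0.01) {
  trace <- character()
  repeat {
    fit <- fitPathModel(list(sun = dataSun, shade = dataShade), spec)
    co <- fit@coefficients[fit@coefficients$op == "~", ]
    if (!nrow(co)) break
    co$p[is.na(co$p)] <- 1
    key <- paste(co$lhs, co$rhs, sep = "~")
    pmat <- tapply(co$p, list(key, co$group), identity)
    worstOk <- apply(pmat, 1, min) # significant anywhere => min p small
    dropable <- which(apply(pmat > alpha, 1, all))
    if (!length(dropable)) break
    drop <- names(which.max(worstOk[dropable]))[1]
    lhs <- sub("~.*$", "", drop)
    rhs <- sub("^.*~", "", drop)
    trace <- c(trace, sprintf("dropped %s (min p %.4g)", drop,
      max(worstOk[dropable])))
    if (rhs %in% spec@traits) {
      keep <- !(spec@edges$from == rhs & spec@edges$to == lhs)
      spec@edges <- spec@edges[keep, , drop = FALSE]
    } else {
      keep <- !(spec@qtlEdges$qtl == rhs & spec@qtlEdges$trait == lhs)
      spec@qtlEdges <- spec@qtlEdges[keep, , drop = FALSE]
    }
  }
  fit <- fitPathModel(list(sun = dataSun, shade = dataShade), spec)
  list(spec = spec, fit = fit, trace = trace)
}

## enumerate all directed paths qtl -> ... -> trait; each path is a character
## vector of edge labels "lhs~rhs" in order
.enumeratePaths <- function(spec, qtl, trait) {
  paths <- list()
  walk <- function(node, edgesSoFar) {
    if (node == trait) {
      paths[[length(paths) + 1]] <<- edgesSoFar
      return(invisible())
    }
    nxt <- spec@edges$to[spec@edges$from == node]
    for (t2 in nxt) {
      walk(t2, c(edgesSoFar, sprintf("%s~%s", t2, node)))
    }
  }
  starts <- spec@qtlEdges$trait[spec@qtlEdges$qtl == qtl]
  for (t1 in starts) {
    walk(t1, sprintf("%s~%s", t1, qtl))
  }
  paths
}

## delta-method variance of sum over paths of products of edge coefficients.
## Coefficient covariances are taken within equations (block-diagonal across
## equations, which are asymptotically uncorrelated in a recursive system).
.deltaVar <- function(paths, est, vcovs) {
  if (!length(paths)) return(0)
  edges <- unique(unlist(paths))
  grad <- setNames(numeric(length(edges)), edges)
  for (pth in paths) {
    prod_all <- prod(est[pth])
    for (e in unique(pth)) {
      k <- sum(pth == e)
      grad[e] <- grad[e] + k * prod_all / est[e]
    }
  }
  V <- matrix(0, length(edges), length(edges),
    dimnames = list(edges, edges))
  lhs <- sub("~.*$", "", edges)
  rhs <- sub("^.*~", "", edges)
  for (eq in unique(lhs)) {
    sel <- which(lhs == eq)
    Veq <- vcovs[[eq]]
    V[sel, sel] <- Veq[rhs[sel], rhs[sel]]
  }
  drop(t(grad) %*% V %*% grad)
}

#' Mediation decomposition of a QTL effect
#'
#' Splits the QTL effect on a trait, per group, into the direct effect (the
#' QTL-to-trait edge coefficient, zero if eliminated) and one indirect
#' component per mediating path (the product of edge coefficients along the
#' path), with first-order delta-method standard errors. The total equals
#' direct plus the summed indirects exactly, and coincides with the
#' reduced-form coefficient implied by the fitted recursive system. The
#' shade-minus-sun difference is reported for each component with
#' SE = sqrt(SE_sun^2 + SE_shade^2).
#'
#' @param fit a fitted multi-group \linkS4class{PathFit} (groups "sun" and
#'   "shade" for the environment difference rows).
#' @param qtl QTL variable name.
#' @param trait target trait.
#' @return data.frame(group, qtl, trait, component, estimate, se,
#'   disconnected); components are "direct", "indirect:<path>",
#'   "indirect_total" and "total", plus "shade-sun" difference rows when both
#'   groups are present.
#' @export
decomposeEffects <- function(fit, qtl, trait) {
  spec <- fit@spec
  groups <- setdiff(unique(fit@fitIndices$group), "all")
  allPaths <- .enumeratePaths(spec, qtl, trait)
  directKey <- sprintf("%s~%s", trait, qtl)
  isDirect <- vapply(allPaths, function(p) identical(p, directKey),
    logical(1))
  medPaths <- allPaths[!isDirect]
  hasDirect <- any(isDirect)
  disconnected <- !hasDirect && !length(medPaths)
  rows <- list()
  for (g in groups) {
    co <- fit@coefficients[
      fit@coefficients$group == g & fit@coefficients$op == "~",
    ]
    est <- setNames(co$estimate, paste(co$lhs, co$rhs, sep = "~"))
    se <- setNames(co$se, paste(co$lhs, co$rhs, sep = "~"))
    dEst <- if (hasDirect) unname(est[directKey]) else 0
    dSe <- if (hasDirect) unname(se[directKey]) else 0
    out <- data.frame(
      group = g, qtl = qtl, trait = trait, component = "direct",
      estimate = dEst, se = dSe
    )
    indTotal <- 0
    for (pth in medPaths) {
      pe <- prod(est[pth])
      pv <- .deltaVar(list(pth), est, fit@vcovs[[g]])
      out <- rbind(out, data.frame(
        group = g, qtl = qtl, trait = trait,
        component = paste0("indirect:", paste(rev(pth), collapse = ";")),
        estimate = pe, se = sqrt(pv)
      ))
      indTotal <- indTotal + pe
    }
    vTot <- if (length(medPaths)) {
      .deltaVar(medPaths, est, fit@vcovs[[g]])
    } else {
      0
    }
    out <- rbind(out,
      data.frame(
        group = g, qtl = qtl, trait = trait, component = "indirect_total",
        estimate = indTotal, se = sqrt(vTot)
      ),
      data.frame(
        group = g, qtl = qtl, trait = trait, component = "total",
        estimate = dEst + indTotal,
        se = sqrt(.deltaVar(allPaths, est, fit@vcovs[[g]]))
      )
    )
    rows[[g]] <- out
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (all(c("sun", "shade") %in% groups)) {
    s <- res[res$group == "sun", ]
    h <- res[res$group == "shade", ]
    diff <- data.frame(
      group = "shade-sun", qtl = qtl, trait = trait,
      component = s$component,
      estimate = h$estimate - s$estimate,
      se = sqrt(s$se^2 + h$se^2)
    )
    res <- rbind(res, diff)
  }
  res$disconnected <- disconnected
  res
}

#' Total QTL effect implied by the fitted recursive system
#'
#' Reduced-form coefficient of the trait on the QTL dosage computed from the
#' fitted structural matrix: the (trait, qtl) entry of (I - B)^{-1}.
#'
#' @param fit a \linkS4class{PathFit}.
#' @param group group label.
#' @param qtl QTL variable name.
#' @param trait target trait.
#' @return the implied total effect.
#' @export
impliedTotalEffect <- function(fit, group, qtl, trait) {
  spec <- fit@spec
  vars <- c(.specQtl(spec), spec@traits)
  B <- matrix(0, length(vars), length(vars),
    dimnames = list(vars, vars))
  co <- fit@coefficients[
    fit@coefficients$group == group & fit@coefficients$op == "~",
  ]
  for (i in seq_len(nrow(co))) B[co$lhs[i], co$rhs[i]] <- co$estimate[i]
  Ib <- solve(diag(length(vars)) - B)
  dimnames(Ib) <- list(vars, vars)
  Ib[trait, qtl]
}

#' Conditional (path) QTL scan for one trait
#'
#' Identical to \code{\link{scanJoint}} but the per-family fixed-effect
#' design additionally contains, for every earlier trait in the developmental
#' order, its line-level genotype (G) and plasticity (GxE) effects as
#' covariates. The first trait scans unconditionally.
#'
#' @param trait trait to scan (its GxE effect is the phenotype).
#' @param lineEffects stacked line-effect table (line_id, family_id, trait,
#'   G_effect, GxE_effect).
#' @param genotypes a \linkS4class{NamGenotypes}.
#' @param config a \code{\link{scanConfig}}.
#' @param markers marker set to test.
#' @param traits trait order.
#' @return scan data.frame as from \code{\link{scanJoint}}.
#' @export
qtlPathScan <- function(trait, lineEffects, genotypes,
                        config = scanConfig(), markers = NULL,
                        traits = sarnamTraits()) {
  pos <- match(trait, traits)
  if (is.na(pos)) invalidArg("unknown trait '%s'", trait)
  phen <- lineEffects[lineEffects$trait == trait, ]
  phenotype <- setNames(phen$GxE_effect, phen$line_id)
  covariates <- pathScanCovariates(trait, lineEffects, traits)
  if (is.null(covariates)) {
    message("first trait in the order: scanning without covariates")
  }
  scanJoint(phenotype, genotypes, config, covariates = covariates,
    markers = markers)
}

#' Covariate matrix of earlier-trait effects for a conditional scan
#'
#' @inheritParams qtlPathScan
#' @return numeric matrix (lines x 2 x earlier traits) or NULL for the first
#'   trait.
#' @export
pathScanCovariates <- function(trait, lineEffects, traits = sarnamTraits()) {
  pos <- match(trait, traits)
  earlier <- traits[seq_len(pos - 1)]
  if (!length(earlier)) return(NULL)
  lines <- unique(lineEffects$line_id)
  covariates <- matrix(NA_real_, length(lines), 2 * length(earlier),
    dimnames = list(lines, c(
      paste0("G_", earlier), paste0("GxE_", earlier)
    )))
  for (e in earlier) {
    sub <- lineEffects[lineEffects$trait == e, ]
    covariates[sub$line_id, paste0("G_", e)] <- sub$G_effect
    covariates[sub$line_id, paste0("GxE_", e)] <- sub$GxE_effect
  }
  covariates
}

#' Merge colocalizing QTL across traits
#'
#' QTL from several scan models whose confidence intervals overlap in bp on
#' the same chromosome are merged into a single QTL region (any overlap of
#' the closed intervals); the representative marker of a region is the peak
#' with the largest -log10 p among its members.
#'
#' @param models list of \linkS4class{QtlModel} (confidence intervals filled).
#' @param map the \linkS4class{GeneticMap} (to place CI bound markers).
#' @return data.frame(region_id, chrom, marker_id, left_bp, right_bp,
#'   members).
#' @export
mergeOverlappingQtl <- function(models, map) {
  m <- markerTable(map)
  bp <- setNames(m$pos_bp, m$marker_id)
  rows <- do.call(rbind, lapply(models, function(mod) {
    q <- qtlTable(mod)
    if (!nrow(q)) return(NULL)
    data.frame(
      trait = mod@trait, marker_id = q$marker_id, chrom = q$chrom,
      peak_bp = q$pos_bp, negLog10P = q$negLog10P,
      left_bp = ifelse(is.na(q$ciLeft), q$pos_bp, bp[q$ciLeft]),
      right_bp = ifelse(is.na(q$ciRight), q$pos_bp, bp[q$ciRight])
    )
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(
      region_id = character(), chrom = integer(), marker_id = character(),
      left_bp = numeric(), right_bp = numeric(), members = character()
    ))
  }
  out <- list()
  for (ch in sort(unique(rows$chrom))) {
    sub <- rows[rows$chrom == ch, ]
    sub <- sub[order(sub$left_bp), ]
    grp <- integer(nrow(sub))
    g <- 1
    hi <- sub$right_bp[1]
    grp[1] <- g
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$left_bp[i] <= hi) {
        grp[i] <- g
        hi <- max(hi, sub$right_bp[i])
      } else {
        g <- g + 1
        grp[i] <- g
        hi <- sub$right_bp[i]
      }
    }
    for (gg in unique(grp)) {
      mem <- sub[grp == gg, ]
      rep <- mem[which.max(mem$negLog10P), ]
      out[[length(out) + 1]] <- data.frame(
        region_id = sprintf("SAR%d_%d", ch, gg), chrom = ch,
        marker_id = rep$marker_id, left_bp = min(mem$left_bp),
        right_bp = max(mem$right_bp),
        members = paste(sprintf("%s:%s", mem$trait, mem$marker_id),
          collapse = ",")
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
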