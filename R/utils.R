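#' @import methods
#' @importFrom stats coef cor cov lm lm.fit pchisq pf pnorm pt qnorm quantile
#'   rbinom rnorm runif sd setNames var vcov complete.cases reformulate
#'   model.matrix aggregate reshape
#' @importFrom utils read.delim write.table packageVersion
NULL

## classed conditions so callers can distinguish failure modes
stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "sarnamError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

invalidArg <- function(fmt, ...) stopWithClass("sarnamInvalidArgument", fmt, ...)
degenerateInput <- function(fmt, ...) stopWithClass("sarnamDegenerateInput", fmt, ...)
keyingError <- function(fmt, ...) stopWithClass("sarnamKeyingError", fmt, ...)
estimationError <- function(fmt, ...) stopWithClass("sarnamEstimationError", fmt, ...)

## deterministic child seeds: counter-derived, kept below 2^31
childSeed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 7919) %%
    2147483629L)
}

## run expr with a local RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE)
  }
  set.seed(seed)
  expr
}

## Haldane map function and its selfed-RIL expansion
haldaneR <- function(dCM) 0.5 * (1 - exp(-2 * dCM / 100))
kosambiR <- function(dCM) 0.5 * tanh(2 * dCM / 100)

#' Expected recombinant fraction between RIL genotypes at the inbred limit
#'
#' For recombinant inbred lines produced by repeated selfing, the observed
#' fraction of recombinant lines between two loci with per-meiosis
#' recombination fraction \code{r} converges to \code{2r/(1+2r)}
#' (Haldane-Waddington).
#'
#' @param r per-meiosis recombination fraction in [0, 0.5].
#' @return expected RIL recombinant fraction.
#' @export
rilRecombFraction <- function(r) 2 * r / (1 + 2 * r)

sarnamTraits <- function() c("BD", "RB", "IG", "IB")
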