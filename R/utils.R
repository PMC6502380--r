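#' @keywords internal
"_PACKAGE"

#' @useDynLib kypemorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats anova as.formula coef complete.cases cor cov lm logLik
#'   median optim optimize p.adjust pchisq pf prcomp pt qf quantile resid
#'   rbinom rnorm runif sd setNames terms var vcov formula drop1 model.matrix
#'   ptukey reformulate update.formula delete.response
#' @importFrom utils read.csv write.csv read.delim head tail
NULL

# Strain levels used throughout; order fixed (domesticated, hybrids, wild).
STRAINS <- c("Mowi", "HybridFM", "HybridMF", "Arna", "Figgjo", "Vosso")

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic stages draw their RNG state from a single integer master
#' seed through named sub-streams, so that e.g. regenerating landmarks does
#' not perturb the genotype draw.
#'
#' @param seed master integer seed
#' @param stream stream name, e.g. `"pedigree"`, `"genotype"`
#' @return an integer seed below 2^31
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 97)
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483629)
}

# Run code under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
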