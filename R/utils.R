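# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Deterministic integer hash of a master seed and a stage label. Used
#' throughout the package so that individual stochastic stages (QTN
#' placement, effect sampling, residuals, fold assignment, per-fold model
#' seeds) consume independent, reproducible streams: changing one stage's
#' label leaves every other stream untouched.
#'
#' @param seed integer master seed.
#' @param stage character label of the consuming stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(42, "placement")
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  chars <- utf8ToInt(stage)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483646) + 1L
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# validate genotype codes: integers 0/1/2 with NA allowed
.checkCodes <- function(x, what = "genotype codes") {
  v <- x[!is.na(x)]
  .check(all(v %in% c(0, 1, 2)), "%s must be 0, 1 or 2 (or NA)", what)
  invisible(TRUE)
}

# merge user options into a default config list, rejecting unknown names
.mergeConfig <- function(defaults, user, where) {
  if (length(user) == 0L) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  .check(length(unknown) == 0L, "%s: unknown field(s): %s", where,
         paste(unknown, collapse = ", "))
  modifyList(defaults, user)
}
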