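# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# which is what makes the pipeline a pure function of its seeds.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and an index. Kept strictly below
# 2^31 (R integers are 32-bit) and computed in doubles that stay below 2^53
# so the arithmetic is exact. Multiplicative mixing ensures cohorts with
# different parent seeds do not share child seeds for small index offsets.
deriveSeed <- function(seed, i) {
  m <- 2147483647
  v <- ((as.double(seed) %% m) * 48271 + as.double(i) * 16807 + 12345) %% m
  as.integer(v)
}

# MD5 of an R object via its serialized bytes (used for checkpoint and
# manifest integrity). Deterministic within one R build.
objectHash <- function(x) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

# Condition helpers: format errors (unreadable/unsupported files) and
# validation errors (bad arguments) are signalled with dedicated classes so
# callers can distinguish them from programming errors.
stopFormat <- function(...) {
  stop(errorCondition(paste0(...), class = c("mrisr_format_error", "error")))
}
stopValidation <- function(...) {
  stop(errorCondition(paste0(...), class = c("mrisr_validation_error", "error")))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

assertSameShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopValidation(what, " must share dimensions (got ",
                   paste(dim(a), collapse = "x"), " and ",
                   paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}
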