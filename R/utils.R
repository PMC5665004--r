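## small shared helpers

# round half away from zero at `digits` decimals; base round() is banker's
# rounding, which does not reproduce printed report tables
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

.joinMulti <- function(x) if (length(x) == 0L || all(is.na(x))) NA_character_ else paste(x, collapse = ";")

.splitMulti <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0L) else strsplit(x, ";", fixed = TRUE)[[1L]]
}
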