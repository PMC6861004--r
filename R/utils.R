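# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_fraction <- function(x, name, allow_zero = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > 1))
    stopf("`%s` must be in [%s, 1]", name, if (allow_zero) "0" else "(0")
  invisible(x)
}

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || length(x) == 0L)
    stopf("`%s` must be a non-empty matrix image", name)
  invisible(x)
}

assert_same_shape <- function(...) {
  imgs <- list(...)
  dims <- lapply(imgs, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    stopf("images must all have the same shape")
  invisible(TRUE)
}

saturation_value <- function(bit_depth) 2^bit_depth - 1

# slope of the least-squares line through the origin
slope_through_origin <- function(x, y) {
  sxx <- sum(x * x)
  if (sxx == 0) return(0)
  sum(x * y) / sxx
}
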