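# Half-up rounding is used package-wide (quantization, Lloyd center updates,
# clone counts) so every rounded quantity has one documented, testable rule.
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

# A gray image is an integer-valued matrix with every entry in [0, 255].
assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || length(img) == 0L) {
    stop(sprintf("`%s` must be a non-empty matrix", arg), call. = FALSE)
  }
  v <- as.vector(img)
  if (anyNA(v) || any(v != as.integer(v)) || any(v < 0) || any(v > 255)) {
    stop(sprintf("`%s` must contain integer intensities in [0, 255]", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_same_shape <- function(a, b, names = c("pred", "truth")) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("`%s` and `%s` must share the same shape", names[1], names[2]),
         call. = FALSE)
  }
  invisible(NULL)
}

# Run `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
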