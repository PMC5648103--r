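# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a locally seeded RNG
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so seeded operations do not perturb the global stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Error constructors with condition classes so callers can catch precisely.
et_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "ethotrack_error")))
}

# Otsu threshold of a numeric vector on [0, 255] (delegates to EBImage).
otsu255 <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(0)
  img <- EBImage::Image(matrix(clamp(v, 0, 255) / 255, ncol = 1))
  EBImage::otsu(img, range = c(0, 1), levels = 256) * 255
}

# Signed area of a triangle given a 3x2 point matrix.
triangle_area <- function(p) {
  0.5 * abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
            (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
}

# Pairwise side lengths of a triangle: side i is opposite vertex i.
triangle_opposite_sides <- function(p) {
  c(sqrt(sum((p[2, ] - p[3, ])^2)),
    sqrt(sum((p[1, ] - p[3, ])^2)),
    sqrt(sum((p[1, ] - p[2, ])^2)))
}
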