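#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef dnorm fft mvfft lm lm.fit optim optimize
#'   rnorm runif sd setNames cor rpois quantile
#' @importFrom utils modifyList head tail
NULL

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Near-uniform directions on the unit sphere
#'
#' Deterministic Fibonacci-spiral sampling of the sphere, used wherever a
#' reproducible quasi-uniform direction set is needed (e.g. the degree of
#' anisotropy of a tensor).
#'
#' @param n number of directions.
#' @return an `n x 3` matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## Rotation matrices (active rotations, right-handed)
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

deg2rad <- function(d) d * pi / 180

## Deterministic content fingerprint of a numeric object (no cryptographic
## claim; stable across runs for identical content, used by the run manifest).
content_fingerprint <- function(x) {
  v <- as.numeric(x)
  v[!is.finite(v)] <- -123456789.5
  k <- seq_along(v) %% 97 + 1
  sprintf("%d:%.10e:%.10e", length(v), sum(v * k), sum(abs(v)))
}

## Derive a bounded child seed from a master seed and a stage tag.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483L)
}
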