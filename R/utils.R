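#' Convert between percent and fraction viability
#'
#' Viability is stored as a percent of the vehicle mean (0--100 scale) at the
#' I/O boundary and as a fraction (0--1) inside all synergy arithmetic. These
#' two helpers are the single conversion point between the scales.
#'
#' @param x Numeric vector of viabilities.
#' @return Numeric vector on the other scale.
#' @examples
#' percentToFraction(50)   # 0.5
#' fractionToPercent(0.25) # 25
#' @export
percentToFraction <- function(x) {
  stopifnot(is.numeric(x))
  x / 100
}

#' @rdname percentToFraction
#' @export
fractionToPercent <- function(x) {
  stopifnot(is.numeric(x))
  x * 100
}

## Counter-based stream seeding: each simulated entity (compound, animal,
## sample) draws from its own stream keyed by (seed, scenario, entity id), so
## extending a simulation never perturbs draws already made for existing
## entities. The hash is a plain polynomial rolling hash kept below 2^31.
.streamSeed <- function(seed, scenario, id = "") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  key <- paste(scenario, id, sep = "\r")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Multiplicative log-normal noise with mean 1 and coefficient of variation cv.
.lnormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))
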