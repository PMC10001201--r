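## Independent oracles used to cross-check the package implementations.

## Forward median-effect curve from raw parameters (no package code).
oracle_fa <- function(D, m, Dm) 1 / (1 + (Dm / D)^m)

## Exhaustive two-stage grid search minimizing the squared error of the
## linearized median-effect plot over (m, Dm) space. Independent of the
## closed-form least-squares route used by fitMedianEffect.
oracle_grid_fit <- function(dose, fa, m_range = c(0.2, 6),
                            Dm_range = NULL, steps = 80L, stages = 3L) {
  keep <- dose > 0 & fa > 0 & fa < 1
  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  if (is.null(Dm_range)) Dm_range <- range(dose[keep]) * c(0.1, 10)
  sse <- function(m, lDm) sum((y - m * (x - lDm))^2)
  lD_range <- log10(Dm_range)
  for (stage in seq_len(stages)) {
    ms <- seq(m_range[1], m_range[2], length.out = steps)
    lDs <- seq(lD_range[1], lD_range[2], length.out = steps)
    grid <- expand.grid(m = ms, lDm = lDs)
    vals <- mapply(sse, grid$m, grid$lDm)
    best <- grid[which.min(vals), ]
    dm <- diff(m_range) / steps
    dl <- diff(lD_range) / steps
    m_range <- c(best$m - 2 * dm, best$m + 2 * dm)
    lD_range <- c(best$lDm - 2 * dl, best$lDm + 2 * dl)
  }
  c(m = best$m, Dm = 10^best$lDm)
}

## Naive O(n^3) agglomerative average-linkage clustering on a distance
## matrix: returns merge heights in order and the cophenetic distance matrix.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  active <- rep(TRUE, length(clusters))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    idx <- which(active)
    for (i in idx) for (j in idx) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    heights[step] <- best_d
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  list(heights = heights, cophenetic = coph)
}

## Permutation test for any group difference in means (one-way layout).
oracle_permutation_p <- function(values, groups, nPerm = 2000, seed = 42) {
  obs <- stats::var(tapply(values, groups, mean))
  set.seed(seed)
  perm <- replicate(nPerm, {
    stats::var(tapply(sample(values), groups, mean))
  })
  mean(perm >= obs)
}

## Numeric inversion of a simulated Loewe-additive surface: the fa reached
## at component doses (dA, dB), found by bisection on the additivity
## identity using only raw parameters.
oracle_loewe_fa <- function(dA, dB, mA, DmA, mB, DmB, tol = 1e-12) {
  dx <- function(fa, m, Dm) Dm * (fa / (1 - fa))^(1 / m)
  g <- function(fa) dA / dx(fa, mA, DmA) + dB / dx(fa, mB, DmB) - 1
  lo <- 1e-12; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Standard viability table for one drug under the canonical assay design:
## 8 doses at sqrt(2) escalation from Dm/2 to ~5.7 Dm.
canonical_doses <- function(Dm) Dm * 2^seq(-1, 2.5, by = 0.5)

## fa vector from a normalized viability table.
fa_from_normalized <- function(nv) 1 - percentToFraction(nv$viability_pct)
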