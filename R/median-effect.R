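#' Fit the median-effect model to dose-response data
#'
#' Fits the mass-action median-effect model \deqn{fa/fu = (D/Dm)^m} (with
#' \eqn{fu = 1 - fa}) by unweighted least squares on the linearized form
#' \deqn{\log_{10}(fa/fu) = m \log_{10} D - m \log_{10} Dm,} the convention
#' of the classical combination-index software. `m` is the slope
#' (sigmoidicity), `Dm` the median-effect dose, and `r` the Pearson
#' correlation of the linearized regression.
#'
#' Fraction-affected values are clipped into `faClip` before linearization;
#' values outside (0, 1) — e.g. viability above 100\% of vehicle — are clipped
#' with a warning rather than dropped. A non-positive fitted slope marks the
#' fit as flagged (see [isFlagged()]) instead of failing silently.
#'
#' @param dose Numeric vector of doses (uM); only positive doses are used.
#' @param fa Numeric vector of fraction affected (1 - viability fraction),
#'   same length as `dose`.
#' @param faClip Length-2 numeric, clipping bounds for fa (default
#'   `c(0.005, 0.995)`).
#' @return A [MedianEffectFit-class].
#' @examples
#' D <- c(1, 2, 4, 8, 16)
#' fa <- 1 / (1 + (5 / D)^2)  # true m = 2, Dm = 5
#' fitMedianEffect(D, fa)
#' @export
fitMedianEffect <- function(dose, fa, faClip = c(0.005, 0.995)) {
  stopifnot(length(dose) == length(fa), faClip[1] > 0, faClip[2] < 1,
            faClip[1] < faClip[2])
  keep <- is.finite(dose) & is.finite(fa) & dose > 0
  dose <- dose[keep]; fa <- fa[keep]
  if (any(fa < faClip[1] | fa > faClip[2])) {
    warning("fraction-affected values outside [", faClip[1], ", ", faClip[2],
            "] clipped before linearization")
    fa <- pmin(pmax(fa, faClip[1]), faClip[2])
  }
  if (length(dose) < 3L)
    stop("need at least 3 points with dose > 0 and usable fa")
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  if (stats::sd(x) == 0) stop("all doses identical; cannot fit a slope")
  m <- stats::cov(x, y) / stats::var(x)
  b0 <- mean(y) - m * mean(x)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  flagged <- !is.finite(m) || m <= 0
  if (flagged) {
    warning("non-positive median-effect slope; fit flagged")
    Dm <- NA_real_
  } else {
    Dm <- 10^(-b0 / m)
  }
  methods::new("MedianEffectFit", m = m, Dm = Dm, r = r,
               nPoints = length(dose), flagged = flagged)
}

#' Fraction affected at a dose (forward median-effect curve)
#'
#' Evaluates \eqn{fa(D) = 1 / (1 + (Dm/D)^m)}, the inverse of
#' [doseForEffect()].
#'
#' @param fit A [MedianEffectFit-class].
#' @param dose Numeric vector of doses (>= 0; dose 0 gives fa 0).
#' @return Fraction affected in `[0, 1)`.
#' @export
faAtDose <- function(fit, dose) {
  stopifnot(methods::is(fit, "MedianEffectFit"), all(dose >= 0))
  if (isFlagged(fit)) stop("cannot evaluate a flagged median-effect fit")
  ifelse(dose == 0, 0, 1 / (1 + (fit@Dm / dose)^fit@m))
}

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect equation: \eqn{D_x = Dm (fa/(1-fa))^{1/m}}.
#'
#' @param fit A [MedianEffectFit-class].
#' @param fa Fraction affected, strictly inside (0, 1).
#' @return The dose `Dx` achieving `fa`.
#' @examples
#' f <- MedianEffectFit(m = 1, Dm = 2)
#' doseForEffect(f, 0.5)   # 2
#' doseForEffect(f, 0.75)  # 6
#' @export
doseForEffect <- function(fit, fa) {
  stopifnot(methods::is(fit, "MedianEffectFit"))
  if (isFlagged(fit)) stop("cannot evaluate a flagged median-effect fit")
  if (any(fa <= 0) || any(fa >= 1))
    stop("fa must lie strictly inside (0, 1)")
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

.splitDose <- function(design, totalDose) {
  w <- doseRatio(design)
  list(a = totalDose * w[["A"]], b = totalDose * w[["B"]])
}

#' Combination index at a fraction affected
#'
#' For a fixed-ratio two-drug mixture, the total combination dose achieving
#' `fa` is read off the mixture's median-effect fit and split into component
#' doses by the design ratio; the combination index is
#' \deqn{CI = d_A / Dx_A(fa) + d_B / Dx_B(fa)}
#' (mutually exclusive two-term form; set `exclusive = FALSE` to add the
#' non-exclusive third term \eqn{d_A d_B / (Dx_A Dx_B)}). CI < 1 indicates
#' synergy, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param fitA,fitB Single-agent [MedianEffectFit-class] objects.
#' @param fitCombo Fit of the mixture on total dose at the fixed ratio.
#' @param design A [ComboDesign-class] giving the ratio.
#' @param fa Fraction affected, strictly inside (0, 1); vectorized.
#' @param exclusive Use the two-term (mutually exclusive) CI (default).
#' @return Numeric CI value(s).
#' @export
ciAtFa <- function(fitA, fitB, fitCombo, design, fa, exclusive = TRUE) {
  stopifnot(methods::is(design, "ComboDesign"))
  D <- doseForEffect(fitCombo, fa)
  d <- .splitDose(design, D)
  dxa <- doseForEffect(fitA, fa)
  dxb <- doseForEffect(fitB, fa)
  ci <- d$a / dxa + d$b / dxb
  if (!exclusive) ci <- ci + (d$a * d$b) / (dxa * dxb)
  unname(ci)
}

#' Dose-reduction index at a fraction affected
#'
#' \eqn{DRI_i = Dx_i(fa) / d_i}: the fold reduction in drug i's dose
#' achievable inside the combination at equal effect. DRI > 1 means the
#' combination reaches `fa` with less of drug i than the single agent needs.
#'
#' @inheritParams ciAtFa
#' @return A list with numeric elements `driA` and `driB` (vectorized over
#'   `fa`).
#' @export
driAtFa <- function(fitA, fitB, fitCombo, design, fa) {
  stopifnot(methods::is(design, "ComboDesign"))
  D <- doseForEffect(fitCombo, fa)
  d <- .splitDose(design, D)
  list(driA = unname(doseForEffect(fitA, fa) / d$a),
       driB = unname(doseForEffect(fitB, fa) / d$b))
}

#' CI / DRI profile over a fraction-affected grid
#'
#' Evaluates [ciAtFa()] and [driAtFa()] on a grid of fraction-affected values
#' and marks the high-effect range of interest (fa >= 0.75) where synergy
#' calls are made (CI below one, or DRI above one).
#'
#' @inheritParams ciAtFa
#' @param faGrid Strictly increasing grid in (0, 1); default 99 points
#'   0.01--0.99.
#' @param roiMin Lower edge of the range of interest (default 0.75).
#' @return A [CiProfile-class].
#' @export
ciDriProfile <- function(fitA, fitB, fitCombo, design,
                         faGrid = seq(0.01, 0.99, by = 0.01),
                         exclusive = TRUE, roiMin = 0.75) {
  if (length(faGrid) < 1L) stop("fa grid must be non-empty")
  ci <- ciAtFa(fitA, fitB, fitCombo, design, faGrid, exclusive = exclusive)
  dri <- driAtFa(fitA, fitB, fitCombo, design, faGrid)
  methods::new("CiProfile", fa = as.numeric(faGrid), ci = ci,
               driA = dri$driA, driB = dri$driB,
               ratio = design@ratio, roi = faGrid >= roiMin)
}
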