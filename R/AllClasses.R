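#' Fitted median-effect parameters
#'
#' Holds the parameters of the median-effect (mass-action) dose-response model
#' \deqn{fa/fu = (D/Dm)^m} for a single drug or a fixed-ratio two-drug mixture:
#' the sigmoidicity slope `m`, the median-effect dose `Dm` (the dose producing
#' 50\% effect), the Pearson correlation `r` of the linearized fit, and the
#' number of dose points used. Fits whose linearized slope is non-positive
#' (non-monotone or inverted response) are kept but marked `flagged`.
#'
#' @slot m Numeric(1), dimensionless slope of the median-effect plot.
#' @slot Dm Numeric(1), median-effect dose in the dose units supplied (uM).
#' @slot r Numeric(1), Pearson correlation of the linearized regression.
#' @slot nPoints Integer(1), number of usable dose points.
#' @slot flagged Logical(1), `TRUE` for a non-positive fitted slope.
#'
#' @seealso [fitMedianEffect()], [doseForEffect()], [faAtDose()]
#' @export
setClass("MedianEffectFit",
  representation(
    m = "numeric", Dm = "numeric", r = "numeric",
    nPoints = "integer", flagged = "logical"
  ),
  prototype(m = NA_real_, Dm = NA_real_, r = NA_real_,
            nPoints = 3L, flagged = FALSE)
)

setValidity("MedianEffectFit", function(object) {
  msg <- character()
  for (s in c("m", "Dm", "r", "flagged"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (!object@flagged) {
    if (!is.finite(object@m) || object@m <= 0)
      msg <- c(msg, "m must be finite and > 0 for an unflagged fit")
    if (!is.finite(object@Dm) || object@Dm <= 0)
      msg <- c(msg, "Dm must be finite and > 0 for an unflagged fit")
  }
  if (is.finite(object@r) && (object@r < -1 - 1e-8 || object@r > 1 + 1e-8))
    msg <- c(msg, "r must lie in [-1, 1]")
  if (object@nPoints < 3L)
    msg <- c(msg, "nPoints must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Construct a MedianEffectFit from known parameters
#'
#' Mostly useful for building fits with known ground truth (e.g. simulation
#' oracles); experimental data should go through [fitMedianEffect()].
#'
#' @param m,Dm Slope and median-effect dose.
#' @param r Correlation of the linearized fit (1 for an exact construction).
#' @param nPoints Number of supporting points.
#' @param flagged Whether the fit is flagged as non-monotone.
#' @return A [MedianEffectFit-class] object.
#' @examples
#' MedianEffectFit(m = 2, Dm = 5)
#' @export
MedianEffectFit <- function(m, Dm, r = 1, nPoints = 3L, flagged = FALSE) {
  methods::new("MedianEffectFit", m = as.numeric(m), Dm = as.numeric(Dm),
               r = as.numeric(r), nPoints = as.integer(nPoints),
               flagged = isTRUE(flagged))
}

#' @describeIn MedianEffectFit-class slope `m` accessor
#' @param object,x A `MedianEffectFit`.
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname MedianEffectFit-class
#' @export
setMethod("hillSlope", "MedianEffectFit", function(object) object@m)

#' @describeIn MedianEffectFit-class median-effect dose `Dm` accessor
#' @export
setGeneric("medianDose", function(object) standardGeneric("medianDose"))

#' @rdname MedianEffectFit-class
#' @export
setMethod("medianDose", "MedianEffectFit", function(object) object@Dm)

#' @describeIn MedianEffectFit-class linear-fit correlation accessor
#' @export
setGeneric("fitCor", function(object) standardGeneric("fitCor"))

#' @rdname MedianEffectFit-class
#' @export
setMethod("fitCor", "MedianEffectFit", function(object) object@r)

#' @describeIn MedianEffectFit-class flagged-fit accessor
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))

#' @rdname MedianEffectFit-class
#' @export
setMethod("isFlagged", "MedianEffectFit", function(object) object@flagged)

#' @rdname MedianEffectFit-class
#' @param ... Ignored.
#' @export
setMethod("coef", "MedianEffectFit", function(object, ...) {
  c(m = object@m, Dm = object@Dm, r = object@r)
})

setMethod("show", "MedianEffectFit", function(object) {
  cat("MedianEffectFit:",
      sprintf("m = %.4g, Dm = %.4g, r = %.4f (n = %d)%s\n",
              object@m, object@Dm, object@r, object@nPoints,
              if (object@flagged) " [FLAGGED: non-positive slope]" else ""))
  invisible(NULL)
})

#' Fixed-ratio two-drug combination design
#'
#' A constant-ratio design: the mixture is dosed as a total concentration
#' split between drug A and drug B according to a fixed weight pair
#' (ratio by concentration), over a strictly increasing series of total doses.
#'
#' @slot ratio Named numeric(2), positive weights for drugs A and B.
#' @slot doseSeries Numeric, strictly increasing total doses (uM).
#' @export
setClass("ComboDesign",
  representation(ratio = "numeric", doseSeries = "numeric")
)

setValidity("ComboDesign", function(object) {
  msg <- character()
  if (length(object@ratio) != 2L || any(!is.finite(object@ratio)) ||
      any(object@ratio <= 0))
    msg <- c(msg, "ratio must be two positive finite weights")
  ds <- object@doseSeries
  if (length(ds) < 1L || any(!is.finite(ds)) || any(ds <= 0))
    msg <- c(msg, "doseSeries must be positive and finite")
  if (length(ds) > 1L && any(diff(ds) <= 0))
    msg <- c(msg, "doseSeries must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname ComboDesign-class
#' @param ratio Positive weights `c(A, B)` splitting the total dose.
#' @param doseSeries Strictly increasing total doses.
#' @return A `ComboDesign`.
#' @examples
#' ComboDesign(c(1, 2), c(0.5, 1, 2, 4, 8))
#' @export
ComboDesign <- function(ratio, doseSeries) {
  ratio <- as.numeric(ratio)
  names(ratio) <- c("A", "B")
  methods::new("ComboDesign", ratio = ratio,
               doseSeries = as.numeric(doseSeries))
}

#' @describeIn ComboDesign-class dose-ratio accessor (weights normalized to sum 1)
#' @param object A `ComboDesign`.
#' @export
setGeneric("doseRatio", function(object) standardGeneric("doseRatio"))

#' @rdname ComboDesign-class
#' @export
setMethod("doseRatio", "ComboDesign", function(object) {
  object@ratio / sum(object@ratio)
})

#' @describeIn ComboDesign-class total-dose series accessor
#' @export
setGeneric("doseSeries", function(object) standardGeneric("doseSeries"))

#' @rdname ComboDesign-class
#' @export
setMethod("doseSeries", "ComboDesign", function(object) object@doseSeries)

setMethod("show", "ComboDesign", function(object) {
  w <- doseRatio(object)
  cat(sprintf("ComboDesign: ratio A:B = %.3g:%.3g, %d total doses [%g .. %g]\n",
              object@ratio[1], object@ratio[2], length(object@doseSeries),
              min(object@doseSeries), max(object@doseSeries)))
  invisible(NULL)
})

#' Combination-index / dose-reduction-index profile
#'
#' CI and per-drug DRI of a fixed-ratio combination evaluated on a grid of
#' fraction-affected values, together with the high-effect range of interest
#' (fa >= 0.75) used to call synergy.
#'
#' @slot fa Numeric, strictly increasing fraction-affected grid in (0, 1).
#' @slot ci Numeric, combination index per grid point.
#' @slot driA,driB Numeric, dose-reduction index of each drug per grid point.
#' @slot ratio Named numeric(2), the design ratio.
#' @slot roi Logical, range-of-interest mask (fa >= 0.75).
#' @seealso [ciDriProfile()]
#' @export
setClass("CiProfile",
  representation(fa = "numeric", ci = "numeric", driA = "numeric",
                 driB = "numeric", ratio = "numeric", roi = "logical")
)

setValidity("CiProfile", function(object) {
  msg <- character()
  n <- length(object@fa)
  if (n < 1L) msg <- c(msg, "fa grid must be non-empty")
  if (any(object@fa <= 0) || any(object@fa >= 1))
    msg <- c(msg, "fa grid must lie strictly inside (0, 1)")
  if (n > 1L && any(diff(object@fa) <= 0))
    msg <- c(msg, "fa grid must be strictly increasing")
  for (s in c("ci", "driA", "driB", "roi"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must match the fa grid length", s))
  if (any(is.finite(object@ci) & object@ci <= 0))
    msg <- c(msg, "CI values must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname CiProfile-class
#' @param x A `CiProfile`.
#' @param row.names,optional,... Passed on for S3 compatibility; ignored.
#' @export
as.data.frame.CiProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(fa = x@fa, ci = x@ci, dri_a = x@driA, dri_b = x@driB,
             roi = x@roi)
}

setMethod("show", "CiProfile", function(object) {
  roi <- object@roi
  cat(sprintf("CiProfile: ratio A:B = %.3g:%.3g, %d fa points\n",
              object@ratio[1], object@ratio[2], length(object@fa)))
  if (any(roi)) {
    cat(sprintf("  range of interest (fa >= 0.75): CI in [%.3f, %.3f]\n",
                min(object@ci[roi]), max(object@ci[roi])))
  }
  invisible(NULL)
})

#' Longitudinal tumor-growth trial
#'
#' Per-animal tumor measurements over time, grouped by treatment arm. Tumor
#' size is the product length x width (mm^2); the slot stores one row per
#' (animal, day). Treatment begins at `treatmentStartDay` (days since
#' seeding).
#'
#' Note on units: the source protocol computes "volume = length times width",
#' which is dimensionally an area and is reported as tumor area; this class
#' follows that convention and stores size in mm^2.
#'
#' @slot measurements `data.frame` with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`, `size_mm2`.
#' @slot treatmentStartDay Integer(1).
#' @seealso [summarizeFinal()], [finalMeasureAnova()], [invivoCdi()]
#' @export
setClass("TumorTrial",
  representation(measurements = "data.frame", treatmentStartDay = "integer")
)

setValidity("TumorTrial", function(object) {
  msg <- character()
  m <- object@measurements
  need <- c("animal_id", "group", "day", "length_mm", "width_mm", "size_mm2")
  miss <- setdiff(need, names(m))
  if (length(miss))
    return(sprintf("measurements lack column(s): %s",
                   paste(miss, collapse = ", ")))
  if (any(m$length_mm <= 0) || any(m$width_mm <= 0))
    msg <- c(msg, "length and width must be positive")
  if (max(abs(m$size_mm2 - m$length_mm * m$width_mm)) > 1e-6 * max(m$size_mm2))
    msg <- c(msg, "size_mm2 must equal length_mm * width_mm")
  grp_per_animal <- tapply(m$group, m$animal_id,
                           function(g) length(unique(g)))
  if (any(grp_per_animal > 1L))
    msg <- c(msg, "each animal must belong to exactly one group")
  if (length(object@treatmentStartDay) != 1L)
    msg <- c(msg, "treatmentStartDay must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @rdname TumorTrial-class
#' @param measurements `data.frame` with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm` (and optionally `size_mm2`, recomputed if absent).
#' @param treatmentStartDay Day treatment began (days since seeding).
#' @return A `TumorTrial`.
#' @export
TumorTrial <- function(measurements, treatmentStartDay = 0L) {
  measurements <- as.data.frame(measurements)
  measurements$size_mm2 <- measurements$length_mm * measurements$width_mm
  o <- order(measurements$animal_id, measurements$day)
  measurements <- measurements[o, , drop = FALSE]
  rownames(measurements) <- NULL
  methods::new("TumorTrial", measurements = measurements,
               treatmentStartDay = as.integer(treatmentStartDay))
}

#' @describeIn TumorTrial-class measurement table accessor
#' @param object A `TumorTrial`.
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname TumorTrial-class
#' @export
setMethod("measurements", "TumorTrial", function(object) object@measurements)

#' @describeIn TumorTrial-class treatment start day accessor
#' @export
setGeneric("treatmentStart", function(object) standardGeneric("treatmentStart"))

#' @rdname TumorTrial-class
#' @export
setMethod("treatmentStart", "TumorTrial",
          function(object) object@treatmentStartDay)

setMethod("show", "TumorTrial", function(object) {
  m <- object@measurements
  cat(sprintf("TumorTrial: %d animals in %d arms, days %d..%d (treatment from day %d)\n",
              length(unique(m$animal_id)), length(unique(m$group)),
              min(m$day), max(m$day), object@treatmentStartDay))
  print(table(arm = m$group[!duplicated(m$animal_id)]))
  invisible(NULL)
})

#' Signature-by-sample score matrix
#'
#' Gene-signature scores (mean Log2 TPM over the signature genes present in
#' the expression matrix) for each signature x sample pair, plus the number of
#' genes actually used per signature.
#'
#' @slot scores Numeric matrix, signatures x samples.
#' @slot nGenesUsed Named integer, genes used per signature.
#' @seealso [scoreSignatures()], [clusterProfiles()], [profileSimilarity()]
#' @export
setClass("SignatureProfiles",
  representation(scores = "matrix", nGenesUsed = "integer")
)

setValidity("SignatureProfiles", function(object) {
  msg <- character()
  if (!is.numeric(object@scores))
    msg <- c(msg, "scores must be a numeric matrix")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must have signature rownames and sample colnames")
  if (length(object@nGenesUsed) != nrow(object@scores))
    msg <- c(msg, "nGenesUsed must have one entry per signature")
  if (length(msg)) msg else TRUE
})

#' @describeIn SignatureProfiles-class score-matrix accessor
#' @param object A `SignatureProfiles`.
#' @export
setGeneric("profileScores", function(object) standardGeneric("profileScores"))

#' @rdname SignatureProfiles-class
#' @export
setMethod("profileScores", "SignatureProfiles", function(object) object@scores)

#' @describeIn SignatureProfiles-class genes-used accessor
#' @export
setGeneric("nGenesUsed", function(object) standardGeneric("nGenesUsed"))

#' @rdname SignatureProfiles-class
#' @export
setMethod("nGenesUsed", "SignatureProfiles", function(object) object@nGenesUsed)

setMethod("show", "SignatureProfiles", function(object) {
  cat(sprintf("SignatureProfiles: %d signatures x %d samples\n",
              nrow(object@scores), ncol(object@scores)))
  invisible(NULL)
})
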