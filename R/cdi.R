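#' Coefficient of drug interaction
#'
#' \deqn{CDI = v_{AB} / (v_A v_B)} on viability *fractions*: the observed
#' combination viability relative to the Bliss-independent expectation (the
#' product of the single-agent viabilities). CDI = 1 is additive
#' (independent), CDI < 1 synergistic, CDI > 1 antagonistic.
#'
#' When the single-agent product falls below `floorEps` the ratio is
#' numerically meaningless (a single agent is already near-lethal); the CDI
#' is returned as `NA` rather than a number.
#'
#' @param vA,vB Single-agent viability fractions (>= 0); vectorized.
#' @param vAB Combination viability fraction.
#' @param floorEps Denominator floor below which CDI is undefined.
#' @return Numeric CDI (with `NA` where undefined).
#' @examples
#' computeCdi(0.5, 0.5, 0.25)  # 1 (Bliss-independent)
#' computeCdi(0.8, 0.6, 0.24)  # 0.5
#' @export
computeCdi <- function(vA, vB, vAB, floorEps = 1e-4) {
  stopifnot(all(vA >= 0), all(vB >= 0), all(vAB >= 0))
  denom <- vA * vB
  out <- vAB / denom
  out[denom < floorEps] <- NA_real_
  out
}

.cdiLevels <- c("significantly_synergistic", "synergistic", "additive",
                "antagonistic")

#' Classify a CDI value
#'
#' Thresholds follow the study convention: CDI < 0.7 is significant
#' synergism; 0.7 <= CDI < 1 - tau is synergism; CDI within tau of 1 is
#' additive (exact CDI = 1 has measure zero, so additivity is a band);
#' CDI > 1 + tau is antagonistic.
#'
#' @param cdi Numeric CDI values (`NA` allowed, propagated).
#' @param additiveTolerance Half-width tau of the additive band (default
#'   0.05; must be < 0.3 so the bands stay disjoint).
#' @return Factor with levels `significantly_synergistic`, `synergistic`,
#'   `additive`, `antagonistic`.
#' @examples
#' classifyCdi(c(0.69, 0.77, 1.0, 1.2))
#' @export
classifyCdi <- function(cdi, additiveTolerance = 0.05) {
  stopifnot(additiveTolerance > 0, additiveTolerance < 0.3)
  if (any(cdi < 0, na.rm = TRUE)) stop("CDI must be >= 0")
  tau <- additiveTolerance
  ## sequential partition: bands tile [0, Inf) with no floating-point gaps
  lab <- rep(NA_character_, length(cdi))
  def <- !is.na(cdi)
  lab[def] <- "antagonistic"
  lab[def & cdi <= 1 + tau] <- "additive"
  lab[def & cdi < 1 - tau] <- "synergistic"
  lab[def & cdi < 0.7] <- "significantly_synergistic"
  factor(lab, levels = .cdiLevels)
}

#' Score a one-dose anchor combination screen
#'
#' For a library screened alone and together with a fixed anchor compound,
#' computes a per-compound CDI with `vA` the compound-alone viability, `vB`
#' the anchor-alone viability, and `vAB` the combination viability. Compounds
#' whose single-agent viability is already below `singleAgentFloor` are
#' flagged `single_agent_effective` and excluded from synergy calls (no
#' label): a compound that kills on its own leaves no room to demonstrate
#' synergy.
#'
#' @param viabilityAlone Named numeric, compound-alone viability fractions.
#' @param viabilityWithAnchor Named numeric, compound+anchor viability
#'   fractions over the same compound names.
#' @param anchorViability Scalar, anchor-alone viability fraction.
#' @param singleAgentFloor Viability floor below which a compound is flagged
#'   single-agent effective (default 0.1).
#' @param additiveTolerance Passed to [classifyCdi()].
#' @return A `data.frame` (one row per compound): `compound`,
#'   `viability_alone`, `viability_with_anchor`, `anchor_viability`, `cdi`,
#'   `label`, `single_agent_effective`.
#' @seealso [computeCdi()], [synergyIntersection()]
#' @export
anchorScreen <- function(viabilityAlone, viabilityWithAnchor, anchorViability,
                         singleAgentFloor = 0.1, additiveTolerance = 0.05) {
  stopifnot(length(anchorViability) == 1L, anchorViability >= 0)
  if (is.null(names(viabilityAlone)) || is.null(names(viabilityWithAnchor)))
    stop("viability vectors must be named by compound")
  only_a <- setdiff(names(viabilityAlone), names(viabilityWithAnchor))
  only_c <- setdiff(names(viabilityWithAnchor), names(viabilityAlone))
  if (length(only_a) || length(only_c))
    stop("compound keys do not match; unmatched: ",
         paste(c(only_a, only_c), collapse = ", "))
  cmpd <- names(viabilityAlone)
  va <- unname(viabilityAlone)
  vab <- unname(viabilityWithAnchor[cmpd])
  lethal <- va < singleAgentFloor
  cdi <- computeCdi(va, rep(anchorViability, length(va)), vab)
  label <- classifyCdi(cdi, additiveTolerance)
  label[lethal] <- NA
  data.frame(
    compound = cmpd,
    viability_alone = va,
    viability_with_anchor = vab,
    anchor_viability = anchorViability,
    cdi = cdi,
    label = label,
    single_agent_effective = lethal,
    stringsAsFactors = FALSE
  )
}

#' Intersect synergy hits across screens
#'
#' The hit set of a screen is the set of compounds with a defined CDI below
#' `threshold` (single-agent-effective compounds never qualify). Returns per
#' screen hit sets, all pairwise intersections, the overall intersection, and
#' exclusive Venn-region counts.
#'
#' @param screens Named list (>= 2) of screen results from [anchorScreen()].
#' @param threshold CDI hit threshold (default 0.7).
#' @return List with `hits` (named list of compound character vectors),
#'   `pairwise` (named list of pairwise intersections), `overall`
#'   (intersection of all screens), and `venn` (`data.frame` of exclusive
#'   membership-pattern counts).
#' @export
synergyIntersection <- function(screens, threshold = 0.7) {
  if (length(screens) < 2L) stop("need at least 2 screens")
  if (is.null(names(screens)) || any(!nzchar(names(screens))))
    stop("screens must be named")
  hits <- lapply(screens, function(s) {
    stopifnot(all(c("compound", "cdi", "single_agent_effective") %in% names(s)))
    s$compound[!s$single_agent_effective & !is.na(s$cdi) & s$cdi < threshold]
  })
  nm <- names(screens)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) intersect(hits[[p[1]]], hits[[p[2]]]))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = " & ")
  overall <- Reduce(intersect, hits)
  universe <- sort(unique(unlist(hits)))
  if (length(universe)) {
    member <- vapply(hits, function(h) universe %in% h,
                     logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
                     dimnames = list(universe, nm))
    pattern <- apply(member, 1, function(z) paste(nm[z], collapse = " & "))
    venn <- as.data.frame(table(region = pattern),
                          stringsAsFactors = FALSE)
    names(venn) <- c("region", "count")
  } else {
    venn <- data.frame(region = character(), count = integer())
  }
  list(hits = hits, pairwise = pairwise, overall = overall, venn = venn)
}

#' Pearson correlation of screen responses
#'
#' Correlates per-compound viabilities of two screens over their shared
#' compound set. Either argument may be a list of named vectors, which are
#' averaged compound-wise first (e.g. the mean of two mutant-line screens
#' against the parental screen).
#'
#' @param x,y Named numeric vectors of per-compound viabilities, or lists of
#'   such vectors to be averaged.
#' @return Pearson correlation coefficient.
#' @export
compareScreens <- function(x, y) {
  avg <- function(v) {
    if (is.list(v)) {
      nm <- Reduce(intersect, lapply(v, names))
      if (length(nm) == 0L) stop("no shared compounds to average")
      rowMeans(vapply(v, function(z) z[nm], numeric(length(nm))))
    } else v
  }
  x <- avg(x); y <- avg(y)
  if (is.null(names(x)) || is.null(names(y)))
    stop("screen vectors must be named by compound")
  nm <- intersect(names(x), names(y))
  if (length(nm) < 3L) stop("need at least 3 shared compounds")
  xv <- x[nm]; yv <- y[nm]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in screen responses; correlation undefined")
  stats::cor(xv, yv)
}
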