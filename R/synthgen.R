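## Synthetic-data generators with known ground truth for every pipeline
## stage. All draws go through per-entity streams keyed by
## (seed, scenario, entity id), so generators are pure functions of their
## arguments and extending a simulation (more compounds, more animals) never
## perturbs the draws of entities already present. Noise is multiplicative
## log-normal throughout: viabilities and tumor sizes are positive,
## scale-dependent quantities.

#' Simulate a median-effect dose-response viability plate
#'
#' Generates a plate-reader viability table for one compound on one model
#' whose true response follows the median-effect curve
#' `viability = 1 - fa(D)` with `fa(D) = 1 / (1 + (Dm/D)^m)`. Each well's
#' signal is `vehicleSignal * viability` times a log-normal noise factor of
#' coefficient of variation `noiseCv`; vehicle wells carry the same noise
#' around `vehicleSignal`. With `noiseCv = 0` the normalization + fit loop
#' recovers `(m, Dm)` exactly.
#'
#' @param seed Integer seed.
#' @param m,Dm True slope and median-effect dose (> 0).
#' @param doses Positive dose series (uM).
#' @param replicates Wells per condition (default 3).
#' @param noiseCv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param model,compound Identifiers written into the table.
#' @param vehicleSignal Mean vehicle luminescence (default 10000).
#' @return A viability table `data.frame` (see [validateViabilityTable()]).
#' @export
simDoseResponse <- function(seed, m, Dm, doses, replicates = 3,
                            noiseCv = 0.05, model = "SIM1",
                            compound = "drugA", vehicleSignal = 10000) {
  stopifnot(m > 0, Dm > 0)
  if (length(doses) == 0L) stop("dose list must be non-empty")
  stopifnot(all(doses > 0))
  fa <- 1 / (1 + (Dm / doses)^m)
  viability <- 1 - fa
  rows <- list()
  veh_noise <- .withSeed(.streamSeed(seed, "dose_response_vehicle",
                                     paste(model, compound)),
                         .lnormNoise(replicates, noiseCv))
  rows[[1]] <- data.frame(
    model_id = model, compound = "vehicle", dose_uM = 0,
    replicate = seq_len(replicates),
    signal = vehicleSignal * veh_noise, role = "vehicle",
    stringsAsFactors = FALSE)
  for (i in seq_along(doses)) {
    noise <- .withSeed(
      .streamSeed(seed, "dose_response", paste(model, compound, i)),
      .lnormNoise(replicates, noiseCv))
    rows[[i + 1L]] <- data.frame(
      model_id = model, compound = compound, dose_uM = doses[i],
      replicate = seq_len(replicates),
      signal = vehicleSignal * viability[i] * noise, role = "sample",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Solve Loewe additivity for fa by bisection: find fa such that
## dA/DxA(fa) + dB/DxB(fa) = 1. The left side decreases monotonically in fa.
.loeweFa <- function(dA, dB, fitA, fitB, tol = 1e-10, maxIter = 200L) {
  g <- function(fa) dA / doseForEffect(fitA, fa) +
    dB / doseForEffect(fitB, fa) - 1
  lo <- 1e-12; hi <- 1 - 1e-12
  glo <- g(lo); ghi <- g(hi)
  if (glo < 0) return(lo)  # dose too small for any appreciable effect
  if (ghi > 0) return(hi)  # dose beyond the representable effect range
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) return((lo + hi) / 2)
  }
  stop("Loewe bisection did not converge")
}

#' Simulate a fixed-ratio combination viability surface
#'
#' Generates the combination arm of a constant-ratio design under a chosen
#' reference model:
#' * `"bliss"` — independence: `v_AB = v_A * v_B`;
#' * `"loewe"` — additivity: fa solves `d_A/Dx_A(fa) + d_B/Dx_B(fa) = 1`
#'   (bisection to tolerance 1e-10);
#' * `"interaction"` — a Loewe surface whose dose axis is rescaled by
#'   `kappa`: the combination achieves at actual dose D what the additive
#'   surface achieves at `D / kappa`, so `kappa < 1` is synergistic
#'   (CI approaches `kappa`) and `kappa > 1` antagonistic.
#'
#' @param seed Integer seed.
#' @param fitA,fitB Single-agent [MedianEffectFit-class] objects (true
#'   parameters).
#' @param design A [ComboDesign-class]: the ratio and total-dose series.
#' @param model `"bliss"`, `"loewe"`, or `"interaction"`.
#' @param kappa Dose-scale interaction factor (used by `"interaction"`).
#' @param replicates,noiseCv,modelId,vehicleSignal As in
#'   [simDoseResponse()].
#' @return A viability table `data.frame` with the mixture as one compound
#'   (`"comboAB"`) dosed at the total dose.
#' @export
simCombinationSurface <- function(seed, fitA, fitB, design,
                                  model = c("bliss", "loewe", "interaction"),
                                  kappa = 1, replicates = 3, noiseCv = 0,
                                  modelId = "SIM1", vehicleSignal = 10000) {
  model <- match.arg(model)
  stopifnot(methods::is(design, "ComboDesign"), kappa > 0)
  doses <- doseSeries(design)
  w <- doseRatio(design)
  viability <- vapply(doses, function(D) {
    dA <- D * w[["A"]]; dB <- D * w[["B"]]
    if (model == "bliss") {
      (1 - faAtDose(fitA, dA)) * (1 - faAtDose(fitB, dB))
    } else {
      eff <- if (model == "interaction") 1 / kappa else 1
      1 - .loeweFa(dA * eff, dB * eff, fitA, fitB)
    }
  }, numeric(1))
  rows <- list()
  veh_noise <- .withSeed(.streamSeed(seed, "combo_vehicle", modelId),
                         .lnormNoise(replicates, noiseCv))
  rows[[1]] <- data.frame(
    model_id = modelId, compound = "vehicle", dose_uM = 0,
    replicate = seq_len(replicates),
    signal = vehicleSignal * veh_noise, role = "vehicle",
    stringsAsFactors = FALSE)
  for (i in seq_along(doses)) {
    noise <- .withSeed(.streamSeed(seed, "combo", paste(modelId, i)),
                       .lnormNoise(replicates, noiseCv))
    rows[[i + 1L]] <- data.frame(
      model_id = modelId, compound = "comboAB", dose_uM = doses[i],
      replicate = seq_len(replicates),
      signal = vehicleSignal * viability[i] * noise, role = "sample",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a one-dose anchor combination screen
#'
#' Generates per-compound viabilities for a library screened alone and with
#' a fixed anchor. Non-planted compounds combine with the anchor under exact
#' Bliss independence (true CDI = 1); planted synergistic compounds get a
#' true CDI drawn uniformly from `cdiRange` (below the 0.7 hit threshold);
#' planted lethal compounds are effective single agents (viability below
#' 0.05) regardless of the anchor. Observed viabilities are replicate means
#' under multiplicative log-normal noise.
#'
#' @param seed Integer seed.
#' @param nDrugs Library size (default 516).
#' @param plantedSynergy Compound names, or a count (taken from the head of
#'   the library), of planted synergistic hits.
#' @param plantedLethal Compound names or a count of single-agent-lethal
#'   compounds (disjoint from the synergy set).
#' @param anchorViability True anchor-alone viability fraction (default 0.8).
#' @param replicates,noiseCv Replicates averaged per viability and the noise
#'   CV (defaults 1 and 0: noiseless).
#' @param anchorReplicates Wells averaged for the anchor-alone viability
#'   (default `8 * replicates`: the anchor control is present on every assay
#'   plate, so it is measured far more often than any library compound).
#' @param cdiRange True-CDI range for planted hits (default `c(0.3, 0.65)`).
#' @return List with `viabilityAlone`, `viabilityWithAnchor` (named
#'   vectors), `anchorViability` (observed), and `truth` (list: `synergistic`,
#'   `lethal`, `trueCdi`).
#' @export
simAnchorScreen <- function(seed, nDrugs = 516, plantedSynergy = 20,
                            plantedLethal = 0, anchorViability = 0.8,
                            replicates = 1, noiseCv = 0,
                            anchorReplicates = 8L * replicates,
                            cdiRange = c(0.3, 0.65)) {
  compounds <- sprintf("C%03d", seq_len(nDrugs))
  pick <- function(x, offset) {
    if (is.character(x)) {
      stopifnot(all(x %in% compounds))
      x
    } else {
      stopifnot(x + offset <= nDrugs)
      compounds[seq_len(x) + offset]
    }
  }
  syn <- pick(plantedSynergy, 0L)
  lethal <- pick(plantedLethal, if (is.character(plantedSynergy))
    length(plantedSynergy) else plantedSynergy)
  if (length(intersect(syn, lethal)))
    stop("planted synergy and lethal sets must be disjoint")
  obsMean <- function(truth, stream, n = replicates) {
    noise <- .withSeed(stream, .lnormNoise(n, noiseCv))
    truth * mean(noise)
  }
  trueCdi <- stats::setNames(rep(1, nDrugs), compounds)
  vAlone <- vWith <- numeric(nDrugs)
  names(vAlone) <- names(vWith) <- compounds
  for (i in seq_len(nDrugs)) {
    cm <- compounds[i]
    pars <- .withSeed(.streamSeed(seed, "screen_compound", cm), {
      va <- if (cm %in% lethal) stats::runif(1, 0, 0.05)
            else stats::runif(1, 0.4, 0.95)
      cdi <- if (cm %in% syn) stats::runif(1, cdiRange[1], cdiRange[2]) else 1
      c(va, cdi)
    })
    trueCdi[cm] <- pars[2]
    vAlone[cm] <- obsMean(pars[1], .streamSeed(seed, "screen_alone", cm))
    vWith[cm] <- obsMean(pars[1] * anchorViability * pars[2],
                         .streamSeed(seed, "screen_combo", cm))
  }
  anchorObs <- obsMean(anchorViability, .streamSeed(seed, "screen_anchor", ""),
                       n = anchorReplicates)
  list(viabilityAlone = vAlone, viabilityWithAnchor = vWith,
       anchorViability = anchorObs,
       truth = list(synergistic = syn, lethal = lethal, trueCdi = trueCdi))
}

#' Simulate a four-arm tumor-growth trial
#'
#' Per-animal exponential tumor growth measured as length x width (mm^2).
#' Every tumor grows at rate `growthRate` until `treatmentStartDay`; from
#' then on the rate is scaled by the arm's effect multiplier. The
#' combination arm is constructed so that, on the final-size scale, its
#' relative effect is the *product* of the single-arm relative effects times
#' the synergy factor `sigma`: with `sigma = 1` the arms combine
#' independently and the expected in-vivo CDI is exactly 1; `sigma < 1`
#' plants synergy (expected CDI = sigma). Baseline sizes vary across animals
#' and every measurement carries multiplicative log-normal noise.
#'
#' @param seed Integer seed.
#' @param effectA,effectB Growth-rate multipliers of the single-agent arms
#'   (> 0; < 1 slows growth).
#' @param sigma Synergy factor on the final-size scale (default 1, additive
#'   in the CDI sense).
#' @param nAnimals Animals per arm (default 8).
#' @param days Measurement days since seeding (default three per week over
#'   four weeks).
#' @param treatmentStartDay Day dosing begins (default 7).
#' @param growthRate Vehicle exponential growth rate per day (default 0.08).
#' @param baselineSize Mean tumor size at day 0 (mm^2, default 50).
#' @param animalCv Between-animal baseline size CV (default 0.15).
#' @param noiseCv Per-measurement noise CV (default 0.1).
#' @return A [TumorTrial-class] with arms `vehicle`, `drug_a`, `drug_b`,
#'   `combination`.
#' @export
simTumorTrial <- function(seed, effectA = 0.7, effectB = 0.55, sigma = 1,
                          nAnimals = 8, days = c(0, 3, 5, 7, 10, 12, 14, 17,
                                                 19, 21, 24, 26, 28),
                          treatmentStartDay = 7, growthRate = 0.08,
                          baselineSize = 50, animalCv = 0.15,
                          noiseCv = 0.1) {
  stopifnot(effectA > 0, effectB > 0, sigma > 0,
            max(days) > treatmentStartDay)
  tau <- max(days) - treatmentStartDay
  ## combination growth-rate multiplier giving relative final size
  ## rAB = rA * rB * sigma (rates add where final-size effects multiply)
  effectAB <- effectA + effectB - 1 + log(sigma) / (growthRate * tau)
  mult <- c(vehicle = 1, drug_a = effectA, drug_b = effectB,
            combination = effectAB)
  rows <- list()
  for (arm in names(mult)) {
    for (a in seq_len(nAnimals)) {
      id <- sprintf("%s_%02d", arm, a)
      draws <- .withSeed(.streamSeed(seed, "tumor_animal", id), {
        s0 <- baselineSize * .lnormNoise(1, animalCv)
        meas <- .lnormNoise(length(days), noiseCv)
        aspect <- stats::runif(1, 1.0, 1.5)
        list(s0 = s0, meas = meas, aspect = aspect)
      })
      grown <- ifelse(days <= treatmentStartDay,
                      growthRate * days,
                      growthRate * (treatmentStartDay +
                                      mult[[arm]] * (days - treatmentStartDay)))
      size <- draws$s0 * exp(grown) * draws$meas
      rows[[id]] <- data.frame(
        animal_id = id, group = arm, day = days,
        length_mm = sqrt(size * draws$aspect),
        width_mm = sqrt(size / draws$aspect),
        stringsAsFactors = FALSE)
    }
  }
  TumorTrial(do.call(rbind, rows), treatmentStartDay)
}

#' Simulate a bulk expression cohort with planted signature effects
#'
#' Builds a genes x samples Log2 TPM matrix in which the genes of each
#' signature are shifted, per sample, by a planted effect size on top of a
#' per-gene baseline, plus i.i.d. Gaussian noise. Returns the ground-truth
#' per-sample signature means so scoring can be validated exactly at zero
#' noise.
#'
#' @param seed Integer seed.
#' @param nGenes Size of the gene universe (default 500).
#' @param nSamples Number of samples (default 12).
#' @param signatures Named list of gene symbols, or `NULL` to auto-build
#'   `nSignatures` disjoint 25-gene signatures.
#' @param nSignatures,genesPerSig Used when `signatures` is `NULL`.
#' @param effects Signatures x samples matrix of planted shifts (Log2 TPM
#'   units), or `NULL` to draw them `N(0, 1)` per (signature, sample).
#' @param noiseSd Residual Gaussian noise SD (default 0.25).
#' @return List with `expr` (matrix), `signatures`, `effects`, and `truth`
#'   (signatures x samples matrix of true mean scores).
#' @export
simExpressionCohort <- function(seed, nGenes = 500, nSamples = 12,
                                signatures = NULL, nSignatures = 3,
                                genesPerSig = 25, effects = NULL,
                                noiseSd = 0.25) {
  genes <- sprintf("G%04d", seq_len(nGenes))
  if (is.null(signatures)) {
    stopifnot(nSignatures * genesPerSig <= nGenes)
    signatures <- lapply(seq_len(nSignatures), function(k) {
      genes[seq_len(genesPerSig) + (k - 1L) * genesPerSig]
    })
    names(signatures) <- sprintf("SIG%02d", seq_len(nSignatures))
  }
  stopifnot(all(unlist(signatures) %in% genes))
  samples <- sprintf("S%02d", seq_len(nSamples))
  baseline <- .withSeed(.streamSeed(seed, "cohort_baseline", ""),
                        stats::runif(nGenes, 2, 8))
  names(baseline) <- genes
  if (is.null(effects)) {
    effects <- .withSeed(.streamSeed(seed, "cohort_effects", ""),
                         matrix(stats::rnorm(length(signatures) * nSamples),
                                nrow = length(signatures)))
  }
  stopifnot(nrow(effects) == length(signatures), ncol(effects) == nSamples)
  dimnames(effects) <- list(names(signatures), samples)
  expr <- matrix(rep(baseline, nSamples), ncol = nSamples,
                 dimnames = list(genes, samples))
  for (k in seq_along(signatures)) {
    g <- signatures[[k]]
    expr[g, ] <- expr[g, ] + rep(effects[k, ], each = length(g))
  }
  if (noiseSd > 0) {
    noise <- .withSeed(.streamSeed(seed, "cohort_noise", ""),
                       matrix(stats::rnorm(nGenes * nSamples, sd = noiseSd),
                              nrow = nGenes))
    expr <- expr + noise
  }
  truth <- t(vapply(seq_along(signatures), function(k) {
    mean(baseline[signatures[[k]]]) + effects[k, ]
  }, numeric(nSamples)))
  dimnames(truth) <- dimnames(effects)
  list(expr = expr, signatures = signatures, effects = effects, truth = truth)
}

#' Simulate single-cell QC metrics with planted outliers
#'
#' Generates per-cell QC metrics for one sample. Baseline cells are drawn
#' multiplicatively but *bounded*: uniform within +/- 2 raw MADs of the
#' sample center, so no baseline cell can cross a 3-MAD fence and the
#' planted outliers are exactly recoverable. Outliers are planted at
#' `outlierMads` (>= 6 by default) raw MADs from the nCount/nFeature median,
#' alternating direction, and mitochondrial outliers above the 25\% hard
#' ceiling.
#'
#' @param seed Integer seed.
#' @param nCells Cells in the sample (default 500).
#' @param nCountOutliers Planted nCount/nFeature outliers (default 10).
#' @param mitoOutliers Planted high-mitochondrial outliers (default 5).
#' @param outlierMads How many raw MADs out the count outliers sit
#'   (default 6.5).
#' @param sample Sample identifier.
#' @return List with `metrics` (`data.frame`: `cell_id`, `sample`,
#'   `nFeature`, `nCount`, `percent_mt`) and `truth` (character vector of
#'   planted outlier cell ids).
#' @export
simCellQcMetrics <- function(seed, nCells = 500, nCountOutliers = 10,
                             mitoOutliers = 5, outlierMads = 6.5,
                             sample = "S1") {
  nOut <- nCountOutliers + mitoOutliers
  if (nOut >= nCells) stop("planted outliers must be fewer than nCells")
  countCenter <- 10000; countHalf <- 2000   # uniform => MAD = half/2
  mtLo <- 2; mtHi <- 10
  ids <- sprintf("%s_cell%04d", sample, seq_len(nCells))
  base <- .withSeed(.streamSeed(seed, "cellqc", sample), {
    nCount <- stats::runif(nCells, countCenter - countHalf,
                           countCenter + countHalf)
    pmt <- stats::runif(nCells, mtLo, mtHi)
    list(nCount = nCount, pmt = pmt)
  })
  nCount <- base$nCount
  pmt <- base$pmt
  truth <- character()
  if (nCountOutliers > 0) {
    idx <- seq_len(nCountOutliers)
    mad0 <- countHalf / 2
    dirs <- rep(c(1, -1), length.out = nCountOutliers)
    offs <- .withSeed(.streamSeed(seed, "cellqc_out", sample),
                      stats::runif(nCountOutliers, outlierMads,
                                   outlierMads + 2))
    nCount[idx] <- countCenter + dirs * offs * mad0
    truth <- c(truth, ids[idx])
  }
  if (mitoOutliers > 0) {
    idx <- nCountOutliers + seq_len(mitoOutliers)
    offs <- .withSeed(.streamSeed(seed, "cellqc_mito", sample),
                      stats::runif(mitoOutliers, 30, 45))
    pmt[idx] <- offs
    truth <- c(truth, ids[idx])
  }
  metrics <- data.frame(
    cell_id = ids, sample = sample,
    nFeature = round(nCount * 0.35),
    nCount = round(nCount),
    percent_mt = pmt,
    stringsAsFactors = FALSE)
  list(metrics = metrics, truth = truth)
}
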