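#' Read tumor measurements into a TumorTrial
#'
#' Reads a measurement log CSV with columns `animal_id`, `group`, `day`,
#' `length_mm`, `width_mm`. Tumor size is computed as length x width (mm^2).
#'
#' @param path Path to the CSV.
#' @param treatmentStartDay Day (since seeding) treatment began.
#' @return A [TumorTrial-class].
#' @export
readTumorCsv <- function(path, treatmentStartDay = 0L) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  TumorTrial(m, treatmentStartDay)
}

#' @rdname readTumorCsv
#' @param trial A [TumorTrial-class] to write.
#' @export
writeTumorCsv <- function(trial, path) {
  m <- measurements(trial)
  utils::write.csv(m[c("animal_id", "group", "day", "length_mm", "width_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Final sizes per animal: default is per-protocol (only animals measured on
## the trial's last day); carryForward = TRUE instead takes each animal's
## last observation.
.finalSizes <- function(trial, carryForward = FALSE) {
  m <- measurements(trial)
  if (carryForward) {
    last <- do.call(rbind, lapply(split(m, m$animal_id), function(a) {
      a[which.max(a$day), , drop = FALSE]
    }))
  } else {
    fday <- max(m$day)
    last <- m[m$day == fday, , drop = FALSE]
  }
  rownames(last) <- NULL
  last
}

#' Per-group summary of final tumor size
#'
#' Mean, SEM and n of tumor size per treatment arm at the final measurement
#' day. By default "final" is the last day of the trial and animals without a
#' measurement on that day (e.g. euthanized early) are excluded
#' (per-protocol); with `carryForward = TRUE` each animal contributes its
#' last observed size.
#'
#' @param trial A [TumorTrial-class].
#' @param carryForward Use last observation for animals missing the final
#'   day (default `FALSE`).
#' @return `data.frame` with columns `group`, `mean_size`, `sem`, `n`,
#'   `final_day`.
#' @export
summarizeFinal <- function(trial, carryForward = FALSE) {
  last <- .finalSizes(trial, carryForward)
  groups <- unique(measurements(trial)$group)
  empty <- setdiff(groups, unique(last$group))
  if (length(empty))
    stop("no animals measured at the final day in group(s): ",
         paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(last, last$group), function(g) {
    data.frame(group = g$group[1],
               mean_size = mean(g$size_mm2),
               sem = if (nrow(g) > 1) .sem(g$size_mm2) else NA_real_,
               n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out$final_day <- max(last$day)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD on final tumor sizes
#'
#' Tests for any difference in final tumor size across treatment arms
#' (one-way ANOVA) and returns Tukey-adjusted p-values for every arm pair.
#' When the final sizes carry essentially no variance at all (all arms
#' identical) the test degenerates to p = 1 rather than failing.
#'
#' @inheritParams summarizeFinal
#' @return List with `anovaP` (overall p), `tukey` (named numeric of adjusted
#'   p per `"a-b"` pair), and `finalDay`.
#' @export
finalMeasureAnova <- function(trial, carryForward = FALSE) {
  last <- .finalSizes(trial, carryForward)
  grp <- factor(last$group)
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 2L)) stop("need at least 2 animals per group")
  size <- last$size_mm2
  pairs <- utils::combn(levels(grp), 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  if (stats::sd(size) < 1e-12 * max(abs(size), 1)) {
    tukey <- stats::setNames(rep(1, ncol(pairs)), pair_names)
    return(list(anovaP = 1, tukey = tukey, finalDay = max(last$day)))
  }
  fit <- stats::aov(size ~ grp)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$grp
  tukey <- stats::setNames(tk[, "p adj"], rownames(tk))
  list(anovaP = p, tukey = tukey, finalDay = max(last$day))
}

#' In-vivo coefficient of drug interaction
#'
#' Scores in-vivo synergy of a four-arm trial (vehicle, drug A, drug B,
#' combination) on final tumor size: each arm's mean final size is expressed
#' relative to vehicle, \eqn{r_g = \bar S_g / \bar S_{vehicle}}, and
#' \deqn{CDI = r_{AB} / (r_A r_B).} If the single-agent effects combined
#' independently the combination arm would show the product of the relative
#' single-agent sizes; CDI < 1 means the combination shrank tumors beyond
#' that expectation. The value is classified with [classifyCdi()].
#'
#' @inheritParams summarizeFinal
#' @param arms Named character of length 4 mapping roles `vehicle`, `drugA`,
#'   `drugB`, `combination` to group labels in the trial.
#' @param center `"mean"` (default) or `"median"` group summary of final
#'   sizes.
#' @param additiveTolerance Passed to [classifyCdi()].
#' @return List with the relative sizes `rA`, `rB`, `rAB`, the `cdi`, its
#'   `label`, and `finalDay`.
#' @examples
#' ## vehicle 100, A 80, B 60, combo 24 -> CDI = 0.5
#' @export
invivoCdi <- function(trial,
                      arms = c(vehicle = "vehicle", drugA = "drug_a",
                               drugB = "drug_b", combination = "combination"),
                      carryForward = FALSE, center = c("mean", "median"),
                      additiveTolerance = 0.05) {
  center <- match.arg(center)
  stopifnot(all(c("vehicle", "drugA", "drugB", "combination") %in% names(arms)))
  last <- .finalSizes(trial, carryForward)
  missing_arms <- setdiff(unname(arms), unique(last$group))
  if (length(missing_arms))
    stop("arm(s) absent from the trial at the final day: ",
         paste(missing_arms, collapse = ", "))
  cen <- if (center == "mean") mean else stats::median
  msize <- vapply(arms, function(g) cen(last$size_mm2[last$group == g]),
                  numeric(1))
  if (msize[["vehicle"]] <= 0) stop("vehicle mean final size must be > 0")
  r <- msize / msize[["vehicle"]]
  cdi <- computeCdi(r[["drugA"]], r[["drugB"]], r[["combination"]])
  list(rA = r[["drugA"]], rB = r[["drugB"]], rAB = r[["combination"]],
       cdi = cdi, label = classifyCdi(cdi, additiveTolerance),
       finalDay = max(last$day))
}
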