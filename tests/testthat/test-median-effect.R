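test_that("noiseless median-effect data are recovered exactly", {
  D <- c(1, 2, 4, 8, 16, 32)
  fit <- fitMedianEffect(D, oracle_fa(D, m = 2, Dm = 5))
  expect_equal(hillSlope(fit), 2, tolerance = 1e-10)
  expect_equal(medianDose(fit), 5, tolerance = 1e-10)
  expect_equal(fitCor(fit), 1, tolerance = 1e-12)
  ## D = Dm gives fa = 0.5 on the fitted curve regardless of slope
  expect_equal(faAtDose(fit, medianDose(fit)), 0.5, tolerance = 1e-10)
})

test_that("out-of-range fa values are clipped with a warning, not dropped", {
  D <- c(1, 2, 4, 8)
  fa <- c(-0.02, 0.3, 0.6, 0.9)  # viability above vehicle at the low dose
  expect_warning(fit <- fitMedianEffect(D, fa), "clipped")
  expect_s4_class(fit, "MedianEffectFit")
  expect_equal(fit@nPoints, 4L)
})

test_that("degenerate inputs error and inverted responses are flagged", {
  expect_error(fitMedianEffect(c(1, 2), c(0.3, 0.6)), "at least 3")
  expect_error(fitMedianEffect(c(0, 0, 0), c(0.2, 0.4, 0.6)), "at least 3")
  D <- c(1, 2, 4, 8)
  expect_warning(fit <- fitMedianEffect(D, c(0.9, 0.7, 0.4, 0.2)),
                 "flagged")
  expect_true(isFlagged(fit))
  expect_error(doseForEffect(fit, 0.5), "flagged")
})

test_that("dose_for_effect inverts the median-effect equation", {
  f <- MedianEffectFit(m = 1, Dm = 2)
  expect_equal(doseForEffect(f, 0.5), 2)
  expect_equal(doseForEffect(f, 0.75), 6)  # 2 * (0.75/0.25)^1
  expect_error(doseForEffect(f, 1), "strictly inside")
  expect_error(doseForEffect(f, 0), "strictly inside")
  ## mutual inverses to machine precision, and fa(D) strictly increasing
  for (m in c(0.6, 1, 2.3)) {
    fit <- MedianEffectFit(m, Dm = 3.7)
    fa <- seq(0.02, 0.98, by = 0.04)
    expect_equal(faAtDose(fit, doseForEffect(fit, fa)), fa,
                 tolerance = 1e-12)
    D <- seq(0.1, 50, length.out = 40)
    expect_true(all(diff(faAtDose(fit, D)) > 0))
  }
})

test_that("noisy recovery agrees with the exhaustive grid-search oracle", {
  for (s in 1:5) {
    tb <- simDoseResponse(s, m = 1.5, Dm = 2, doses = canonical_doses(2),
                          replicates = 3, noiseCv = 0.05)
    nv <- suppressWarnings(normalizeViability(tb))
    fa <- fa_from_normalized(nv)
    fit <- suppressWarnings(fitMedianEffect(nv$dose_uM, fa))
    grid <- oracle_grid_fit(nv$dose_uM, pmin(pmax(fa, 0.005), 0.995))
    expect_equal(hillSlope(fit), unname(grid["m"]), tolerance = 0.01)
    expect_equal(medianDose(fit), unname(grid["Dm"]), tolerance = 0.01)
  }
})

test_that("a drug combined with itself gives CI = 1 at every fa", {
  fit <- MedianEffectFit(m = 1.3, Dm = 4)
  des <- ComboDesign(c(1, 3), 2^seq(-2, 4))
  fa <- seq(0.05, 0.95, by = 0.05)
  expect_equal(ciAtFa(fit, fit, fit, des, fa), rep(1, length(fa)),
               tolerance = 1e-12)
  prof <- ciDriProfile(fit, fit, fit, des)
  expect_equal(prof@ci, rep(1, 99), tolerance = 1e-12)
})

test_that("CI on a matched-slope Loewe-additive surface is 1 across fa", {
  fA <- MedianEffectFit(m = 1, Dm = 2)
  fB <- MedianEffectFit(m = 1, Dm = 4)
  des <- ComboDesign(c(1, 1), exp(seq(log(0.05), log(80), length.out = 10)))
  tbl <- simCombinationSurface(1, fA, fB, des, model = "loewe")
  nv <- normalizeViability(tbl)
  fa <- fa_from_normalized(nv)
  ok <- fa > 0.005 & fa < 0.995
  fc <- fitMedianEffect(nv$dose_uM[ok], fa[ok])
  ci <- ciAtFa(fA, fB, fc, des, seq(0.1, 0.9, by = 0.02))
  expect_true(all(abs(ci - 1) < 0.05))
})

test_that("CI is invariant to relabeling the two drugs", {
  fA <- MedianEffectFit(1.4, 2); fB <- MedianEffectFit(1.4, 7)
  fc <- MedianEffectFit(1.4, 3)
  des <- ComboDesign(c(2, 1), 2^seq(-2, 4))
  swapped <- ComboDesign(c(1, 2), 2^seq(-2, 4))
  fa <- seq(0.1, 0.9, by = 0.1)
  expect_equal(ciAtFa(fA, fB, fc, des, fa),
               ciAtFa(fB, fA, fc, swapped, fa), tolerance = 1e-12)
})

test_that("Bliss-independent surfaces of unequal drugs do not sit at CI = 1", {
  fA <- MedianEffectFit(1, 1); fB <- MedianEffectFit(2, 8)
  des <- ComboDesign(c(1, 1), exp(seq(log(0.2), log(60), length.out = 10)))
  tbl <- simCombinationSurface(1, fA, fB, des, model = "bliss")
  nv <- normalizeViability(tbl)
  fa <- fa_from_normalized(nv)
  ok <- fa > 0.005 & fa < 0.995
  fc <- fitMedianEffect(nv$dose_uM[ok], fa[ok])
  ci <- ciAtFa(fA, fB, fc, des, seq(0.1, 0.9, by = 0.1))
  expect_gt(max(abs(ci - 1)), 0.02)
})

test_that("DRI identities hold: no-reduction and half-dose cases", {
  ## combination achieving fa at exactly half of each single-agent dose
  fA <- MedianEffectFit(1, 2); fB <- MedianEffectFit(1, 2)
  fc <- MedianEffectFit(1, 1)  # total dose 1 = 0.5 + 0.5 at fa = 0.5
  des <- ComboDesign(c(1, 1), 2^seq(-2, 3))
  dri <- driAtFa(fA, fB, fc, des, 0.5)
  expect_equal(dri$driA, 4)  # Dx = 2, component dose 0.5
  expect_equal(dri$driB, 4)
  ## d_i == Dx_i means DRI = 1: self-combination at equal split of 2x dose
  fc2 <- MedianEffectFit(1, 4)
  dri2 <- driAtFa(fA, fB, fc2, des, 0.5)
  expect_equal(dri2$driA, 1)
  expect_equal(dri2$driB, 1)
})

test_that("profiles equal point-wise recomputation and mark the ROI", {
  fA <- MedianEffectFit(1.2, 1.5); fB <- MedianEffectFit(1.2, 6)
  fc <- MedianEffectFit(1.25, 2.2)
  des <- ComboDesign(c(1, 2), 2^seq(-2, 4))
  prof <- ciDriProfile(fA, fB, fc, des)
  for (i in c(1, 25, 50, 75, 99)) {
    expect_equal(prof@ci[i], ciAtFa(fA, fB, fc, des, prof@fa[i]))
    dri <- driAtFa(fA, fB, fc, des, prof@fa[i])
    expect_equal(prof@driA[i], dri$driA)
    expect_equal(prof@driB[i], dri$driB)
  }
  expect_equal(prof@roi, prof@fa >= 0.75)
  single <- ciDriProfile(fA, fB, fc, des, faGrid = 0.4)
  expect_equal(single@ci, ciAtFa(fA, fB, fc, des, 0.4))
  expect_error(ciDriProfile(fA, fB, fc, des, faGrid = numeric()), "non-empty")
  df <- as.data.frame(prof)
  expect_named(df, c("fa", "ci", "dri_a", "dri_b", "roi"))
})

test_that("the non-exclusive CI adds the cross term", {
  fA <- MedianEffectFit(1, 2); fB <- MedianEffectFit(1, 4)
  fc <- MedianEffectFit(1, 2.5)
  des <- ComboDesign(c(1, 1), 2^seq(-2, 3))
  fa <- 0.6
  two <- ciAtFa(fA, fB, fc, des, fa)
  three <- ciAtFa(fA, fB, fc, des, fa, exclusive = FALSE)
  D <- doseForEffect(fc, fa)
  cross <- (D / 2) * (D / 2) / (doseForEffect(fA, fa) * doseForEffect(fB, fa))
  expect_equal(three, two + cross)
})
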