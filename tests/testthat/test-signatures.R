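toy_expr <- function(nGenes = 50, nSamples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nGenes * nSamples, 0, 10), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", 1:nGenes),
                              sprintf("S%d", 1:nSamples)))
  m
}

test_that("signature scores are per-sample means over present genes", {
  expr <- toy_expr()
  sigs <- list(s1 = rownames(expr)[1:10], s2 = rownames(expr)[11:12],
               s3 = rownames(expr)[30])
  prof <- scoreSignatures(expr, sigs)
  sc <- profileScores(prof)
  for (k in names(sigs)) {
    expect_equal(sc[k, ], colMeans(expr[sigs[[k]], , drop = FALSE]))
  }
  ## single-gene signature equals the gene's row
  expect_equal(unname(sc["s3", ]), unname(expr[sigs$s3, ]))
  ## constant matrix gives the constant everywhere
  const <- matrix(3.5, 4, 2, dimnames = list(letters[1:4], c("x", "y")))
  expect_true(all(profileScores(
    scoreSignatures(const, list(s = c("a", "c")))) == 3.5))
})

test_that("scores ignore gene order and genes absent from the matrix", {
  expr <- toy_expr()
  g <- rownames(expr)[5:14]
  a <- scoreSignatures(expr, list(s = g))
  b <- scoreSignatures(expr, list(s = rev(g)))
  expect_equal(profileScores(a), profileScores(b))
  expect_warning(
    c_ <- scoreSignatures(expr, list(s = c(g, "NOT_A_GENE"))), "absent")
  expect_equal(profileScores(c_), profileScores(a))
  expect_equal(unname(nGenesUsed(c_)["s"]), 10L)
  expect_error(scoreSignatures(expr, list(s = c("NOPE1", "NOPE2"))),
               "no signature")
})

test_that("profile clustering matches the naive average-linkage oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    m <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("p", 1:n), paste0("s", 1:8)))
    cl <- clusterProfiles(m)
    d <- 1 - cor(t(m))
    oracle <- oracle_average_linkage(as.dist(d))
    expect_equal(sort(cl$rows$height), sort(oracle$heights),
                 tolerance = 1e-10)
    expect_equal(as.matrix(stats::cophenetic(cl$rows))[rownames(m), rownames(m)],
                 `dimnames<-`(oracle$cophenetic, list(rownames(m), rownames(m))),
                 tolerance = 1e-10)
  }
})

test_that("duplicated and anti-correlated profiles behave as expected", {
  m <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  m[2, ] <- m[1, ]            # duplicate row: correlation distance 0
  cl <- clusterProfiles(m)
  expect_equal(min(cl$rows$height), 0, tolerance = 1e-12)
  m2 <- m
  m2[2, ] <- -m[1, ]          # perfectly anti-correlated: distance 2
  d <- 1 - cor(t(m2))
  expect_equal(d["p1", "p2"], 2, tolerance = 1e-12)
  flat <- m
  flat[3, ] <- 7
  expect_error(clusterProfiles(flat), "p3")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  expr <- toy_expr()
  sigs <- lapply(split(rownames(expr)[1:40], rep(1:4, each = 10)), identity)
  names(sigs) <- paste0("sig", 1:4)
  prof <- scoreSignatures(expr, sigs)
  ps <- profileSimilarity(prof)
  R <- ps$similarity
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(ps$summary$nPairs, choose(4, 2))
  expect_equal(R, cor(t(profileScores(prof))))  # direct formula
  ## identical rows correlate at 1; affine transforms leave R unchanged
  m <- profileScores(prof)
  m2 <- rbind(m, dup = m[1, ])
  R2 <- profileSimilarity(m2)$similarity
  expect_equal(R2["sig1", "dup"], 1, tolerance = 1e-12)
  m3 <- m; m3[2, ] <- 3 * m[2, ] + 5
  expect_equal(profileSimilarity(m3)$similarity, R, tolerance = 1e-12)
  ## 14 profiles enumerate 91 unordered pairs
  big <- matrix(rnorm(14 * 6), 14, 6,
                dimnames = list(paste0("p", 1:14), paste0("s", 1:6)))
  expect_equal(profileSimilarity(big)$summary$nPairs, 91)
})

test_that("percent positivity counts cells above zero per model", {
  expr <- matrix(0, 3, 5,
                 dimnames = list(c("PIK3CA", "AKT1", "AKT2"),
                                 paste0("c", 1:5)))
  expr["PIK3CA", ] <- c(1, 0, 2, 0, 3)
  expr["AKT1", ] <- c(1, 1, 0, 0, 0)
  expr["AKT2", ] <- c(0, 1, 0, 0, 1)
  groups <- c("M1", "M1", "M1", "M2", "M2")
  pp <- percentPositive(expr, "PIK3CA", groups)
  expect_equal(unname(pp), c(100 * 2 / 3, 50))
  ## averaged multi-gene mode thresholds the per-cell mean
  pa <- percentPositive(expr, c("AKT1", "AKT2"), groups)
  expect_equal(unname(pa), c(100 * 2 / 3, 50))
  ## all-zero and strictly positive genes
  zero <- matrix(0, 1, 4, dimnames = list("g", paste0("c", 1:4)))
  expect_equal(unname(percentPositive(zero, "g", rep("M", 4))), 0)
  pos <- zero + 1
  expect_equal(unname(percentPositive(pos, "g", rep("M", 4))), 100)
  expect_error(percentPositive(expr, "MISSING", groups), "absent")
})

test_that("signature-restricted PCA equals full PCA when unrestricted", {
  expr <- toy_expr(20, 15)
  full <- stats::prcomp(t(expr), center = TRUE, scale. = TRUE)
  res <- signaturePca(expr, rownames(expr), k = 3)
  for (j in 1:3) {
    ## components match up to sign
    agree <- abs(sum(res$scores[, j] * full$x[, j])) /
      sqrt(sum(res$scores[, j]^2) * sum(full$x[, j]^2))
    expect_equal(agree, 1, tolerance = 1e-10)
  }
  ## scores centered, components orthogonal
  expect_equal(unname(colMeans(res$scores)), rep(0, 3), tolerance = 1e-10)
  cross <- crossprod(res$scores)
  expect_equal(unname(cross[upper.tri(cross)]), rep(0, 3), tolerance = 1e-8)
})

test_that("rank-1 data recover the planted direction up to sign", {
  set.seed(8)
  u <- rnorm(12); v <- rnorm(30)
  expr <- outer(v, u)  # genes x cells, rank 1
  rownames(expr) <- sprintf("g%02d", 1:30)
  colnames(expr) <- sprintf("c%02d", 1:12)
  res <- signaturePca(expr, rownames(expr), k = 1, scale = FALSE)
  sc <- res$scores[, 1]
  cc <- abs(cor(sc, u))
  expect_equal(cc, 1, tolerance = 1e-8)
})

test_that("PCA handles sparse signatures and rank limits", {
  expr <- toy_expr(20, 10)
  expect_warning(
    res <- signaturePca(expr, c(rownames(expr)[1:2], "GONE1", "GONE2"), k = 1),
    "absent")
  expect_equal(ncol(res$scores), 1L)
  expect_length(res$genes, 2L)
  expect_error(signaturePca(expr, rownames(expr)[1:3], k = 3), "rank")
  expect_error(signaturePca(expr, c("GONE1", "GONE2"), k = 1), "fewer than 2")
})

test_that("antibody arrays normalize to background and positive controls", {
  ## probe identical to the single positive control normalizes to 1
  norm <- normalizeAntibodyArray(raw = c(p1 = 500), background = 50,
                                 posRaw = 500, posBackground = 50)
  expect_equal(unname(norm), 1)
  ## 4-probe membrane against hand arithmetic
  raw <- c(a = 200, b = 400, c = 100, d = 800)
  bg <- c(20, 20, 10, 40)
  posRaw <- c(600, 640); posBg <- c(30, 32)
  norm2 <- normalizeAntibodyArray(raw, bg, posRaw, posBg)
  expect_equal(unname(norm2), (raw / bg) / mean(posRaw / posBg),
               ignore_attr = TRUE)
  ## doubling exposure globally changes nothing
  norm3 <- normalizeAntibodyArray(raw * 2, bg, posRaw * 2, posBg)
  expect_equal(norm3, norm2, tolerance = 1e-12)
  expect_error(normalizeAntibodyArray(raw, c(0, 1, 1, 1), posRaw, posBg),
               "positive")
  ## fold changes align probes by name
  fc <- arrayFoldChange(norm2 * 2, norm2)
  expect_equal(unname(fc), rep(2, 4))
})

test_that("expression matrices and signatures round-trip through disk", {
  expr <- toy_expr(10, 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readExpressionTsv(tsv)
  expect_equal(back, expr, tolerance = 1e-12)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG001\tG002", "setB\tdesc\tG005"), gmt)
  sigs <- readGmt(gmt)
  expect_equal(sigs, list(setA = c("G001", "G002"), setB = "G005"))
  lst <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G001", "g002", ""), lst)
  expect_equal(readGeneList(lst, "pi3k")$pi3k, c("G001", "G002"))
})
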