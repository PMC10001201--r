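#' MAD-based single-cell quality-control filter
#'
#' Filters cells on three per-cell metrics — genes detected (`nFeature`),
#' molecules detected (`nCount`), and percent mitochondrial expression
#' (`percent_mt`) — with cutoffs derived per sample from the median and the
#' raw median absolute deviation (MAD, no consistency scaling by default):
#'
#' * a cell is removed if `nFeature` or `nCount` lies strictly more than
#'   `nMads` MADs from its sample median, in either direction;
#' * the mitochondrial median and MAD are computed only over cells with
#'   `percent_mt <= mtMedianCap` (default 50, so grossly dying cells do not
#'   drag the center up), and a cell is removed if its `percent_mt` exceeds
#'   `min(median + nMads * MAD, hardMtCutoff)` — the 3-MAD fence or the hard
#'   25\% ceiling, whichever is lower.
#'
#' Comparisons are strict (`>`), so a degenerate sample of identical cells
#' (MAD = 0) keeps every cell. Removing all cells of a sample is allowed but
#' warned about.
#'
#' @param metrics `data.frame` with columns `sample`, `nFeature`, `nCount`,
#'   `percent_mt` (optionally `cell_id`; generated if absent).
#' @param nMads Number of MADs for the fences (default 3).
#' @param hardMtCutoff Hard ceiling on percent mitochondrial (default 25).
#' @param madConstant Consistency constant passed to [stats::mad()]
#'   (default 1, the raw MAD).
#' @param mtMedianCap Only cells at or below this percent_mt enter the
#'   mitochondrial median/MAD (default 50).
#' @return List with `keep` (logical mask, one per row of `metrics`, named by
#'   cell id) and `cutoffs` (`data.frame` per sample: the nFeature/nCount
#'   fences and the mitochondrial cutoff).
#' @export
qcFilterCells <- function(metrics, nMads = 3, hardMtCutoff = 25,
                          madConstant = 1, mtMedianCap = 50) {
  need <- c("sample", "nFeature", "nCount", "percent_mt")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(metrics) < 1L) stop("need at least one cell")
  if (any(metrics$nFeature > metrics$nCount))
    stop("nFeature cannot exceed nCount")
  if (any(metrics$percent_mt < 0 | metrics$percent_mt > 100))
    stop("percent_mt must lie in [0, 100]")
  if (is.null(metrics$cell_id))
    metrics$cell_id <- sprintf("cell%06d", seq_len(nrow(metrics)))

  keep <- rep(TRUE, nrow(metrics))
  cutoffs <- list()
  for (s in unique(metrics$sample)) {
    idx <- which(metrics$sample == s)
    sub <- metrics[idx, , drop = FALSE]
    fence <- function(x) {
      med <- stats::median(x)
      dev <- nMads * stats::mad(x, constant = madConstant)
      c(lo = med - dev, hi = med + dev)
    }
    ff <- fence(sub$nFeature)
    fc <- fence(sub$nCount)
    mt_ok <- sub$percent_mt <= mtMedianCap
    if (any(mt_ok)) {
      mt_med <- stats::median(sub$percent_mt[mt_ok])
      mt_mad <- stats::mad(sub$percent_mt[mt_ok], constant = madConstant)
      mt_cut <- min(mt_med + nMads * mt_mad, hardMtCutoff)
    } else {
      mt_cut <- hardMtCutoff
    }
    bad <- sub$nFeature < ff["lo"] | sub$nFeature > ff["hi"] |
      sub$nCount < fc["lo"] | sub$nCount > fc["hi"] |
      sub$percent_mt > mt_cut
    keep[idx] <- !bad
    if (all(bad)) warning("all cells removed in sample '", s, "'")
    cutoffs[[s]] <- data.frame(
      sample = s, nFeature_lo = ff[["lo"]], nFeature_hi = ff[["hi"]],
      nCount_lo = fc[["lo"]], nCount_hi = fc[["hi"]], mt_cutoff = mt_cut,
      stringsAsFactors = FALSE)
  }
  cutoffs <- do.call(rbind, cutoffs)
  rownames(cutoffs) <- NULL
  list(keep = stats::setNames(keep, metrics$cell_id), cutoffs = cutoffs)
}

#' Read/write sparse cell count matrices (MatrixMarket)
#'
#' Thin wrappers over [Matrix::readMM()] with gene and barcode sidecar files
#' (one symbol / barcode per line), the plain-text exchange format for
#' single-cell counts.
#'
#' @param mtxPath,genesPath,barcodesPath Paths to the `.mtx` matrix and its
#'   row/column sidecars.
#' @return `readCellCounts()`: a sparse `dgCMatrix`, genes x cells.
#' @export
readCellCounts <- function(mtxPath, genesPath, barcodesPath) {
  m <- methods::as(Matrix::readMM(mtxPath), "CsparseMatrix")
  genes <- readLines(genesPath)
  barcodes <- readLines(barcodesPath)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("sidecar lengths do not match the matrix dimensions")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' @rdname readCellCounts
#' @param counts Sparse or dense genes x cells matrix with dimnames.
#' @export
writeCellCounts <- function(counts, mtxPath, genesPath, barcodesPath) {
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), mtxPath)
  writeLines(rownames(counts), genesPath)
  writeLines(colnames(counts), barcodesPath)
  invisible(mtxPath)
}

#' Log-normalize cell counts
#'
#' The common per-cell scaling: counts are scaled so every cell sums to
#' `scaleFactor` (default 10,000) and then log1p-transformed.
#'
#' @param counts Genes x cells matrix (sparse or dense).
#' @param scaleFactor Per-cell target sum (default 1e4).
#' @return Dense numeric matrix of log-normalized values.
#' @export
logNormalizeCounts <- function(counts, scaleFactor = 1e4) {
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) stop("cells with zero total counts cannot be normalized")
  m <- as.matrix(counts)
  log1p(sweep(m, 2, cs, "/") * scaleFactor)
}
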