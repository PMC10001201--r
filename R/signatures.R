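#' Read a bulk expression matrix (genes x samples TSV)
#'
#' First column = gene symbol, remaining columns = samples; values Log2 TPM.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

#' Read gene signatures
#'
#' `readGmt()` reads GMT (one signature per line: name, description, then
#' genes, tab-separated); `readGeneList()` reads a one-symbol-per-line text
#' file as a single signature.
#'
#' @param path Path to the file.
#' @return Named list of character vectors (gene symbols, upper-cased,
#'   de-duplicated).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >= 1 gene)")
    unique(toupper(trimws(parts[-(1:2)])))
  })
  names(sigs) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1))
  sigs
}

#' @rdname readGmt
#' @param name Signature name for the gene list.
#' @export
readGeneList <- function(path, name = basename(path)) {
  genes <- trimws(readLines(path))
  genes <- unique(toupper(genes[nzchar(genes)]))
  if (length(genes) == 0L) stop("empty gene list: ", path)
  stats::setNames(list(genes), name)
}

#' Score gene signatures on an expression matrix
#'
#' The score of signature s in sample j is the mean Log2 TPM over the
#' signature genes present in the matrix. Signature genes absent from the
#' matrix are dropped with a warning; a signature with no gene present gets
#' `NA` scores (all signatures empty is an error). Single genes can be
#' supplied as one-gene signatures.
#'
#' @param expr Numeric matrix, genes x samples, gene symbols as rownames.
#' @param signatures Named list of character vectors of gene symbols.
#' @return A [SignatureProfiles-class] (signatures x samples score matrix).
#' @export
scoreSignatures <- function(expr, signatures) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.null(names(signatures)) || any(!nzchar(names(signatures))))
    stop("signatures must be a named list")
  if (any(vapply(signatures, length, integer(1)) == 0L))
    stop("signatures must be non-empty")
  present <- lapply(signatures, function(g) intersect(unique(g),
                                                      rownames(expr)))
  nUsed <- vapply(present, length, integer(1))
  if (all(nUsed == 0L))
    stop("no signature has any gene present in the expression matrix")
  dropped <- mapply(function(g, p) length(unique(g)) - length(p),
                    signatures, present)
  if (any(dropped > 0))
    warning(sum(dropped), " signature gene(s) absent from the matrix were dropped")
  scores <- t(vapply(present, function(g) {
    if (length(g) == 0L) return(rep(NA_real_, ncol(expr)))
    colMeans(expr[g, , drop = FALSE])
  }, numeric(ncol(expr))))
  colnames(scores) <- colnames(expr)
  methods::new("SignatureProfiles", scores = scores, nGenesUsed = nUsed)
}

.pearsonDist <- function(m, what) {
  v <- apply(m, 1, stats::sd)
  if (any(v == 0))
    stop("zero-variance ", what, ": ",
         paste(rownames(m)[v == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Cluster signature profiles (rows and columns)
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' correlation distance d = 1 - Pearson r, applied independently to the
#' signature rows and the sample columns of the score matrix — the standard
#' heat-map ordering for signature-by-model profiles.
#'
#' @param profiles A [SignatureProfiles-class] or a plain numeric matrix.
#' @return List with `rows` and `cols` (`hclust` objects) and `rowOrder`,
#'   `colOrder` (leaf-order labels).
#' @export
clusterProfiles <- function(profiles) {
  m <- if (methods::is(profiles, "SignatureProfiles"))
    profileScores(profiles) else profiles
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  hr <- stats::hclust(.pearsonDist(m, "profile row(s)"), method = "average")
  hc <- stats::hclust(.pearsonDist(t(m), "sample column(s)"),
                      method = "average")
  list(rows = hr, cols = hc,
       rowOrder = rownames(m)[hr$order], colOrder = colnames(m)[hc$order])
}

#' Pairwise similarity of signature profiles
#'
#' All-by-all Pearson correlation of the signature score rows across samples,
#' with a summary of the off-diagonal extremes and the number of
#' negatively-correlated pairs out of the C(k, 2) unordered pairs.
#'
#' @param profiles A [SignatureProfiles-class] or numeric matrix
#'   (signatures x samples).
#' @return List with `similarity` (symmetric k x k matrix, unit diagonal) and
#'   `summary` (list: `min`, `max`, `negativePairs`, `nPairs`).
#' @export
profileSimilarity <- function(profiles) {
  m <- if (methods::is(profiles, "SignatureProfiles"))
    profileScores(profiles) else profiles
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  v <- apply(m, 1, stats::sd)
  if (any(v == 0))
    stop("zero-variance profile(s): ",
         paste(rownames(m)[v == 0], collapse = ", "))
  R <- stats::cor(t(m))
  off <- R[upper.tri(R)]
  list(similarity = R,
       summary = list(min = min(off), max = max(off),
                      negativePairs = sum(off < 0), nPairs = length(off)))
}

#' Percent of cells positive for a gene (or gene-set mean)
#'
#' Fraction of cells per model/sample with expression strictly above zero.
#' With several genes and `average = TRUE` (the multi-gene mode, e.g.
#' AKT1/AKT2/AKT3) the per-cell mean over the genes is thresholded instead.
#'
#' @param expr Numeric matrix, genes x cells.
#' @param genes Gene symbol(s) to assess; must be present in the matrix.
#' @param groups Character/factor of length `ncol(expr)` assigning cells to
#'   models.
#' @param average Average the genes per cell before thresholding (default
#'   `TRUE` when several genes are given).
#' @return If one value per group: named numeric of percent positive; with
#'   `average = FALSE` and several genes, a genes x groups matrix.
#' @export
percentPositive <- function(expr, genes, groups,
                            average = length(genes) > 1L) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr))
  if (ncol(expr) == 0L) stop("no cells in the expression matrix")
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes))
    stop("gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  groups <- as.factor(groups)
  pct <- function(val) {
    vapply(split(val > 0, groups), function(z) 100 * mean(z), numeric(1))
  }
  if (average || length(genes) == 1L) {
    val <- if (length(genes) == 1L) expr[genes, ]
           else colMeans(expr[genes, , drop = FALSE])
    pct(val)
  } else {
    t(vapply(genes, function(g) pct(expr[g, ]),
             numeric(nlevels(groups))))
  }
}

#' Signature-restricted principal component analysis
#'
#' PCA of cells on the expression submatrix restricted to the genes of one
#' signature (instead of the most variable genes), the embedding used to lay
#' out cells by pathway activity. Genes are centered and, by default, scaled
#' to unit variance; zero-variance genes are dropped with a warning when
#' scaling.
#'
#' @param expr Numeric matrix, genes x cells (log-normalized).
#' @param signature Character vector of gene symbols (or a one-element named
#'   list as produced by [readGeneList()]).
#' @param k Number of components to return; must not exceed
#'   min(genes used, cells) - 1.
#' @param scale Scale genes to unit variance (default `TRUE`).
#' @return List with `scores` (cells x k), `loadings` (genes x k), `sdev`,
#'   and `genes` (the symbols used).
#' @export
signaturePca <- function(expr, signature, k, scale = TRUE) {
  if (is.list(signature)) signature <- signature[[1]]
  stopifnot(is.matrix(expr), k >= 1L)
  present <- intersect(unique(signature), rownames(expr))
  if (length(present) < 2L)
    stop("fewer than 2 signature genes present in the matrix")
  if (length(present) < length(unique(signature)))
    warning(length(unique(signature)) - length(present),
            " signature gene(s) absent; PCA runs on the intersection")
  X <- t(expr[present, , drop = FALSE])
  if (scale) {
    v <- apply(X, 2, stats::sd)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance gene(s) dropped before scaling")
      X <- X[, v > 0, drop = FALSE]
      present <- colnames(X)
      if (ncol(X) < 2L) stop("fewer than 2 usable genes after dropping")
    }
  }
  if (k > min(ncol(X), nrow(X)) - 1L)
    stop("k exceeds the available rank (min(genes, cells) - 1)")
  p <- stats::prcomp(X, center = TRUE, scale. = scale, rank. = k)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       sdev = p$sdev, genes = present)
}

#' Normalize an antibody array against background and positive controls
#'
#' Each probe is normalized to its own background, then to the mean of the
#' positive-control probes normalized to their own backgrounds:
#' \deqn{norm_i = (raw_i / bg_i) / \mathrm{mean}_j(pos_j / posbg_j).}
#' The result is invariant to a global exposure change affecting probes and
#' controls alike. Treated-vs-control fold changes per probe come from
#' [arrayFoldChange()].
#'
#' @param raw Named numeric, raw probe intensities.
#' @param background Numeric, per-probe background (> 0; recycled if scalar).
#' @param posRaw Numeric, positive-control probe intensities (>= 1 probe).
#' @param posBackground Numeric, positive-control backgrounds (> 0).
#' @return Named numeric of normalized probe values.
#' @export
normalizeAntibodyArray <- function(raw, background, posRaw, posBackground) {
  if (length(background) == 1L) background <- rep(background, length(raw))
  if (length(posBackground) == 1L)
    posBackground <- rep(posBackground, length(posRaw))
  stopifnot(length(background) == length(raw),
            length(posBackground) == length(posRaw),
            length(posRaw) >= 1L)
  if (any(background <= 0) || any(posBackground <= 0))
    stop("backgrounds must be positive")
  factor <- mean(posRaw / posBackground)
  (raw / background) / factor
}

#' @rdname normalizeAntibodyArray
#' @param normTreated,normControl Normalized probe vectors (named, matching
#'   probes) from [normalizeAntibodyArray()].
#' @return `arrayFoldChange()`: named numeric of treated/control fold changes.
#' @export
arrayFoldChange <- function(normTreated, normControl) {
  if (is.null(names(normTreated)) || is.null(names(normControl)))
    stop("normalized vectors must be named by probe")
  nm <- intersect(names(normTreated), names(normControl))
  if (length(nm) == 0L) stop("no shared probes")
  normTreated[nm] / normControl[nm]
}
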