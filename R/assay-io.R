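#' Read a plate-reader viability table
#'
#' Reads a long-format viability CSV with columns `model_id`, `compound`,
#' `dose_uM`, `replicate`, `signal`, `role` (role one of `sample`, `vehicle`,
#' `blank`) as produced by a luminescence viability assay (one row per well).
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame` (a viability table).
#' @seealso [normalizeViability()], [writeViabilityCsv()]
#' @export
readViabilityCsv <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateViabilityTable(tbl)
}

#' @rdname readViabilityCsv
#' @param table A viability `data.frame` to write.
#' @export
writeViabilityCsv <- function(table, path) {
  validateViabilityTable(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a viability table
#'
#' Checks the well-level invariants: non-negative doses and signals, known
#' well roles, and at least one vehicle well per model.
#'
#' @param table A `data.frame` with columns `model_id`, `compound`, `dose_uM`,
#'   `replicate`, `signal`, `role`.
#' @return The table, invisibly unchanged, or an error.
#' @export
validateViabilityTable <- function(table) {
  need <- c("model_id", "compound", "dose_uM", "replicate", "signal", "role")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("viability table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!table$role %in% c("sample", "vehicle", "blank")))
    stop("role must be one of 'sample', 'vehicle', 'blank'")
  if (any(table$dose_uM < 0)) stop("doses must be >= 0")
  if (any(table$signal < 0)) stop("raw signals must be >= 0")
  for (m in unique(table$model_id)) {
    if (!any(table$role[table$model_id == m] == "vehicle"))
      stop("model '", m, "' has no vehicle wells")
  }
  table
}

#' Normalize raw viability signals to percent of vehicle
#'
#' Computes percent viability relative to the vehicle control, per model: the
#' replicate signals of each (compound, dose) condition are averaged and
#' divided by the mean vehicle signal, times 100. If blank wells are present
#' for a model, their mean is subtracted from every signal of that model
#' first; signals that become negative after blank subtraction are clipped to
#' zero with a warning (instrument noise).
#'
#' Vehicle wells average to 100\% by construction; condition values may
#' exceed 100\% (stimulated growth).
#'
#' @param table A viability table (see [validateViabilityTable()]).
#' @return A `data.frame` with columns `model_id`, `compound`, `dose_uM`,
#'   `viability_pct`, one row per (model, compound, dose) condition.
#' @examples
#' tbl <- data.frame(
#'   model_id = "M1", compound = c("veh", "drug", "drug"),
#'   dose_uM = c(0, 1, 1), replicate = c(1, 1, 2),
#'   signal = c(10000, 4000, 6000),
#'   role = c("vehicle", "sample", "sample"))
#' normalizeViability(tbl) # drug at 1 uM -> 50%
#' @export
normalizeViability <- function(table) {
  validateViabilityTable(table)
  out <- lapply(split(table, table$model_id), function(sub) {
    model <- sub$model_id[1]
    sig <- sub$signal
    blanks <- sub$role == "blank"
    if (any(blanks)) {
      sig <- sig - mean(sig[blanks])
      if (any(sig[!blanks] < 0)) {
        warning("negative post-blank signals clipped to 0 for model '",
                model, "'")
        sig[sig < 0] <- 0
      }
    }
    veh_mean <- mean(sig[sub$role == "vehicle"])
    if (!is.finite(veh_mean) || veh_mean <= 0)
      stop("vehicle mean signal is not positive for model '", model, "'")
    smp <- sub$role == "sample"
    if (!any(smp)) return(NULL)
    key <- interaction(sub$compound[smp], sub$dose_uM[smp], drop = TRUE)
    agg <- tapply(sig[smp], key, mean)
    first <- !duplicated(key)
    data.frame(
      model_id = model,
      compound = sub$compound[smp][first],
      dose_uM = sub$dose_uM[smp][first],
      viability_pct = 100 * as.numeric(agg[as.character(key[first])]) / veh_mean,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- mutation-call table (Table-1-style fixture) -------------------------

## Extract gene symbols from a free-text call field. Handles the verbatim
## quirks of printed tables: entries separated by ';' (or ','), optional '*'
## re-sequencing marks, HGVS text in parentheses (possibly containing its own
## separators), and occasional missing separators between calls.
.extractGenes <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  ## symbols immediately followed by an HGVS parenthetical
  with_hgvs <- regmatches(
    text, gregexpr("\\b[A-Z][A-Z0-9]+\\*?\\s*\\(", text))[[1]]
  with_hgvs <- sub("\\s*\\($", "", with_hgvs)
  ## drop parentheticals, then take bare symbols from the remaining tokens
  bare <- gsub("\\([^)]*\\)", "", text)
  tokens <- strsplit(bare, "[;,]")[[1]]
  tokens <- trimws(tokens)
  bare_syms <- tokens[grepl("^[A-Z][A-Z0-9-]+\\*?$", tokens)]
  syms <- unique(sub("\\*$", "", c(with_hgvs, bare_syms)))
  toupper(syms)
}

#' Read a mutation-call table
#'
#' Reads a CSV transcription of a clinical sequencing call table with columns
#' `Name`, `Model` (`Cell line` or `PDX`), `Mutation`, `Amplification`,
#' `Fusion`; multi-entry fields are semicolon-separated, mutation entries
#' carry HGVS text in parentheses, and `*` marks calls confirmed in repeat
#' sequencing. The table is assumed to already contain only pathogenic calls.
#'
#' A transcription of the study's 34-model panel ships with the package:
#' `system.file("extdata", "table1_oncomine_calls.csv", package =
#' "SynergyScreen")`.
#'
#' @param path Path to the CSV.
#' @return A `data.frame` with the raw columns plus list-columns `mutGenes`,
#'   `ampGenes`, `fusionPairs` of parsed gene symbols.
#' @seealso [filterMutationTable()]
#' @export
readMutationTable <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Name", "Model", "Mutation", "Amplification", "Fusion")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tbl$Name))
    stop("model names must be unique")
  tbl$mutGenes <- I(lapply(tbl$Mutation, .extractGenes))
  tbl$ampGenes <- I(lapply(tbl$Amplification, .extractGenes))
  tbl$fusionPairs <- I(lapply(tbl$Fusion, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character())
    trimws(strsplit(x, ";")[[1]])
  }))
  tbl
}

#' Flag and count models carrying aberrations of a gene
#'
#' A model is flagged if the gene appears among its pathogenic mutation calls
#' OR its amplification calls (fusions are not counted). Returns per-model
#' flags, counts by model type, and the overall flagged fraction.
#'
#' @param records A parsed mutation table from [readMutationTable()].
#' @param gene Gene symbol (case-insensitive).
#' @return A list with elements `flags` (`data.frame` of `Name`, `Model`,
#'   `flagged`), `counts` (named integer by model type), `nFlagged`,
#'   `nModels`, and `fraction` (flagged / total).
#' @examples
#' path <- system.file("extdata", "table1_oncomine_calls.csv",
#'                     package = "SynergyScreen")
#' res <- filterMutationTable(readMutationTable(path), "PIK3CA")
#' res$counts   # Cell line: 5, PDX: 7
#' @export
filterMutationTable <- function(records, gene) {
  stopifnot(is.character(gene), length(gene) == 1L)
  gene <- toupper(gene)
  known <- c("Cell line", "PDX")
  bad <- setdiff(unique(records$Model), known)
  if (length(bad))
    stop("unknown model type(s): ", paste(bad, collapse = ", "))
  flagged <- mapply(function(mut, amp) gene %in% mut || gene %in% amp,
                    records$mutGenes, records$ampGenes)
  counts <- vapply(known, function(k) sum(flagged[records$Model == k]),
                   integer(1))
  list(
    flags = data.frame(Name = records$Name, Model = records$Model,
                       flagged = as.logical(flagged),
                       stringsAsFactors = FALSE),
    counts = counts,
    nFlagged = sum(flagged),
    nModels = nrow(records),
    fraction = sum(flagged) / nrow(records)
  )
}
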