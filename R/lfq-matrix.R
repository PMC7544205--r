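#' LFQ intensity matrix with sample design
#'
#' Container for a proteins x samples label-free quantification (LFQ)
#' intensity matrix as produced by MaxQuant-style proteinGroups tables.
#' Missing values are explicit `NA` (never 0 after loading); each sample
#' carries a role (`"bait"` or `"control"`), an IP-condition id and a
#' replicate index.
#'
#' @param values numeric matrix, proteins in rows, samples in columns;
#'   `NA` encodes non-detection. Row names are protein ids.
#' @param mw_kda numeric vector of molecular weights (kDa), one per row,
#'   all positive.
#' @param samples data.frame with columns `name`, `role` (`"bait"` or
#'   `"control"`), `condition`, `replicate`; one row per column of
#'   `values`, `name` matching its column name.
#' @param gene_names optional character vector of gene symbols per row.
#' @param log_transformed logical; whether `values` are on the log2 scale.
#'
#' @return An object of class `lfq_matrix`: a list with elements
#'   `values`, `mw_kda`, `gene_names`, `samples`, `log_transformed`.
#' @seealso [load_protein_groups()], [log2_transform()],
#'   [filter_valid_values()], [impute_missing()]
#' @export
lfq_matrix <- function(values, mw_kda, samples, gene_names = NULL,
                       log_transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stopf("`values` must have protein ids as row names")
    rownames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stopf("duplicated protein ids in `values`")
  if (length(mw_kda) != nrow(values))
    stopf("`mw_kda` must have one entry per protein row")
  if (any(!is.finite(mw_kda)) || any(mw_kda <= 0))
    stopf("molecular weights must be positive and finite")
  req <- c("name", "role", "condition", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stopf("`samples` must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stopf("`samples` must have one row per sample column")
  if (is.null(colnames(values))) colnames(values) <- samples$name
  if (!identical(as.character(samples$name), colnames(values)))
    stopf("sample names must match the column names of `values`")
  if (anyDuplicated(samples$name)) stopf("duplicated sample names")
  if (!all(samples$role %in% c("bait", "control")))
    stopf("sample roles must be 'bait' or 'control'")
  if (is.null(gene_names)) gene_names <- rownames(values)
  structure(
    list(values = values,
         mw_kda = stats::setNames(as.numeric(mw_kda), rownames(values)),
         gene_names = stats::setNames(as.character(gene_names),
                                      rownames(values)),
         samples = samples,
         log_transformed = isTRUE(log_transformed)),
    class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("lfq_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(v), ncol(v),
              if (x$log_transformed) "log2" else "raw"))
  cat(sprintf("  conditions: %s\n",
              paste(unique(paste0(x$samples$condition, "/",
                                  x$samples$role)), collapse = ", ")))
  cat(sprintf("  missing values: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Sample names of a (condition, role) group
#'
#' @param m an [lfq_matrix()].
#' @param condition IP-condition id.
#' @param role `"bait"` or `"control"`.
#' @return Character vector of sample names.
#' @export
lfq_group <- function(m, condition, role) {
  s <- m$samples
  as.character(s$name[s$condition == condition & s$role == role])
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Loads a tab-separated proteinGroups file, drops rows flagged in any of
#' the columns "Only identified by site", "Reverse" or
#' "Potential contaminant", and converts zero or empty LFQ intensities to
#' explicit missing values.
#'
#' @param path path to a tab-separated proteinGroups-style file.
#' @param sample_spec data.frame mapping LFQ intensity columns to the
#'   design, with columns `column` (full column name in the file, e.g.
#'   `"LFQ intensity b1"`), `role`, `condition`, `replicate`.
#' @return An [lfq_matrix()] on the raw intensity scale.
#' @export
load_protein_groups <- function(path, sample_spec) {
  req <- c("column", "role", "condition", "replicate")
  if (!is.data.frame(sample_spec) || !all(req %in% names(sample_spec)))
    stopf("`sample_spec` needs columns %s", paste(req, collapse = ", "))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mw_col <- "Mol. weight [kDa]"
  if (!mw_col %in% names(tab))
    stopf("required molecular-weight column '%s' not found in %s",
          mw_col, path)
  missing_cols <- setdiff(sample_spec$column, names(tab))
  if (length(missing_cols))
    stopf("LFQ column(s) not found in file: %s",
          paste(missing_cols, collapse = ", "))

  filter_cols <- intersect(
    c("Only identified by site", "Reverse", "Potential contaminant"),
    names(tab))
  flagged <- rep(FALSE, nrow(tab))
  for (fc in filter_cols)
    flagged <- flagged | (!is.na(tab[[fc]]) & tab[[fc]] == "+")
  if (any(flagged))
    message(sprintf("load_protein_groups: dropped %d flagged row(s)",
                    sum(flagged)))
  tab <- tab[!flagged, , drop = FALSE]
  if (nrow(tab) == 0L)
    warnf("no rows survive the decoy/contaminant filter")

  ids <- if ("Protein IDs" %in% names(tab)) tab[["Protein IDs"]]
         else as.character(seq_len(nrow(tab)))
  genes <- if ("Gene names" %in% names(tab)) tab[["Gene names"]] else ids

  vals <- as.matrix(tab[, sample_spec$column, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[!is.finite(vals) | vals == 0] <- NA_real_
  rownames(vals) <- ids
  colnames(vals) <- sub("^LFQ intensity ", "", sample_spec$column)

  samples <- data.frame(name = colnames(vals),
                        role = as.character(sample_spec$role),
                        condition = as.character(sample_spec$condition),
                        replicate = sample_spec$replicate,
                        stringsAsFactors = FALSE)
  lfq_matrix(vals, mw_kda = tab[[mw_col]], samples = samples,
             gene_names = genes, log_transformed = FALSE)
}

#' Log2-transform an LFQ matrix
#'
#' @param m an [lfq_matrix()] on the raw scale.
#' @return The matrix with every observed intensity replaced by its log2;
#'   missing values stay missing and the `log_transformed` flag is set.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (m$log_transformed) stopf("matrix is already log2-transformed")
  obs <- !is.na(m$values)
  if (any(m$values[obs] <= 0))
    stopf("non-positive observed intensity: corrupt input")
  m$values[obs] <- log2(m$values[obs])
  m$log_transformed <- TRUE
  m
}

#' Filter proteins by number of valid values
#'
#' Keeps a protein if it is observed in at least `min_valid` replicates of
#' at least one sample group (the default scope), or across the whole row
#' (`scope = "whole-row"`). Groups are (condition, role) pairs.
#'
#' @param m a log2-transformed [lfq_matrix()].
#' @param min_valid minimum number of observed values (default 2).
#' @param scope `"any-group"` (default) or `"whole-row"`.
#' @return The filtered [lfq_matrix()].
#' @export
filter_valid_values <- function(m, min_valid = 2,
                                scope = c("any-group", "whole-row")) {
  stopifnot(inherits(m, "lfq_matrix"))
  scope <- match.arg(scope)
  if (!m$log_transformed)
    stopf("filter_valid_values expects a log2-transformed matrix")
  grp <- interaction(m$samples$condition, m$samples$role, drop = TRUE)
  if (min_valid > max(table(grp)))
    stopf("min_valid (%d) exceeds the largest group size (%d)",
          min_valid, max(table(grp)))
  obs <- !is.na(m$values)
  keep <- if (scope == "whole-row") {
    rowSums(obs) >= min_valid
  } else {
    ok <- rep(FALSE, nrow(obs))
    for (g in levels(grp))
      ok <- ok | rowSums(obs[, grp == g, drop = FALSE]) >= min_valid
    ok
  }
  m$values <- m$values[keep, , drop = FALSE]
  m$mw_kda <- m$mw_kda[keep]
  m$gene_names <- m$gene_names[keep]
  m
}

#' Impute missing values from a left-shifted normal distribution
#'
#' Per sample column, missing entries are drawn from
#' `Normal(mean - downshift * sd, (width * sd)^2)` where mean and sd are
#' computed from the observed values of that column — the Perseus default
#' for left-censored (missing-not-at-random) LFQ data.
#'
#' @param m a log2-transformed [lfq_matrix()].
#' @param width imputation width as a fraction of the column sd
#'   (default 0.3).
#' @param downshift downward shift in multiples of the column sd
#'   (default 1.8).
#' @param seed integer seed for reproducible draws.
#' @param fallback_global if `TRUE`, a column with fewer than two observed
#'   values is imputed from the whole-matrix mean/sd instead of erroring.
#' @return The [lfq_matrix()] with no missing values; observed entries are
#'   unchanged.
#' @export
impute_missing <- function(m, width = 0.3, downshift = 1.8, seed = 1L,
                           fallback_global = FALSE) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (!m$log_transformed)
    stopf("impute_missing expects a log2-transformed matrix")
  if (width < 0 || downshift < 0) stopf("width and downshift must be >= 0")
  v <- m$values
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      obs <- v[!miss, j]
      if (length(obs) >= 2) {
        mu <- mean(obs); sdv <- stats::sd(obs)
      } else if (fallback_global) {
        all_obs <- v[!is.na(v)]
        if (length(all_obs) < 2)
          stopf("not enough observed values for global fallback")
        mu <- mean(all_obs); sdv <- stats::sd(all_obs)
      } else {
        stopf("column '%s' has fewer than 2 observed values; %s",
              colnames(v)[j],
              "enable `fallback_global` to impute from the global distribution")
      }
      v[miss, j] <- stats::rnorm(sum(miss),
                                 mean = mu - downshift * sdv,
                                 sd = width * sdv)
    }
  })
  m$values <- v
  m
}
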