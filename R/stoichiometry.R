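#' Bait-relative stoichiometric abundance
#'
#' Scores each significantly enriched protein in one IP condition by the
#' three-step procedure: (i) the mean raw LFQ intensity over replicates is
#' divided by the protein's molecular weight; (ii) the corresponding
#' control-IP background is subtracted; (iii) the result is normalised to
#' the bait protein, which is set to 100. Non-positive
#' background-subtracted values are not determinable (ND, reported `NA`).
#'
#' @param raw an [lfq_matrix()] on the raw (un-logged) intensity scale.
#' @param significant character vector of protein ids to score (typically
#'   from [call_significant()]); the bait is always scored.
#' @param bait_id protein id of the bait.
#' @param condition IP condition whose bait and control samples are used.
#' @param missing_as_zero if `TRUE` (default, the MaxQuant convention that
#'   absent = not detected), missing intensities enter the replicate mean
#'   as 0; otherwise the mean is over observed replicates only.
#' @return A `stoich_table`: data.frame with columns `protein`, `S`
#'   (bait = 100 scale, `NA` = ND), `heat` (`log2(S * 1000)`),
#'   `significant_source`.
#' @export
stoichiometric_abundance <- function(raw, significant, bait_id, condition,
                                     missing_as_zero = TRUE) {
  stopifnot(inherits(raw, "lfq_matrix"))
  if (raw$log_transformed)
    stopf("stoichiometric abundance uses raw (un-logged) intensities")
  bait_cols <- lfq_group(raw, condition, "bait")
  ctrl_cols <- lfq_group(raw, condition, "control")
  if (!length(bait_cols) || !length(ctrl_cols))
    stopf("condition '%s' needs both bait and control samples", condition)
  if (!bait_id %in% rownames(raw$values))
    stopf("bait '%s' not present in the matrix", bait_id)

  ids <- union(bait_id, intersect(significant, rownames(raw$values)))
  v <- raw$values[ids, , drop = FALSE]
  grp_mean <- function(cols) {
    x <- v[, cols, drop = FALSE]
    if (missing_as_zero) { x[is.na(x)] <- 0; rowMeans(x) }
    else { m <- rowMeans(x, na.rm = TRUE); ifelse(is.nan(m), 0, m) }
  }
  a <- (grp_mean(bait_cols) - grp_mean(ctrl_cols)) / raw$mw_kda[ids]
  a_bait <- a[[bait_id]]
  if (!is.finite(a_bait) || a_bait <= 0)
    stopf("bait '%s' is not enriched over the control in condition '%s'",
          bait_id, condition)
  s <- 100 * (a / a_bait)    # bait ratio is exactly 1, so bait S is 100
  s[s <= 0] <- NA_real_
  out <- data.frame(protein = ids, S = unname(s),
                    heat = log2(unname(s) * 1000),
                    significant_source = ids %in% significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "bait") <- bait_id
  attr(out, "condition") <- condition
  class(out) <- c("stoich_table", "data.frame")
  out
}

#' Heatmap transform of stoichiometric abundances
#'
#' `log2(S * 1000)`, the scale used for clustering and heatmap display;
#' ND propagates to ND.
#'
#' @param x a `stoich_table`, or a numeric vector/matrix of S values.
#' @return Object of the same shape with heat values.
#' @export
heat_transform <- function(x) {
  if (inherits(x, "stoich_table")) {
    x$heat <- log2(x$S * 1000)
    return(x)
  }
  log2(x * 1000)
}

#' @export
print.stoich_table <- function(x, ...) {
  cat(sprintf("stoich_table: bait %s, condition %s, %d proteins (%d ND)\n",
              attr(x, "bait"), attr(x, "condition"), nrow(x),
              sum(is.na(x$S))))
  print.data.frame(utils::head(x[order(-ifelse(is.na(x$S), -Inf, x$S)), ],
                               8), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assemble a protein x condition stoichiometry matrix
#'
#' @param tables named list of `stoich_table`s, one per IP condition
#'   column (names become column names).
#' @param value `"heat"` (default, the clustering scale) or `"S"`.
#' @return Numeric matrix, proteins x conditions, `NA` = ND.
#' @export
stoich_matrix <- function(tables, value = c("heat", "S")) {
  value <- match.arg(value)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stopf("`tables` must be a named list")
  prots <- sort(unique(unlist(lapply(tables, `[[`, "protein"))))
  out <- matrix(NA_real_, length(prots), length(tables),
                dimnames = list(prots, names(tables)))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    out[t$protein, j] <- t[[value]]
  }
  out
}

#' Hierarchical clustering of IP conditions
#'
#' Average-linkage agglomerative clustering of condition columns using
#' Euclidean distances. ND entries are handled pairwise-complete: the
#' squared distance over shared defined entries is rescaled by
#' `n_total / n_shared`; column pairs with no shared entries are assigned
#' the maximum observed distance. Columns that are entirely ND are
#' dropped with a warning.
#'
#' @param mat numeric matrix (proteins x conditions), e.g. from
#'   [stoich_matrix()].
#' @param distance only `"euclidean"` is implemented.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`, the Perseus default).
#' @return A `condition_clustering`: list with the `hclust` tree, the
#'   distance matrix, cophenetic distances and the leaf order.
#' @export
cluster_conditions <- function(mat, distance = "euclidean",
                               linkage = "average") {
  if (!identical(distance, "euclidean"))
    stopf("only euclidean distance is implemented")
  if (!is.matrix(mat)) stopf("`mat` must be a matrix")
  all_nd <- colSums(!is.na(mat)) == 0
  if (any(all_nd)) {
    warnf("dropping %d entirely-ND column(s): %s", sum(all_nd),
          paste(colnames(mat)[all_nd], collapse = ", "))
    mat <- mat[, !all_nd, drop = FALSE]
  }
  k <- ncol(mat)
  if (k < 2) stopf("need at least 2 condition columns")
  n_total <- nrow(mat)
  dm <- matrix(0, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sh <- !is.na(mat[, i]) & !is.na(mat[, j])
    dm[i, j] <- dm[j, i] <- if (!any(sh)) NA_real_ else
      sqrt(sum((mat[sh, i] - mat[sh, j])^2) * n_total / sum(sh))
  }
  if (anyNA(dm)) {
    mx <- max(dm, na.rm = TRUE)
    dm[is.na(dm)] <- mx
  }
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  structure(list(hclust = hc, dist = stats::as.dist(dm),
                 cophenetic = stats::cophenetic(hc),
                 leaf_order = hc$labels[hc$order]),
            class = "condition_clustering")
}

#' @export
print.condition_clustering <- function(x, ...) {
  cat(sprintf("condition_clustering (%s linkage): %d conditions\n",
              x$hclust$method, length(x$leaf_order)))
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.condition_clustering <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Multi-bait overlap sets (three-set Venn regions)
#'
#' For exactly three baits, unions of significant proteins over each
#' bait's conditions, the 7 disjoint Venn region counts, and pairwise
#' shared fractions |A n B| / |B|.
#'
#' @param per_bait_significant named list of length 3; each element is a
#'   list of per-condition character vectors (or a single character
#'   vector) of significant protein ids for that bait.
#' @return An `overlap_sets`: list with `unions` (per-bait id vectors),
#'   `regions` (named counts of the 7 disjoint regions), and
#'   `shared_fraction` (matrix F where `F[i, j] = |Ui n Uj| / |Uj|`).
#' @export
overlap_sets <- function(per_bait_significant) {
  if (length(per_bait_significant) != 3L)
    stopf("exactly three baits are required")
  nm <- names(per_bait_significant)
  if (is.null(nm) || any(!nzchar(nm))) nm <- c("A", "B", "C")
  unions <- lapply(per_bait_significant,
                   function(x) sort(unique(unlist(x))))
  names(unions) <- nm
  all_ids <- sort(unique(unlist(unions)))
  memb <- vapply(unions, function(u) all_ids %in% u,
                 logical(length(all_ids)))
  if (length(all_ids) == 1L) memb <- matrix(memb, nrow = 1)
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  region_names <- c(nm, paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
  regions <- stats::setNames(integer(7), region_names)
  tabk <- table(key)
  regions[names(tabk)] <- as.integer(tabk)
  shared <- matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
  for (i in 1:3) for (j in 1:3)
    shared[i, j] <- if (length(unions[[j]]) == 0) 0 else
      length(intersect(unions[[i]], unions[[j]])) / length(unions[[j]])
  structure(list(unions = unions, regions = regions,
                 shared_fraction = shared),
            class = "overlap_sets")
}

#' @export
print.overlap_sets <- function(x, ...) {
  cat("overlap_sets:\n  union sizes:",
      paste(sprintf("%s=%d", names(x$unions), lengths(x$unions)),
            collapse = ", "), "\n  regions:\n")
  print(x$regions)
  cat("  pairwise shared fraction |row n col| / |col|:\n")
  print(round(x$shared_fraction, 3))
  invisible(x)
}
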