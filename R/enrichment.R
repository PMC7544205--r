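#' S0-moderated two-sample test with permutation FDR
#'
#' Per-protein moderated statistic in the SAM / Perseus volcano
#' parameterisation,
#' \deqn{d = (\bar x_A - \bar x_B) / (s + s_0),}
#' where \eqn{s} is the two-sample pooled standard error and \eqn{s_0} a
#' fudge factor damping significance at small fold changes. With
#' `s0 = 0`, `d` is the classical two-sample Student t statistic.
#' False-discovery rates are estimated by permutation of sample labels:
#' at each observed |d| cutoff, the FDR is the mean number of permuted
#' |d| values strictly exceeding the cutoff divided by the observed
#' number at or above it, clipped to \[0, 1\] and enforced monotone
#' non-increasing in |d|. Label assignments equivalent to the observed
#' grouping (the identity and, for equal group sizes, the complete
#' swap) are excluded from the permutation set: they reproduce the
#' observed statistics exactly and would otherwise place a hard floor
#' under every q-value.
#'
#' @param m an imputed (missing-free) log2-scale [lfq_matrix()].
#' @param group_a,group_b character vectors of sample names forming the
#'   two groups (A is typically the bait IP, B the control); they must be
#'   disjoint and each of size >= 2.
#' @param s0 non-negative fudge factor on the log2 scale (default 1, the
#'   "S0 = 1" volcano setting).
#' @param n_permutations number of label permutations (default 250) or
#'   `"exhaustive"`; a request exceeding the exhaustive count is silently
#'   capped at exhaustive enumeration.
#' @param fdr_threshold FDR cutoff used for the `significant` flag
#'   (default 0.01).
#' @param seed integer seed for the permutation draw.
#' @return An `enrichment_result`: a data.frame with one row per protein
#'   and columns `protein`, `gene`, `mean_a`, `mean_b`, `log2_fc`, `d`,
#'   `q`, `significant` (q below threshold *and* positive fold change).
#' @export
sam_test <- function(m, group_a, group_b, s0 = 1, n_permutations = 250,
                     fdr_threshold = 0.01, seed = 1L) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (anyNA(m$values))
    stopf("sam_test requires an imputed matrix (no missing values)")
  if (s0 < 0) stopf("s0 must be >= 0")
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stopf("groups overlap: %s",
          paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("both groups need at least 2 samples")
  bad <- setdiff(c(group_a, group_b), colnames(m$values))
  if (length(bad)) stopf("unknown sample(s): %s", paste(bad, collapse = ", "))

  x <- m$values[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  ia <- seq_len(na); ib <- na + seq_len(nb)
  d_obs <- sam_d(x, ia, ib, s0)
  abs_obs <- abs(d_obs)

  # permutation assignments: columns are index sets for pseudo-group A;
  # assignments equivalent to the observed grouping are excluded
  is_trivial <- function(p) {
    identical(p, seq_len(na)) ||
      (na == nb && identical(p, na + seq_len(nb)))
  }
  n_exh <- choose(n, na) - 1L - (na == nb)
  perms <- if (identical(n_permutations, "exhaustive") ||
               (is.numeric(n_permutations) && n_permutations >= n_exh)) {
    all_p <- utils::combn(n, na)
    all_p[, !apply(all_p, 2, is_trivial), drop = FALSE]
  } else {
    if (!is_count(n_permutations))
      stopf("n_permutations must be a positive count or \"exhaustive\"")
    with_seed(seed, {
      if (choose(n, na) <= 1e5) {
        all_p <- utils::combn(n, na)
        all_p <- all_p[, !apply(all_p, 2, is_trivial), drop = FALSE]
        all_p[, sample(ncol(all_p), n_permutations), drop = FALSE]
      } else {
        # collision with the observed grouping is vanishingly unlikely
        vapply(seq_len(n_permutations),
               function(i) sort(sample(n, na)), integer(na))
      }
    })
  }

  # observed discoveries #{|d_j| >= |d_p|} and mean permuted
  # discoveries #{|d_perm| > |d_p|} for every protein p
  sorted_obs <- sort(abs_obs)
  n_prot <- length(abs_obs)
  obs_ge <- n_prot - findInterval(abs_obs, sorted_obs, left.open = TRUE)
  perm_ge <- numeric(n_prot)
  for (k in seq_len(ncol(perms))) {
    pa <- perms[, k]; pb <- setdiff(seq_len(n), pa)
    sp <- sort(abs(sam_d(x, pa, pb, s0)))
    perm_ge <- perm_ge + (n_prot - findInterval(abs_obs, sp))
  }
  fdr <- pmin(1, pmax(0, (perm_ge / ncol(perms)) / obs_ge))
  # monotone non-increasing in |d|; ties broken by input order
  ord <- order(-abs_obs, seq_along(abs_obs))
  fdr[ord] <- cummax(fdr[ord])

  res <- data.frame(
    protein = rownames(x),
    gene = unname(m$gene_names[rownames(x)]),
    mean_a = rowMeans(x[, ia, drop = FALSE]),
    mean_b = rowMeans(x[, ib, drop = FALSE]),
    d = d_obs, q = fdr,
    stringsAsFactors = FALSE, row.names = NULL)
  res$log2_fc <- res$mean_a - res$mean_b
  res$significant <- res$q < fdr_threshold & res$log2_fc > 0
  res <- res[, c("protein", "gene", "mean_a", "mean_b", "log2_fc",
                 "d", "q", "significant")]
  attr(res, "s0") <- s0
  attr(res, "n_permutations") <- ncol(perms)
  attr(res, "fdr_threshold") <- fdr_threshold
  attr(res, "groups") <- list(a = group_a, b = group_b)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# moderated d for all proteins at once; 0/0 (zero spread, zero difference,
# s0 = 0) is defined as 0
sam_d <- function(x, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  sp2 <- ((na - 1) * row_vars(xa) + (nb - 1) * row_vars(xb)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  num <- ma - mb
  den <- se + s0
  d <- ifelse(den == 0 & num == 0, 0, num / den)
  unname(d)
}

#' Significantly enriched proteins
#'
#' Proteins with permutation FDR below the threshold and a positive log2
#' fold change (enrichment is one-sided toward the bait IP).
#'
#' @param r an `enrichment_result` from [sam_test()].
#' @param fdr_threshold FDR cutoff; defaults to the one stored in `r`.
#' @return Character vector of protein ids.
#' @export
call_significant <- function(r, fdr_threshold = attr(r, "fdr_threshold")) {
  stopifnot(inherits(r, "enrichment_result"))
  if (nrow(r) == 0L) return(character(0))
  r$protein[r$q < fdr_threshold & r$log2_fc > 0]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d proteins, s0 = %g, %d permutations\n",
    nrow(x), attr(x, "s0"), attr(x, "n_permutations")))
  cat(sprintf("  significant (q < %g, log2FC > 0): %d\n",
              attr(x, "fdr_threshold"), sum(x$significant)))
  print.data.frame(utils::head(x[order(x$q, -abs(x$d)), ], 6),
                   digits = 4, row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  s <- object[object$significant, ]
  cat(sprintf("%d / %d proteins enriched at q < %g\n", nrow(s),
              nrow(object), attr(object, "fdr_threshold")))
  if (nrow(s)) print.data.frame(s[order(-s$log2_fc), ], digits = 4,
                                row.names = FALSE)
  invisible(s)
}

#' Volcano plot of an enrichment result
#'
#' @param x an `enrichment_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enrichment_result <- function(x, ...) {
  col <- ifelse(x$significant, "firebrick", "grey60")
  graphics::plot(x$log2_fc, -log10(pmax(x$q, 1e-4)),
                 col = col, pch = 16, cex = 0.7,
                 xlab = "log2 fold change (bait - control)",
                 ylab = "-log10 permutation FDR", ...)
  graphics::abline(h = -log10(attr(x, "fdr_threshold")), lty = 2)
  invisible(x)
}
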