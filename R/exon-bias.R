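#' Load a DESeq2-format differential-expression table
#'
#' Reads a tab-separated results table and assigns a regulation direction
#' per transcript: `up` if `padj < fdr_level` and `log2FoldChange > 0`,
#' `down` symmetrically, otherwise (including missing `padj`, i.e.
#' untested transcripts) `unchanged`.
#'
#' @param path tab-separated file with columns `id` (or
#'   `transcript_id`), `baseMean`, `log2FoldChange`, `padj`.
#' @param fdr_level adjusted-p cutoff (default 0.1).
#' @return A `de_table`: data.frame with the input columns plus
#'   `direction`.
#' @export
load_de_table <- function(path, fdr_level = 0.1) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if ("transcript_id" %in% names(tab) && !"id" %in% names(tab))
    names(tab)[names(tab) == "transcript_id"] <- "id"
  req <- c("id", "baseMean", "log2FoldChange", "padj")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stopf("DE table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  de_table(tab, fdr_level)
}

#' Build a DE table from an in-memory data.frame
#'
#' Assigns regulation directions at the given FDR level; see
#' [load_de_table()] for the file-based equivalent.
#'
#' @param tab data.frame with columns `id`, `baseMean`,
#'   `log2FoldChange`, `padj`.
#' @param fdr_level adjusted-p cutoff (default 0.1).
#' @return A `de_table`.
#' @export
de_table <- function(tab, fdr_level = 0.1) {
  if (!is_fraction(fdr_level) || fdr_level == 0 || fdr_level == 1)
    stopf("fdr_level must be in (0, 1)")
  sig <- !is.na(tab$padj) & tab$padj < fdr_level
  tab$direction <- ifelse(sig & tab$log2FoldChange > 0, "up",
                   ifelse(sig & tab$log2FoldChange < 0, "down",
                          "unchanged"))
  attr(tab, "fdr_level") <- fdr_level
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf(
    "de_table: %d transcripts (FDR < %g): %d up, %d down, %d unchanged\n",
    nrow(x), attr(x, "fdr_level"), sum(x$direction == "up"),
    sum(x$direction == "down"), sum(x$direction == "unchanged")))
  invisible(x)
}

#' Attach per-transcript exon counts from an annotation
#'
#' @param t a `de_table`.
#' @param a a [genome_annotation()]; transcripts absent from it are
#'   dropped with a message stating how many.
#' @return The `de_table` with an `exon_count` column (and `biotype`).
#' @export
attach_exon_counts <- function(t, a) {
  stopifnot(inherits(t, "de_table"), inherits(a, "genome_annotation"))
  tr <- a$transcripts
  idx <- match(t$id, tr$transcript_id)
  if (anyNA(idx))
    message(sprintf(
      "attach_exon_counts: dropped %d id(s) absent from the annotation",
      sum(is.na(idx))))
  keep <- !is.na(idx)
  out <- t[keep, , drop = FALSE]
  out$exon_count <- tr$n_exons[idx[keep]]
  out$biotype <- tr$biotype[idx[keep]]
  rownames(out) <- NULL
  attr(out, "fdr_level") <- attr(t, "fdr_level")
  class(out) <- class(t)
  out
}

#' Per-direction ECDF of exon counts
#'
#' @param t a `de_table` with an `exon_count` column.
#' @return Named list of [stats::ecdf()] step functions, one per
#'   direction present among `up` and `down`.
#' @export
exon_count_ecdf <- function(t) {
  stopifnot(inherits(t, "de_table"))
  if (is.null(t$exon_count))
    stopf("run attach_exon_counts() first")
  out <- list()
  for (dir in c("up", "down")) {
    x <- t$exon_count[t$direction == dir]
    if (!length(x))
      stopf("no transcripts in direction '%s'", dir)
    out[[dir]] <- stats::ecdf(x)
  }
  out
}

#' Mann-Whitney U test with exact or tie-corrected normal null
#'
#' Computes U with midrank tie handling. The exact two-sided p-value is
#' obtained by enumerating all assignments of the pooled observations to
#' the two groups and counting those whose U deviates from the null mean
#' `n_x * n_y / 2` by at least the observed amount. The normal
#' approximation uses the tie-corrected variance and a continuity
#' correction.
#'
#' @param x,y numeric samples (e.g. exon counts), both non-empty.
#' @param mode `"auto"` (exact when `n_x + n_y <= 12`, else normal),
#'   `"exact"` (refused above 20 total observations), or `"normal"`.
#' @return An object of class `htest` with `statistic` (U of `x`),
#'   `p.value` and `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  use_exact <- switch(mode,
                      auto = n <= 12,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact && n > 20)
    stopf("exact enumeration refused for n_x + n_y = %d (> 20)", n)
  if (use_exact) {
    idx <- utils::combn(n, nx)
    rsums <- colSums(matrix(r[idx], nrow = nx))
    u_all <- rsums - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    ties <- table(z)
    sigma2 <- nx * ny / 12 *
      (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 parameter = c(n_x = nx, n_y = ny),
                 data.name = "x and y",
                 alternative = "two.sided"),
            class = "htest")
}

#' Expression-matched subset of up- and down-regulated transcripts
#'
#' Greedy 1:1 nearest-neighbour matching on `log10(baseMean)` without
#' replacement: transcripts of the smaller direction are visited in a
#' seeded random order and each is paired with the closest unmatched
#' transcript of the other direction within the caliper; transcripts
#' with no partner inside the caliper are discarded.
#'
#' @param t a `de_table` with both `up` and `down` transcripts.
#' @param caliper_log10 maximum |log10(baseMean)| difference within a
#'   pair (default 0.1).
#' @param seed integer seed for the visiting order.
#' @return The matched subset of `t` (equal numbers of up and down
#'   rows), with the pairing in `attr(, "pairs")`.
#' @export
expression_match <- function(t, caliper_log10 = 0.1, seed = 1L) {
  stopifnot(inherits(t, "de_table"))
  if (caliper_log10 < 0) stopf("caliper must be >= 0")
  up <- which(t$direction == "up"); dn <- which(t$direction == "down")
  if (!length(up) || !length(dn))
    stopf("both directions must be non-empty")
  swap <- length(dn) < length(up)
  small <- if (swap) dn else up
  large <- if (swap) up else dn
  lx <- log10(t$baseMean)
  pairs <- matrix(NA_integer_, 0, 2)
  with_seed(seed, {
    avail <- rep(TRUE, length(large))
    for (i in sample(seq_along(small))) {
      dists <- abs(lx[large] - lx[small[i]])
      dists[!avail] <- Inf
      j <- which.min(dists)
      if (is.finite(dists[j]) && dists[j] <= caliper_log10) {
        avail[j] <- FALSE
        pairs <- rbind(pairs, c(small[i], large[j]))
      }
    }
  })
  if (nrow(pairs) == 0L)
    stopf("no up/down pairs within caliper %g; increase the caliper",
          caliper_log10)
  keep <- sort(c(pairs[, 1], pairs[, 2]))
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr_level") <- attr(t, "fdr_level")
  attr(out, "pairs") <- data.frame(
    up_id = t$id[if (swap) pairs[, 2] else pairs[, 1]],
    down_id = t$id[if (swap) pairs[, 1] else pairs[, 2]],
    stringsAsFactors = FALSE)
  class(out) <- class(t)
  out
}

#' Exon-count bias test between up- and down-regulated transcripts
#'
#' Convenience wrapper for the full comparison: optional expression
#' matching, per-direction exon-count ECDFs, and the Mann-Whitney U test
#' on exon counts of up- versus down-regulated transcripts.
#'
#' @param t a `de_table` with `exon_count` attached.
#' @param match if `TRUE`, test on an [expression_match()]ed subset.
#' @param caliper_log10,seed passed to [expression_match()].
#' @param mode passed to [mann_whitney()].
#' @return An `exon_bias_test`: list with `n_up`, `n_down`, `U`, `p`,
#'   `ecdf` (per-direction), `test` (the `htest`), and `matched_ids`
#'   when matching was applied.
#' @export
exon_bias_test <- function(t, match = FALSE, caliper_log10 = 0.1,
                           seed = 1L, mode = "auto") {
  stopifnot(inherits(t, "de_table"))
  if (is.null(t$exon_count)) stopf("run attach_exon_counts() first")
  matched_ids <- NULL
  if (match) {
    t <- expression_match(t, caliper_log10 = caliper_log10, seed = seed)
    matched_ids <- t$id
  }
  up <- t$exon_count[t$direction == "up"]
  dn <- t$exon_count[t$direction == "down"]
  ht <- mann_whitney(up, dn, mode = mode)
  structure(list(n_up = length(up), n_down = length(dn),
                 U = unname(ht$statistic), p = ht$p.value,
                 ecdf = exon_count_ecdf(t), test = ht,
                 matched_ids = matched_ids),
            class = "exon_bias_test")
}

#' @export
print.exon_bias_test <- function(x, ...) {
  cat(sprintf(
    "exon_bias_test: %d up vs %d down transcripts%s\n  U = %g, p = %.3g\n",
    x$n_up, x$n_down,
    if (is.null(x$matched_ids)) "" else " (expression-matched)",
    x$U, x$p))
  invisible(x)
}

#' Cumulative frequency plot of exon counts by direction
#'
#' @param x an `exon_bias_test`.
#' @param xlim exon-count range to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.exon_bias_test <- function(x, xlim = NULL, ...) {
  ks <- sort(unique(c(stats::knots(x$ecdf$up),
                      stats::knots(x$ecdf$down))))
  if (is.null(xlim)) xlim <- range(ks)
  grid <- seq(xlim[1], xlim[2])
  graphics::plot(grid, x$ecdf$up(grid), type = "s", col = "blue",
                 ylim = c(0, 1), xlab = "exon count",
                 ylab = "cumulative frequency", ...)
  graphics::lines(grid, x$ecdf$down(grid), type = "s", col = "red")
  graphics::legend("bottomright", c("up", "down"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  graphics::mtext(sprintf("Mann-Whitney p = %.3g", x$p), side = 3,
                  cex = 0.8)
  invisible(x)
}
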