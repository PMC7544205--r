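#' Differential-expression simulator configuration
#'
#' Defaults emulate a knockdown RNA-seq screen over a transcriptome-scale
#' annotation in which a few percent of transcripts respond and the
#' probability of down-regulation rises with exon count, while
#' up-regulation is exon-independent.
#'
#' @param n_transcripts number of transcripts to draw from the
#'   annotation (`NULL` = all of them).
#' @param basemean_meanlog,basemean_sdlog log-scale parameters of the
#'   lognormal baseMean distribution (defaults give a median near 150
#'   normalized counts with a long right tail).
#' @param effect_model list with elements `p_up` (constant probability
#'   of up-regulation), `p_down` (probability of down-regulation: a
#'   constant or a function of exon count), `lfc_mean`, `lfc_sd`
#'   (magnitude of significant log2 fold changes). The default
#'   `p_down` is logistic in exon count.
#' @param dispersion sd of the null log2 fold changes of unchanged
#'   transcripts.
#' @param fdr_level adjusted-p cutoff the table is generated around
#'   (default 0.1).
#' @param frac_untested fraction of unchanged transcripts reported with
#'   `padj = NA` (independent-filtering casualties).
#' @param seed integer seed.
#' @return A list of class `de_sim_config`.
#' @export
de_sim_config <- function(n_transcripts = NULL,
                          basemean_meanlog = 5, basemean_sdlog = 1.5,
                          effect_model = list(
                            p_up = 0.035,
                            p_down = function(k) stats::plogis(-4.2 + 0.15 * k),
                            lfc_mean = 1.5, lfc_sd = 0.5),
                          dispersion = 0.15,
                          fdr_level = 0.1,
                          frac_untested = 0.1,
                          seed = 1L) {
  if (!is.null(n_transcripts) && !is_count(n_transcripts))
    stopf("n_transcripts must be a count or NULL")
  if (!is_fraction(fdr_level) || fdr_level == 0 || fdr_level == 1)
    stopf("fdr_level must be in (0, 1)")
  if (!is_fraction(frac_untested)) stopf("frac_untested must be in [0, 1]")
  req <- c("p_up", "p_down", "lfc_mean", "lfc_sd")
  if (!is.list(effect_model) || !all(req %in% names(effect_model)))
    stopf("effect_model needs elements %s", paste(req, collapse = ", "))
  if (!is_fraction(effect_model$p_up)) stopf("p_up must be in [0, 1]")
  if (!is.function(effect_model$p_down) &&
      !is_fraction(effect_model$p_down))
    stopf("p_down must be a fraction or a function of exon count")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  structure(list(n_transcripts = n_transcripts,
                 basemean_meanlog = basemean_meanlog,
                 basemean_sdlog = basemean_sdlog,
                 effect_model = effect_model,
                 dispersion = dispersion,
                 fdr_level = fdr_level,
                 frac_untested = frac_untested,
                 seed = as.integer(seed)), class = "de_sim_config")
}

#' Simulate a DESeq2-format differential-expression table
#'
#' Draws per-transcript baseMeans from a lognormal distribution and
#' assigns each transcript a true direction under the effect model:
#' `P(down)` may depend on the transcript's exon count (taken from the
#' annotation) while `P(up)` is constant. Significant transcripts get
#' `padj` uniform below the FDR level and a log2 fold change of the
#' configured magnitude and sign; unchanged transcripts get `padj`
#' above the level (or `NA` for a configurable untested fraction) and a
#' small null fold change.
#'
#' @param annotation a [genome_annotation()] supplying transcript ids
#'   and exon counts.
#' @param config a [de_sim_config()].
#' @return A list of class `de_sim` with elements `table` (a
#'   `de_table` with columns `id`, `baseMean`, `log2FoldChange`,
#'   `padj`, `direction`) and `truth` (data.frame: id, exon_count,
#'   true direction).
#' @export
simulate_de_table <- function(annotation, config = de_sim_config()) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "de_sim_config"))
  cf <- config
  tr <- annotation$transcripts
  with_seed(cf$seed, {
    if (!is.null(cf$n_transcripts)) {
      if (cf$n_transcripts > nrow(tr))
        stopf("n_transcripts (%d) exceeds annotation size (%d)",
              cf$n_transcripts, nrow(tr))
      tr <- tr[sample(nrow(tr), cf$n_transcripts), , drop = FALSE]
    }
    n <- nrow(tr)
    k <- tr$n_exons
    p_dn <- if (is.function(cf$effect_model$p_down))
      cf$effect_model$p_down(k) else rep(cf$effect_model$p_down, n)
    p_dn <- pmin(pmax(p_dn, 0), 1)
    p_up <- rep(cf$effect_model$p_up, n)
    if (any(p_up + p_dn > 1))
      stopf("effect model implies P(up) + P(down) > 1")
    u <- stats::runif(n)
    dir_true <- ifelse(u < p_up, "up",
                ifelse(u < p_up + p_dn, "down", "unchanged"))
    base_mean <- stats::rlnorm(n, cf$basemean_meanlog, cf$basemean_sdlog)
    mag <- abs(stats::rnorm(n, cf$effect_model$lfc_mean,
                            cf$effect_model$lfc_sd))
    lfc <- ifelse(dir_true == "up", mag,
           ifelse(dir_true == "down", -mag,
                  stats::rnorm(n, 0, cf$dispersion)))
    # ensure a nonzero magnitude so direction calls match the truth
    lfc[dir_true != "unchanged" & lfc == 0] <- 1e-6 *
      ifelse(dir_true[dir_true != "unchanged" & lfc == 0] == "up", 1, -1)
    padj <- ifelse(dir_true == "unchanged",
                   stats::runif(n, cf$fdr_level, 1),
                   stats::runif(n, 0, cf$fdr_level))
    untested <- dir_true == "unchanged" &
      stats::runif(n) < cf$frac_untested
    padj[untested] <- NA_real_

    tab <- de_table(data.frame(id = tr$transcript_id,
                               baseMean = base_mean,
                               log2FoldChange = lfc,
                               padj = padj,
                               stringsAsFactors = FALSE),
                    fdr_level = cf$fdr_level)
    truth <- data.frame(id = tr$transcript_id, exon_count = k,
                        direction = dir_true, stringsAsFactors = FALSE)
    structure(list(table = tab, truth = truth, config = cf),
              class = "de_sim")
  })
}

#' @export
print.de_sim <- function(x, ...) {
  cat(sprintf("de_sim: %d transcripts, %d up / %d down (true)\n",
              nrow(x$truth), sum(x$truth$direction == "up"),
              sum(x$truth$direction == "down")))
  invisible(x)
}

#' Write a simulated DE table as TSV
#'
#' @param sim a `de_sim` from [simulate_de_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(sim, path) {
  stopifnot(inherits(sim, "de_sim"))
  utils::write.table(
    sim$table[, c("id", "baseMean", "log2FoldChange", "padj")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
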