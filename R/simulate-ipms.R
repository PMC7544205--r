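#' IP-MS simulator configuration
#'
#' Study-like defaults: a bait IP against a LAP-tag control in
#' quadruplicate, a handful of true interactors spanning stoichiometries
#' from near-stoichiometric to trace, a large nonspecific background,
#' 20% replicate-to-replicate variation, and intensity-dependent
#' (left-censored) dropout.
#'
#' @param n_background_proteins nonspecific proteins present in bait and
#'   control IPs at equal means.
#' @param n_interactors true bait-specific interactors.
#' @param true_stoichiometries molar fractions of the bait (0-1 scale),
#'   one per interactor; default log-spaced from 1 to 0.005.
#' @param bait_intensity mean raw LFQ intensity of the bait.
#' @param replicate_cv coefficient of variation of replicate intensities
#'   (lognormal, mean-preserving).
#' @param n_bait_replicates,n_control_replicates replicate counts.
#' @param detection_limit raw intensity at which the dropout probability
#'   is 50%; 0 disables dropout.
#' @param dropout_curve_steepness logistic steepness per log2 intensity.
#' @param seed integer seed.
#' @return A list of class `ipms_sim_config`.
#' @export
ipms_sim_config <- function(n_background_proteins = 150,
                            n_interactors = 10,
                            true_stoichiometries = NULL,
                            bait_intensity = 1e10,
                            replicate_cv = 0.2,
                            n_bait_replicates = 4,
                            n_control_replicates = 4,
                            detection_limit = 1e6,
                            dropout_curve_steepness = 1.5,
                            seed = 1L) {
  if (is.null(true_stoichiometries))
    true_stoichiometries <- exp(seq(log(1), log(0.005),
                                    length.out = n_interactors))
  for (cnt in list(n_background_proteins, n_interactors,
                   n_bait_replicates, n_control_replicates))
    if (!is_count(cnt)) stopf("counts must be integers >= 1")
  if (length(true_stoichiometries) != n_interactors)
    stopf("true_stoichiometries must have length n_interactors (%d), got %d",
          n_interactors, length(true_stoichiometries))
  if (any(true_stoichiometries <= 0))
    stopf("stoichiometries must be > 0")
  if (replicate_cv < 0) stopf("replicate_cv must be >= 0")
  if (bait_intensity <= 0) stopf("bait_intensity must be > 0")
  if (detection_limit < 0) stopf("detection_limit must be >= 0")
  structure(list(n_background_proteins = as.integer(n_background_proteins),
                 n_interactors = as.integer(n_interactors),
                 true_stoichiometries = as.numeric(true_stoichiometries),
                 bait_intensity = bait_intensity,
                 replicate_cv = replicate_cv,
                 n_bait_replicates = as.integer(n_bait_replicates),
                 n_control_replicates = as.integer(n_control_replicates),
                 detection_limit = detection_limit,
                 dropout_curve_steepness = dropout_curve_steepness,
                 seed = as.integer(seed)), class = "ipms_sim_config")
}

#' Simulate a proteinGroups-style IP-MS experiment
#'
#' Builds a bait-vs-control LFQ matrix with known ground truth. The bait
#' is detected only in bait IPs at `bait_intensity`; each true
#' interactor's mean raw intensity is
#' `stoichiometry * bait_intensity * MW_interactor / MW_bait` (LFQ
#' intensity scales with molar amount times molecular weight, so the
#' molecular-weight-normalised stoichiometry score recovers the
#' configured molar ratio); background proteins appear at equal means in
#' both IPs. Molecular weights are drawn uniformly from 10-300 kDa.
#' Replicate noise is mean-preserving lognormal at the configured CV, and
#' missingness is intensity-dependent: an intensity drops out with
#' logistic probability falling with log2 intensity around the detection
#' limit. Three flagged decoy rows (reverse / contaminant) are included
#' to exercise loading filters.
#'
#' @param config an [ipms_sim_config()].
#' @param condition label for the IP condition (default `"c1"`).
#' @return A list of class `ipms_sim` with elements `table`
#'   (proteinGroups-style data.frame, 0 = not detected), `lfq` (the same
#'   data as a raw-scale [lfq_matrix()], decoys removed), `sample_spec`
#'   (design for [load_protein_groups()]), and `truth` (list with
#'   `bait_id` and per-interactor `stoichiometry`).
#' @export
simulate_ipms <- function(config = ipms_sim_config(), condition = "c1") {
  stopifnot(inherits(config, "ipms_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    nb <- cf$n_bait_replicates; nc <- cf$n_control_replicates
    n_int <- cf$n_interactors; n_bg <- cf$n_background_proteins
    ids <- c("BAIT", sprintf("INT%03d", seq_len(n_int)),
             sprintf("BG%04d", seq_len(n_bg)))
    n_prot <- length(ids)
    mw <- stats::runif(n_prot, 10, 300)
    names(mw) <- ids

    mean_bait_ip <- numeric(n_prot); names(mean_bait_ip) <- ids
    mean_ctrl_ip <- numeric(n_prot); names(mean_ctrl_ip) <- ids
    mean_bait_ip["BAIT"] <- cf$bait_intensity
    ints <- sprintf("INT%03d", seq_len(n_int))
    mean_bait_ip[ints] <- cf$true_stoichiometries * cf$bait_intensity *
      mw[ints] / mw[["BAIT"]]
    bg <- sprintf("BG%04d", seq_len(n_bg))
    bg_mean <- 10^stats::runif(n_bg, 6.5, 9.5)
    mean_bait_ip[bg] <- bg_mean
    mean_ctrl_ip[bg] <- bg_mean

    samp <- data.frame(
      name = c(sprintf("bait_r%d", seq_len(nb)),
               sprintf("ctrl_r%d", seq_len(nc))),
      role = c(rep("bait", nb), rep("control", nc)),
      condition = condition,
      replicate = c(seq_len(nb), seq_len(nc)),
      stringsAsFactors = FALSE)

    mu <- cbind(matrix(mean_bait_ip, n_prot, nb),
                matrix(mean_ctrl_ip, n_prot, nc))
    dimnames(mu) <- list(ids, samp$name)
    vals <- mu
    if (cf$replicate_cv > 0) {
      sdlog <- sqrt(log(1 + cf$replicate_cv^2))
      noise <- exp(matrix(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog),
                          n_prot))
      vals <- mu * noise
    }
    # left-censored (MNAR) dropout on the raw scale
    if (cf$detection_limit > 0) {
      p_obs <- stats::plogis(cf$dropout_curve_steepness *
                               (log2(pmax(vals, .Machine$double.xmin)) -
                                  log2(cf$detection_limit)))
      drop <- matrix(stats::runif(length(vals)) > p_obs, n_prot)
      vals[drop] <- 0
    }
    vals[mu == 0] <- 0                   # truly absent

    lfq <- lfq_matrix({v <- vals; v[v == 0] <- NA_real_; v},
                      mw_kda = mw, samples = samp,
                      log_transformed = FALSE)

    tab <- data.frame(
      `Protein IDs` = ids, `Gene names` = ids,
      `Mol. weight [kDa]` = unname(mw),
      `Only identified by site` = "", Reverse = "",
      `Potential contaminant` = "",
      check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(vals)))
      tab[[paste("LFQ intensity", colnames(vals)[j])]] <- vals[, j]
    decoys <- tab[rep(1L, 3L), ]
    decoys$`Protein IDs` <- c("REV__DECOY1", "CON__KRT1", "CON__ALB")
    decoys$`Gene names` <- decoys$`Protein IDs`
    decoys$Reverse <- c("+", "", "")
    decoys$`Potential contaminant` <- c("", "+", "+")
    tab <- rbind(tab, decoys)
    rownames(tab) <- NULL

    sample_spec <- data.frame(
      column = paste("LFQ intensity", samp$name),
      role = samp$role, condition = samp$condition,
      replicate = samp$replicate, stringsAsFactors = FALSE)

    structure(list(
      table = tab, lfq = lfq, sample_spec = sample_spec,
      truth = list(bait_id = "BAIT",
                   stoichiometry = stats::setNames(
                     cf$true_stoichiometries, ints)),
      config = cf), class = "ipms_sim")
  })
}

#' @export
print.ipms_sim <- function(x, ...) {
  cat(sprintf(
    "ipms_sim: bait + %d interactors + %d background, %d+%d replicates\n",
    x$config$n_interactors, x$config$n_background_proteins,
    x$config$n_bait_replicates, x$config$n_control_replicates))
  invisible(x)
}

#' Write a simulated IP-MS experiment as a proteinGroups-style TSV
#'
#' @param sim an `ipms_sim` from [simulate_ipms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ipms_table <- function(sim, path) {
  stopifnot(inherits(sim, "ipms_sim"))
  utils::write.table(sim$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
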