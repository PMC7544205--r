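# fixtures and independent oracles used across test files

# small LFQ matrix built directly (log2 scale unless stated)
tiny_lfq <- function(values, roles = NULL, condition = "c1",
                     mw = NULL, log_transformed = TRUE) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(roles))
    roles <- rep(c("bait", "control"), each = ncol(values) / 2)
  samples <- data.frame(
    name = sprintf("%s_r%d", substr(roles, 1, 4),
                   stats::ave(seq_along(roles), roles, FUN = seq_along)),
    role = roles, condition = condition,
    replicate = stats::ave(seq_along(roles), roles, FUN = seq_along),
    stringsAsFactors = FALSE)
  colnames(values) <- samples$name
  if (is.null(mw)) mw <- rep(50, nrow(values))
  lfq_matrix(values, mw_kda = mw, samples = samples,
             log_transformed = log_transformed)
}

# annotation from a compact spec: list(tid = list(strand, exons list of
# c(start, end)))
tiny_annotation <- function(spec, chrom = "chrT") {
  tr <- do.call(rbind, lapply(names(spec), function(tid) {
    data.frame(transcript_id = tid, gene_id = paste0("g_", tid),
               chrom = chrom, strand = spec[[tid]]$strand,
               biotype = "protein_coding", stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(names(spec), function(tid) {
    m <- do.call(rbind, spec[[tid]]$exons)
    data.frame(transcript_id = tid, start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  }))
  genome_annotation(tr, ex)
}

make_track <- function(chrom, pos, strand, score) {
  crosslink_track(data.frame(chrom = chrom, pos = pos, strand = strand,
                             score = score, stringsAsFactors = FALSE))
}

# --- mirror helpers (coordinate reflection + strand flip) ----------------

mirror_annotation <- function(ann, L) {
  ex <- ann$exons
  new_start <- L - ex$end
  ex$end <- L - ex$start
  ex$start <- new_start
  tr <- ann$transcripts
  tr$strand <- ifelse(tr$strand == "+", "-", "+")
  genome_annotation(tr[, c("transcript_id", "gene_id", "chrom",
                           "strand", "biotype")],
                    ex[, c("transcript_id", "start", "end")])
}

mirror_track <- function(track, L) {
  df <- as.data.frame(track)
  df$pos <- L - 1L - df$pos
  df$strand <- ifelse(df$strand == "+", "-", "+")
  crosslink_track(df)
}

# --- independent oracles --------------------------------------------------

# scalar moderated statistic, computed protein by protein with stats::var
oracle_d <- function(a, b, s0) {
  sp2 <- ((length(a) - 1) * stats::var(a) +
            (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  if (se + s0 == 0) return(0)
  (mean(a) - mean(b)) / (se + s0)
}

# brute-force permutation q-values: direct double loop over all label
# assignments (excluding the observed grouping and, for equal sizes, its
# complement), mean permuted count of |d| strictly above each observed
# |d| over observed count at or above it, clipped and made monotone
oracle_perm_q <- function(x, na, nb, s0) {
  na <- as.integer(na); nb <- as.integer(nb)
  n <- na + nb
  d_for <- function(idx_a) {
    idx_b <- setdiff(seq_len(n), idx_a)
    apply(x, 1, function(row) oracle_d(row[idx_a], row[idx_b], s0))
  }
  d_obs <- d_for(seq_len(na))
  combs <- utils::combn(n, na)
  keep <- logical(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    p <- combs[, k]
    keep[k] <- !(identical(p, seq_len(na)) ||
                   (na == nb && identical(p, na + seq_len(nb))))
  }
  combs <- combs[, keep, drop = FALSE]
  perm_d <- matrix(NA_real_, nrow(x), ncol(combs))
  for (k in seq_len(ncol(combs))) perm_d[, k] <- d_for(combs[, k])
  q <- numeric(nrow(x))
  for (p in seq_len(nrow(x))) {
    cutoff <- abs(d_obs[p])
    obs_cnt <- sum(abs(d_obs) >= cutoff)
    perm_cnt <- mean(colSums(abs(perm_d) > cutoff))
    q[p] <- min(1, perm_cnt / obs_cnt)
  }
  ord <- order(-abs(d_obs), seq_along(d_obs))
  q[ord] <- cummax(q[ord])
  q
}

# naive O(n^3) average-linkage agglomeration over complete columns;
# linkage distance between clusters = mean of all pairwise original
# euclidean column distances
oracle_average_linkage_heights <- function(mat) {
  k <- ncol(mat)
  d0 <- as.matrix(stats::dist(t(mat)))
  clusters <- as.list(seq_len(k))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exact Mann-Whitney by enumeration; U computed by direct pair counting
oracle_mw_exact <- function(x, y) {
  u_of <- function(xx, yy) {
    u <- 0
    for (xi in xx) for (yj in yy)
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  z <- c(x, y); nx <- length(x); n <- length(z)
  u_obs <- u_of(x, y)
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  u_all <- apply(combs, 2, function(idx) u_of(z[idx], z[-idx]))
  list(U = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}
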