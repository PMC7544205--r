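#' Strand-aware crosslink signal track
#'
#' Per-position signal on the genome: interval-derived scores or
#' conversion counts. Positions are 0-based; (chrom, pos, strand) is
#' unique and scores are non-negative.
#'
#' @param df data.frame with columns `chrom`, `pos`, `strand`, `score`.
#' @return A `crosslink_track` (a data.frame).
#' @export
crosslink_track <- function(df = data.frame(chrom = character(),
                                            pos = integer(),
                                            strand = character(),
                                            score = numeric())) {
  req <- c("chrom", "pos", "strand", "score")
  if (!all(req %in% names(df)))
    stopf("track needs columns %s", paste(req, collapse = ", "))
  df <- df[, req, drop = FALSE]
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      stopf("track strand must be '+' or '-'")
    if (any(df$score < 0)) stopf("track scores must be >= 0")
    key <- paste(df$chrom, df$pos, df$strand)
    if (anyDuplicated(key)) {
      agg <- rowsum(df$score, key)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$score <- agg[paste(df$chrom, df$pos, df$strand), 1]
    }
    df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("crosslink_track", "data.frame")
  df
}

#' @export
print.crosslink_track <- function(x, ...) {
  cat(sprintf("crosslink_track: %d positions, total score %g\n",
              nrow(x), sum(x$score)))
  if (nrow(x)) print.data.frame(utils::head(x, 5), row.names = FALSE)
  invisible(x)
}

#' Load a BED6 interval track
#'
#' Distributes each interval's score onto every covered base.
#'
#' @param bed_path path to a BED6 file (0-based half-open, tab-separated:
#'   chrom, start, end, name, score, strand).
#' @param mode `"score"` (default: each covered base gets the interval
#'   score) or `"density"` (score divided by interval length).
#' @return A [crosslink_track()]; scores of overlapping intervals sum.
#' @export
load_track_bed <- function(bed_path, mode = c("score", "density")) {
  mode <- match.arg(mode)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(crosslink_track())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6))
    stopf("BED line %d has %d fields; BED6 required",
          which(nf < 6)[1], nf[nf < 6][1])
  strand <- vapply(parts, `[[`, "", 6L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stopf("malformed strand field '%s' on BED line %d",
          strand[bad[1]], bad[1])
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  score <- as.numeric(vapply(parts, `[[`, "", 5L))
  if (anyNA(start) || anyNA(end) || anyNA(score))
    stopf("non-numeric start/end/score in BED file")
  width <- end - start
  per_base <- if (mode == "density") score / width else score
  idx <- rep.int(seq_along(lines), width)
  off <- sequence(width)
  crosslink_track(data.frame(
    chrom = chrom[idx], pos = start[idx] + off - 1L,
    strand = strand[idx], score = per_base[idx],
    stringsAsFactors = FALSE))
}

# mpileup read-base string -> vector of per-read base symbols
# (handles ^X, $, +n/-n indel tokens, * and > < placeholders)
parse_pileup_bases <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n)
  k <- 0L; i <- 1L
  while (i <= n) {
    c <- chars[i]
    if (c == "^") {
      i <- i + 2L                       # caret + mapping quality char
    } else if (c == "$") {
      i <- i + 1L
    } else if (c == "+" || c == "-") {
      j <- i + 1L; num <- ""
      while (j <= n && chars[j] %in% as.character(0:9)) {
        num <- paste0(num, chars[j]); j <- j + 1L
      }
      if (!nzchar(num)) stopf("malformed indel token in pileup bases")
      i <- j + as.integer(num)          # skip inserted/deleted sequence
    } else {
      k <- k + 1L; out[k] <- c; i <- i + 1L
    }
  }
  out[seq_len(k)]
}

#' Call crosslink conversions from samtools mpileup text
#'
#' Extracts diagnostic crosslink-induced conversions: at a reference T,
#' uppercase `C` read bases are counted as plus-strand T>C conversions;
#' at a reference A, lowercase `g` read bases are counted as minus-strand
#' A>G conversions (the same event seen on reverse reads). All other
#' mismatches and reference bases are ignored. Read-start (`^`),
#' read-end (`$`) and indel (`+n`/`-n`) tokens in the base string are
#' skipped per the mpileup grammar.
#'
#' @param x path to a 6-column mpileup text file (chrom, 1-based pos,
#'   reference base, depth, read bases, qualities), or a character vector
#'   of such lines.
#' @return A [crosslink_track()] of 0-based conversion positions with
#'   conversion counts as scores.
#' @export
call_conversions <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(crosslink_track())
  rows <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "[ \t]+")[[1]]
    if (length(f) < 6L)
      stopf("mpileup line %d has %d fields; 6 expected", li, length(f))
    depth <- suppressWarnings(as.integer(f[4]))
    if (is.na(depth)) stopf("non-integer depth on mpileup line %d", li)
    bases <- parse_pileup_bases(f[5])
    if (length(bases) != depth)
      stopf(paste0("mpileup line %d: depth field (%d) inconsistent with ",
                   "parsed base string length (%d)"),
            li, depth, length(bases))
    ref <- toupper(f[3])
    if (ref == "T") {
      cnt <- sum(bases == "C")
      if (cnt > 0)
        rows[[li]] <- data.frame(chrom = f[1],
                                 pos = as.integer(f[2]) - 1L,
                                 strand = "+", score = cnt,
                                 stringsAsFactors = FALSE)
    } else if (ref == "A") {
      cnt <- sum(bases == "g")
      if (cnt > 0)
        rows[[li]] <- data.frame(chrom = f[1],
                                 pos = as.integer(f[2]) - 1L,
                                 strand = "-", score = cnt,
                                 stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(crosslink_track())
  crosslink_track(do.call(rbind, rows))
}

# --- profile machinery ----------------------------------------------------

# add base-resolution scores at mature positions `mpos` (0-based, axis
# length L) into `prof` (nbins), fractional-overlap binning
add_scaled_bins <- function(prof, mpos, score, L, nbins, offset = 0L) {
  f <- nbins / L
  lo <- mpos * f; hi <- lo + f
  for (i in seq_along(mpos)) {
    b0 <- max(0L, floor(lo[i]))
    b1 <- min(nbins - 1L, ceiling(hi[i]) - 1L)
    for (b in b0:b1) {
      ov <- min(hi[i], b + 1) - max(lo[i], b)
      if (ov > 0)
        prof[offset + b + 1L] <- prof[offset + b + 1L] +
          score[i] * ov / f
    }
  }
  prof
}

# track rows on one exon with mature-orientation position within the exon
exon_track_hits <- function(tchrom, tpos, tscore, exon) {
  sel <- which(tchrom == exon$chrom & tpos >= exon$start &
                 tpos < exon$end)
  if (!length(sel)) return(NULL)
  p <- if (exon$strand == "+") tpos[sel] - exon$start
       else exon$end - 1L - tpos[sel]
  ord <- order(p)                # canonical accumulation order, so that
  list(p = p[ord], score = tscore[sel][ord])  # mirrored inputs sum alike
}

meta_profile <- function(bin, sum_signal, n, anchors = NULL) {
  mean_signal <- if (n > 0) sum_signal / n else rep(NA_real_,
                                                    length(sum_signal))
  structure(list(profile = data.frame(bin = bin,
                                      mean_signal = mean_signal,
                                      sum_signal = sum_signal),
                 n = n, anchors = anchors),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: %d bins, %d features, total signal %g\n",
              nrow(x$profile), x$n, sum(x$profile$sum_signal)))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$profile$bin, x$profile$mean_signal, type = "l",
                 xlab = "bin (5' -> 3')", ylab = "mean signal", ...)
  if (!is.null(x$anchors)) graphics::abline(v = x$anchors, lty = 3)
  invisible(x)
}

#' Metagene profile over mature transcripts
#'
#' Maps the signal on exonic bases of each transcript to
#' mature-transcript coordinates (introns excised), rescales the mature
#' axis of every transcript to `n_bins` bins with fractional-overlap
#' binning, and averages per-bin signal across transcripts (each
#' transcript weighted equally). Bin 1 is always the transcription start
#' site: minus-strand transcripts are traversed right-to-left
#' genomically.
#'
#' @param track a [crosslink_track()]; only positions matching a
#'   transcript's chromosome and strand contribute.
#' @param annotation a [genome_annotation()].
#' @param n_bins number of bins (>= 1).
#' @return A `meta_profile` with `n` = number of transcripts aggregated.
#' @export
metagene_transcript_profile <- function(track, annotation, n_bins = 100) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!is_count(n_bins)) stopf("n_bins must be a count >= 1")
  prof <- numeric(n_bins)
  tr <- annotation$transcripts
  for (tid in tr$transcript_id) {
    ex <- transcript_exons(annotation, tid)
    strand <- ex$strand[1]
    sel <- track$strand == strand
    tchrom <- track$chrom[sel]; tpos <- track$pos[sel]
    tscore <- track$score[sel]
    len <- ex$end - ex$start
    L <- sum(len)
    cum <- cumsum(c(0L, len))[seq_len(nrow(ex))]
    for (k in seq_len(nrow(ex))) {
      h <- exon_track_hits(tchrom, tpos, tscore, ex[k, ])
      if (is.null(h)) next
      prof <- add_scaled_bins(prof, cum[k] + h$p, h$score, L, n_bins)
    }
  }
  meta_profile(seq_len(n_bins), prof, nrow(tr))
}

#' Exon-anchored metagene profile by exon category
#'
#' Averages signal over exons of one category (`monoexonic`, `first`,
#' `internal`, `last`), restricted to exons longer than `min_exon_len`
#' (strictly). Each exon contributes an axis of
#' `flank_bins + body_bins + flank_bins` bins: the first and last
#' `flank_bins` nt are kept at single-nucleotide resolution (unscaled
#' anchors at the exon's 5' and 3' ends) and the remaining body is
#' rescaled to `body_bins` bins.
#'
#' @param track a [crosslink_track()].
#' @param annotation a [genome_annotation()].
#' @param category exon category to profile.
#' @param min_exon_len minimum exon length, exclusive (default 200 nt).
#' @param flank_bins unscaled nt at each exon end (default 50).
#' @param body_bins bins for the scaled exon body (default 60).
#' @return A `meta_profile` with `n` = number of qualifying exons;
#'   `anchors` marks the flank/body boundaries.
#' @export
exon_anchored_profile <- function(track, annotation,
                                  category = c("monoexonic", "first",
                                               "internal", "last"),
                                  min_exon_len = 200, flank_bins = 50,
                                  body_bins = 60) {
  category <- match.arg(category)
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  ex <- ex[ex$category == category &
             (ex$end - ex$start) > min_exon_len &
             (ex$end - ex$start) > 2 * flank_bins, , drop = FALSE]
  # canonical order so accumulation is independent of genomic layout
  ex <- ex[order(match(ex$transcript_id,
                       annotation$transcripts$transcript_id),
                 ex$rank), , drop = FALSE]
  nbins <- 2L * flank_bins + body_bins
  prof <- numeric(nbins)
  if (nrow(ex) == 0L) {
    warnf("no %s exons longer than %d nt", category, min_exon_len)
    return(meta_profile(seq_len(nbins), prof, 0L,
                        anchors = c(flank_bins + 0.5,
                                    flank_bins + body_bins + 0.5)))
  }
  for (k in seq_len(nrow(ex))) {
    e <- ex[k, ]
    h <- exon_track_hits(track$chrom[track$strand == e$strand],
                         track$pos[track$strand == e$strand],
                         track$score[track$strand == e$strand], e)
    if (is.null(h)) next
    len <- e$end - e$start
    five <- h$p < flank_bins
    three <- h$p >= len - flank_bins
    body <- !five & !three
    if (any(five))
      prof[h$p[five] + 1L] <- prof[h$p[five] + 1L] + h$score[five]
    if (any(three)) {
      b <- flank_bins + body_bins + (h$p[three] - (len - flank_bins)) + 1L
      prof[b] <- prof[b] + h$score[three]
    }
    if (any(body))
      prof <- add_scaled_bins(prof, h$p[body] - flank_bins,
                              h$score[body], len - 2L * flank_bins,
                              body_bins, offset = flank_bins)
  }
  meta_profile(seq_len(nbins), prof, nrow(ex),
               anchors = c(flank_bins + 0.5,
                           flank_bins + body_bins + 0.5))
}

#' Histogram of signal by distance upstream of exon-exon junctions
#'
#' For every exon followed by a junction (first and internal exons of
#' multiexonic transcripts), each track position inside the exon
#' contributes its score at `offset` = distance in mature-transcript
#' coordinates from the position to the exon's 3' end: the last exonic
#' base before the junction is offset 1. Offsets above `max_offset` are
#' dropped.
#'
#' @param track a [crosslink_track()] (typically conversion counts).
#' @param annotation a [genome_annotation()].
#' @param max_offset largest offset retained (default 50 nt).
#' @return A `junction_offsets` data.frame with columns `offset`
#'   (1..max_offset) and `count` (summed score).
#' @export
junction_offset_histogram <- function(track, annotation,
                                      max_offset = 50) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!is_count(max_offset)) stopf("max_offset must be a count >= 1")
  ex <- annotation$exons
  ex <- ex[ex$category %in% c("first", "internal"), , drop = FALSE]
  if (nrow(ex) == 0L) stopf("annotation has no multiexonic transcripts")
  ex <- ex[order(match(ex$transcript_id,
                       annotation$transcripts$transcript_id),
                 ex$rank), , drop = FALSE]
  counts <- numeric(max_offset)
  for (k in seq_len(nrow(ex))) {
    e <- ex[k, ]
    h <- exon_track_hits(track$chrom[track$strand == e$strand],
                         track$pos[track$strand == e$strand],
                         track$score[track$strand == e$strand], e)
    if (is.null(h)) next
    len <- e$end - e$start
    off <- len - h$p                     # mature distance to exon 3' end
    keep <- off >= 1 & off <= max_offset
    if (any(keep)) {
      agg <- rowsum(h$score[keep], off[keep])
      idx <- as.integer(rownames(agg))
      counts[idx] <- counts[idx] + agg[, 1]
    }
  }
  out <- data.frame(offset = seq_len(max_offset), count = counts)
  class(out) <- c("junction_offsets", "data.frame")
  out
}

#' @export
plot.junction_offsets <- function(x, ...) {
  graphics::barplot(rev(x$count), names.arg = rev(x$offset),
                    xlab = "nt upstream of exon-exon junction",
                    ylab = "summed conversion count", ...)
  invisible(x)
}
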