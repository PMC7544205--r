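#' CLIP simulator configuration
#'
#' Defaults emulate crosslink sites concentrating in two broad bands,
#' 10-20 nt and 25-35 nt upstream of exon-exon junctions, on top of a
#' diffuse background over 1-45 nt — the junction-proximal deposition
#' pattern expected for an exon-junction-associated RNA-binding protein.
#'
#' @param offset_distribution crosslink offsets upstream of junctions
#'   (offset 1 = last exonic base): either a single integer (all events
#'   at that offset) or a named numeric vector of probabilities with
#'   offsets (>= 1) as names. Default: 45% of mass uniform on 10-20 nt,
#'   45% on 25-35 nt, 10% uniform on 1-45 nt.
#' @param events_per_junction mean number of crosslink events per
#'   junction (Poisson).
#' @param conversion_rate fraction of reads at a site carrying the
#'   diagnostic mismatch (default 0.25, a typical PAR-CLIP conversion
#'   rate).
#' @param read_depth mean read coverage per event site (Poisson,
#'   minimum 1).
#' @param seed integer seed.
#' @return A list of class `clip_sim_config`.
#' @export
clip_sim_config <- function(offset_distribution = NULL,
                            events_per_junction = 3,
                            conversion_rate = 0.25,
                            read_depth = 30,
                            seed = 1L) {
  if (is.null(offset_distribution)) {
    p <- stats::setNames(rep(0.10 / 45, 45), 1:45)
    p[as.character(10:20)] <- p[as.character(10:20)] + 0.45 / 11
    p[as.character(25:35)] <- p[as.character(25:35)] + 0.45 / 11
    offset_distribution <- p
  } else if (is.null(names(offset_distribution))) {
    if (length(offset_distribution) != 1L)
      stopf("unnamed offset_distribution must be a single fixed offset")
    offset_distribution <- stats::setNames(1, offset_distribution)
  }
  offs <- as.integer(names(offset_distribution))
  if (anyNA(offs) || any(offs < 1))
    stopf("offsets must be integers >= 1")
  if (any(offset_distribution < 0) || sum(offset_distribution) <= 0)
    stopf("offset probabilities must be non-negative with positive sum")
  if (events_per_junction <= 0)
    stopf("events_per_junction must be > 0")
  if (!is_fraction(conversion_rate))
    stopf("conversion_rate must be in [0, 1]")
  if (read_depth <= 0) stopf("read_depth must be > 0")
  structure(list(
    offset_distribution =
      offset_distribution / sum(offset_distribution),
    events_per_junction = events_per_junction,
    conversion_rate = conversion_rate,
    read_depth = read_depth,
    seed = as.integer(seed)), class = "clip_sim_config")
}

#' Simulate PAR-CLIP crosslink conversions on a toy annotation
#'
#' Plants crosslink events at sampled offsets upstream of exon-exon
#' junctions (in mature-transcript coordinates) and projects them to
#' genome coordinates respecting strand: a plus-strand event is a
#' reference T with uppercase `C` mismatches among forward reads; a
#' minus-strand event is a reference A with lowercase `g` mismatches
#' among reverse reads. Events whose offset exceeds the exon length are
#' skipped and reported via a message. The emitted pileup text is the
#' 6-column samtools dialect (uppercase = forward-strand reads,
#' lowercase = reverse-strand reads, no indel tokens).
#'
#' @param annotation a [genome_annotation()] with at least one
#'   multiexonic transcript.
#' @param config a [clip_sim_config()].
#' @return A list of class `clip_sim` with elements `pileup` (character
#'   vector of mpileup lines), `bed` (BED6 data.frame of conversion
#'   sites, score = conversion count), and `truth` (per-event
#'   data.frame: transcript_id, exon_rank, offset, chrom, pos, strand,
#'   depth, conversions).
#' @export
simulate_clip <- function(annotation, config = clip_sim_config()) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "clip_sim_config"))
  ex <- annotation$exons
  jx <- ex[ex$category %in% c("first", "internal"), , drop = FALSE]
  if (nrow(jx) == 0L)
    stopf("annotation needs at least one multiexonic transcript")
  cf <- config
  with_seed(cf$seed, {
    offs_support <- as.integer(names(cf$offset_distribution))
    n_ev <- stats::rpois(nrow(jx), cf$events_per_junction)
    jrep <- jx[rep(seq_len(nrow(jx)), n_ev), , drop = FALSE]
    total <- nrow(jrep)
    if (total == 0L)
      stopf("no events drawn; increase events_per_junction")
    offset <- offs_support[sample.int(length(offs_support), total,
                                      replace = TRUE,
                                      prob = cf$offset_distribution)]
    len <- jrep$end - jrep$start
    bad <- offset > len
    if (any(bad))
      message(sprintf(
        "simulate_clip: skipped %d event(s) with offset > exon length",
        sum(bad)))
    jrep <- jrep[!bad, , drop = FALSE]; offset <- offset[!bad]
    pos <- ifelse(jrep$strand == "+", jrep$end - offset,
                  jrep$start + offset - 1L)
    depth <- pmax(1L, stats::rpois(length(pos), cf$read_depth))
    conv <- stats::rbinom(length(pos), depth, cf$conversion_rate)
    truth <- data.frame(transcript_id = jrep$transcript_id,
                        exon_rank = jrep$rank, offset = offset,
                        chrom = jrep$chrom, pos = as.integer(pos),
                        strand = jrep$strand, depth = depth,
                        conversions = conv, stringsAsFactors = FALSE,
                        row.names = NULL)

    # aggregate events by genomic site for the pileup / BED emission
    key <- paste(truth$chrom, truth$pos, truth$strand)
    ord <- order(truth$chrom, truth$pos)
    first <- !duplicated(key)
    site <- truth[first, c("chrom", "pos", "strand"), drop = FALSE]
    site$depth <- as.integer(rowsum(truth$depth, key)[
      paste(site$chrom, site$pos, site$strand), 1])
    site$conv <- as.integer(rowsum(truth$conversions, key)[
      paste(site$chrom, site$pos, site$strand), 1])
    site <- site[order(site$chrom, site$pos), , drop = FALSE]

    ref <- ifelse(site$strand == "+", "T", "A")
    match_c <- ifelse(site$strand == "+", ".", ",")
    mism_c <- ifelse(site$strand == "+", "C", "g")
    pileup <- sprintf("%s\t%d\t%s\t%d\t%s%s\t%s",
                      site$chrom, site$pos + 1L, ref, site$depth,
                      strrep(match_c, site$depth - site$conv),
                      strrep(mism_c, site$conv),
                      strrep("I", site$depth))
    keep <- site$conv > 0
    bed <- data.frame(chrom = site$chrom[keep], start = site$pos[keep],
                      end = site$pos[keep] + 1L,
                      name = sprintf("site%04d", which(keep)),
                      score = site$conv[keep],
                      strand = site$strand[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
    structure(list(pileup = pileup, bed = bed, truth = truth,
                   config = cf), class = "clip_sim")
  })
}

#' @export
print.clip_sim <- function(x, ...) {
  cat(sprintf(
    "clip_sim: %d events at %d sites, %d with >= 1 conversion\n",
    nrow(x$truth), length(x$pileup), nrow(x$bed)))
  invisible(x)
}

#' Write the pileup and BED outputs of a CLIP simulation
#'
#' @param sim a `clip_sim` from [simulate_clip()].
#' @param pileup_path,bed_path output paths (`NULL` to skip either).
#' @return Invisibly, a list of the written paths.
#' @export
write_clip_sim <- function(sim, pileup_path = NULL, bed_path = NULL) {
  stopifnot(inherits(sim, "clip_sim"))
  if (!is.null(pileup_path)) writeLines(sim$pileup, pileup_path)
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", sim$bed$chrom,
                     sim$bed$start, sim$bed$end, sim$bed$name,
                     sim$bed$score, sim$bed$strand)
    writeLines(lines, bed_path)
  }
  invisible(list(pileup = pileup_path, bed = bed_path))
}
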