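#' Genome annotation with ranked exons
#'
#' Internal representation of a transcript annotation: all exon
#' coordinates are 0-based half-open intervals, exon ranks count 5' to 3'
#' in transcript orientation (rank 1 of a minus-strand transcript is the
#' genomically rightmost exon), and each exon carries a category:
#' `monoexonic`, `first`, `internal` or `last`.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `biotype`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open), and optionally `rank` (recomputed anyway).
#' @return A `genome_annotation`: list with `transcripts` (gains
#'   `n_exons`) and `exons` (gains `rank`, `category`, `chrom`, `strand`).
#' @export
genome_annotation <- function(transcripts, exons) {
  req_t <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
  req_e <- c("transcript_id", "start", "end")
  if (!all(req_t %in% names(transcripts)))
    stopf("`transcripts` needs columns %s", paste(req_t, collapse = ", "))
  if (!all(req_e %in% names(exons)))
    stopf("`exons` needs columns %s", paste(req_e, collapse = ", "))
  if (!all(transcripts$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stopf("exon end must exceed exon start (0-based half-open)")
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan))
    stopf("exons reference unknown transcript(s): %s",
          paste(utils::head(orphan, 3), collapse = ", "))
  keep <- transcripts$transcript_id %in% exons$transcript_id
  if (!all(keep)) {
    warnf("skipping %d transcript(s) with no exon records", sum(!keep))
    transcripts <- transcripts[keep, , drop = FALSE]
  }

  strand_of <- stats::setNames(transcripts$strand,
                               transcripts$transcript_id)
  chrom_of <- stats::setNames(transcripts$chrom,
                              transcripts$transcript_id)
  # order genomically within transcript, check non-overlap, assign ranks
  exons <- exons[order(match(exons$transcript_id,
                             transcripts$transcript_id), exons$start), ,
                 drop = FALSE]
  split_idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  rank <- integer(nrow(exons))
  for (tid in names(split_idx)) {
    i <- split_idx[[tid]]
    if (length(i) > 1 &&
        any(exons$start[i][-1] < exons$end[i][-length(i)]))
      stopf("overlapping exons in transcript '%s'", tid)
    rank[i] <- if (strand_of[[tid]] == "+") seq_along(i)
               else rev(seq_along(i))
  }
  exons$rank <- rank
  exons$chrom <- unname(chrom_of[exons$transcript_id])
  exons$strand <- unname(strand_of[exons$transcript_id])
  n_ex <- lengths(split_idx)[transcripts$transcript_id]
  transcripts$n_exons <- unname(n_ex)
  n_of <- stats::setNames(transcripts$n_exons, transcripts$transcript_id)
  ne <- unname(n_of[exons$transcript_id])
  exons$category <- ifelse(ne == 1L, "monoexonic",
                    ifelse(exons$rank == 1L, "first",
                    ifelse(exons$rank == ne, "last", "internal")))
  rownames(transcripts) <- rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  tr <- x$transcripts
  cat(sprintf(
    "genome_annotation: %d transcripts (%d monoexonic), %d exons\n",
    nrow(tr), sum(tr$n_exons == 1L), nrow(x$exons)))
  cat(sprintf("  chromosomes: %s; biotypes: %s\n",
              paste(unique(tr$chrom), collapse = ", "),
              paste(unique(tr$biotype), collapse = ", ")))
  invisible(x)
}

# exons of one transcript ordered 5'->3' in transcript orientation
transcript_exons <- function(ann, tid) {
  e <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
  e[order(e$rank), , drop = FALSE]
}

#' Load a GTF annotation
#'
#' Reads exon records from a GTF file (1-based closed intervals) into the
#' internal 0-based half-open representation, assigns exon ranks by
#' transcript orientation and drops non-matching biotypes.
#'
#' @param gtf_path path to a GTF file with `gene_id` and `transcript_id`
#'   attributes.
#' @param biotype_filter biotype to retain (default `"protein_coding"`);
#'   `NULL` keeps everything. If the file carries no biotype attribute at
#'   all, all transcripts are kept with a message.
#' @param representative `"all"` (default) or `"longest"`: for genes with
#'   several transcripts, keep only the one with the longest mature
#'   (summed-exon) length.
#' @return A [genome_annotation()].
#' @export
load_annotation <- function(gtf_path, biotype_filter = "protein_coding",
                            representative = c("all", "longest")) {
  representative <- match.arg(representative)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  gr <- gr[!is.na(md$type) & md$type == "exon"]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stopf("no exon records in %s", gtf_path)

  bio_col <- intersect(c("gene_biotype", "transcript_biotype",
                         "gene_type", "transcript_type"), names(md))[1]
  biotype <- if (!is.na(bio_col)) as.character(md[[bio_col]])
             else NA_character_
  if (!is.null(biotype_filter)) {
    if (all(is.na(biotype))) {
      message("load_annotation: no biotype attribute; keeping all records")
    } else {
      keep <- !is.na(biotype) & biotype == biotype_filter
      gr <- gr[keep]; md <- S4Vectors::mcols(gr)
      biotype <- biotype[keep]
      if (length(gr) == 0L)
        stopf("no exon records with biotype '%s'", biotype_filter)
    }
  }
  ex <- data.frame(transcript_id = as.character(md$transcript_id),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  first <- !duplicated(ex$transcript_id)
  tr <- data.frame(
    transcript_id = ex$transcript_id[first],
    gene_id = as.character(md$gene_id)[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    biotype = if (all(is.na(biotype))) "unknown" else biotype[first],
    stringsAsFactors = FALSE)
  if (any(tr$strand == "*"))
    stopf("unstranded exon records are not supported")
  ann <- genome_annotation(tr, ex)
  if (representative == "longest") {
    len <- tapply(ann$exons$end - ann$exons$start,
                  ann$exons$transcript_id, sum)
    tr <- ann$transcripts
    tr$mature_len <- unname(len[tr$transcript_id])
    tr <- tr[order(tr$gene_id, -tr$mature_len, tr$transcript_id), ]
    keep_ids <- tr$transcript_id[!duplicated(tr$gene_id)]
    ann$transcripts <-
      ann$transcripts[ann$transcripts$transcript_id %in% keep_ids, ,
                      drop = FALSE]
    ann$exons <- ann$exons[ann$exons$transcript_id %in% keep_ids, ,
                           drop = FALSE]
    rownames(ann$transcripts) <- rownames(ann$exons) <- NULL
  }
  ann
}

#' Write a genome annotation as GTF
#'
#' Emits one `exon` feature line per exon, 1-based closed coordinates,
#' with `gene_id`, `transcript_id`, `gene_biotype` and `exon_number`
#' attributes; [load_annotation()] round-trips the result exactly.
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  tr <- ann$transcripts
  bio <- stats::setNames(tr$biotype, tr$transcript_id)
  gid <- stats::setNames(tr$gene_id, tr$transcript_id)
  e <- ann$exons[order(match(ann$exons$transcript_id, tr$transcript_id),
                       ann$exons$start), , drop = FALSE]
  lines <- sprintf(
    paste0("%s\trnpscreen\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\"; ",
           "exon_number \"%d\";"),
    e$chrom, e$start + 1L, e$end, e$strand,
    gid[e$transcript_id], e$transcript_id, bio[e$transcript_id], e$rank)
  writeLines(lines, path)
  invisible(path)
}

#' Annotation simulator configuration
#'
#' @param n_transcripts number of transcripts to place.
#' @param exon_count_distribution named numeric vector of probabilities
#'   over exon counts >= 2 for multiexonic transcripts (names are the
#'   counts); normalised internally. The default is a negative-binomial
#'   shape over 2..30 exons with a mean near 8, a typical human mRNA.
#' @param exon_length_range,intron_length_range integer (min, max) in nt.
#' @param fraction_monoexonic fraction of single-exon transcripts.
#' @param fraction_minus_strand fraction on the minus strand.
#' @param seed integer seed.
#' @return A list of class `annotation_sim_config`.
#' @export
annotation_sim_config <- function(n_transcripts = 500,
                                  exon_count_distribution = NULL,
                                  exon_length_range = c(80L, 400L),
                                  intron_length_range = c(100L, 2000L),
                                  fraction_monoexonic = 0.1,
                                  fraction_minus_strand = 0.5,
                                  seed = 1L) {
  if (is.null(exon_count_distribution)) {
    k <- 2:30
    p <- stats::dnbinom(k - 2, size = 2, mu = 6)
    exon_count_distribution <- stats::setNames(p / sum(p), k)
  }
  if (!is_count(n_transcripts)) stopf("n_transcripts must be a count >= 1")
  if (is.null(names(exon_count_distribution)) ||
      any(exon_count_distribution < 0) ||
      sum(exon_count_distribution) <= 0)
    stopf("exon_count_distribution must be a named non-negative vector")
  if (any(as.integer(names(exon_count_distribution)) < 2))
    stopf("exon_count_distribution covers multiexonic counts (>= 2)")
  for (r in list(exon_length_range, intron_length_range))
    if (length(r) != 2 || any(r < 1) || r[2] < r[1])
      stopf("length ranges must be (min, max) with min >= 1")
  if (!is_fraction(fraction_monoexonic) ||
      !is_fraction(fraction_minus_strand))
    stopf("fractions must be in [0, 1]")
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    exon_count_distribution =
      exon_count_distribution / sum(exon_count_distribution),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    fraction_monoexonic = fraction_monoexonic,
    fraction_minus_strand = fraction_minus_strand,
    seed = as.integer(seed)), class = "annotation_sim_config")
}

#' Simulate a toy genome annotation
#'
#' Places non-overlapping mono- and multi-exonic transcripts sequentially
#' along a single synthetic chromosome (`"chrS"`), with exon and intron
#' lengths drawn uniformly from the configured ranges and strands
#' assigned at random. One gene per transcript.
#'
#' @param config an [annotation_sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(config = annotation_sim_config()) {
  stopifnot(inherits(config, "annotation_sim_config"))
  with_seed(config$seed, {
    n <- config$n_transcripts
    mono <- stats::runif(n) < config$fraction_monoexonic
    counts <- as.integer(names(config$exon_count_distribution))
    n_ex <- ifelse(mono, 1L,
                   counts[sample.int(length(counts), n, replace = TRUE,
                                     prob = config$exon_count_distribution)])
    minus <- stats::runif(n) < config$fraction_minus_strand
    cursor <- 1000L
    tr_list <- vector("list", n); ex_list <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_ex[i]
      er <- config$exon_length_range; ir <- config$intron_length_range
      elen <- er[1] + sample.int(er[2] - er[1] + 1L, k,
                                 replace = TRUE) - 1L
      ilen <- if (k > 1)
        ir[1] + sample.int(ir[2] - ir[1] + 1L, k - 1, replace = TRUE) - 1L
      else integer(0)
      starts <- cursor + cumsum(c(0L, utils::head(elen, -1) + ilen))
      ends <- starts + elen
      tid <- sprintf("tx%04d", i)
      tr_list[[i]] <- data.frame(
        transcript_id = tid, gene_id = sprintf("gene%04d", i),
        chrom = "chrS", strand = if (minus[i]) "-" else "+",
        biotype = "protein_coding", stringsAsFactors = FALSE)
      ex_list[[i]] <- data.frame(transcript_id = tid, start = starts,
                                 end = ends, stringsAsFactors = FALSE)
      cursor <- ends[length(ends)] + 500L
    }
    genome_annotation(do.call(rbind, tr_list), do.call(rbind, ex_list))
  })
}
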