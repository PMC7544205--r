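test_that("conversion calling counts the diagnostic mismatches only", {
  trk <- call_conversions(c(
    "chr1\t100\tT\t5\t..CC.\tIIIII",     # plus strand: 2 x T>C
    "chr1\t200\tA\t4\t,,gg\tIIII",       # minus strand: 2 x A>G
    "chr1\t300\tG\t3\tAAa\tIII",         # non-T/A reference: ignored
    "chr1\t400\tT\t3\t,cc\tIII",         # lowercase c is a reverse read
    "chr1\t500\tA\t3\tGG,\tIII"))        # uppercase G is a forward read
  expect_identical(nrow(trk), 2L)
  expect_identical(trk$pos, c(99L, 199L))
  expect_identical(trk$strand, c("+", "-"))
  expect_equal(trk$score, c(2, 2))
})

test_that("pileup grammar tokens are skipped but counted correctly", {
  trk <- call_conversions(c(
    "chr1\t10\tT\t4\t^I..C$.\tIIII",       # read start/end markers
    "chr1\t20\tT\t3\t.+2AG.C\tIII",        # insertion after first read
    "chr1\t30\tA\t5\t,-1t,gg*\tIIIII",     # deletion token + * placeholder
    "chr1\t40\tT\t2\t><\tII"))             # reference skips, no mismatch
  expect_identical(trk$pos, c(9L, 19L, 29L))
  expect_equal(trk$score, c(1, 1, 2))
})

test_that("depth inconsistencies and malformed lines are hard errors", {
  expect_error(call_conversions("chr1\t10\tT\t9\t..C\tIII"),
               "line 1.*inconsistent")
  expect_error(
    call_conversions(c("chr1\t10\tT\t3\t..C\tIII",
                       "chr1\t20\tT\t4\t..C\tIII")),
    "line 2")
  expect_error(call_conversions("chr1\t10\tT\t3"), "6 expected")
})

test_that("conversion counts are invariant to pileup line order", {
  lines <- c("chr1\t100\tT\t5\t..CC.\tIIIII",
             "chr1\t50\tA\t4\t,,gg\tIIII",
             "chr2\t10\tT\t2\tCC\tII")
  expect_identical(call_conversions(lines),
                   call_conversions(rev(lines)))
})

test_that("BED intervals expand per base and overlaps sum", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t13\tr1\t3\t+",
               "chr1\t12\t14\tr2\t5\t+",
               "chr1\t10\t12\tr3\t4\t-"), path)
  trk <- load_track_bed(path)
  plus <- trk[trk$strand == "+", ]
  expect_identical(plus$pos, c(10L, 11L, 12L, 13L))
  expect_identical(plus$score, c(3, 3, 8, 5))      # overlap at 12 sums
  dens <- load_track_bed(path, mode = "density")
  expect_identical(dens$score[dens$strand == "+"], c(1, 1, 3.5, 2.5))

  writeLines(character(0), path)
  expect_identical(nrow(load_track_bed(path)), 0L)

  writeLines("chr1\t1\t2\tr\t1\t.", path)
  expect_error(load_track_bed(path), "strand.*line 1")
})

test_that("metagene profiles are flat for uniform signal, TSS mass in bin 1", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "+", exons = list(c(0, 100), c(200, 300)))))
  uni <- make_track("chrT", c(0:99, 200:299), "+", rep(1, 200))
  prof <- metagene_transcript_profile(uni, ann, n_bins = 20)
  expect_equal(prof$profile$sum_signal, rep(10, 20))
  expect_equal(sum(prof$profile$sum_signal), sum(uni$score))

  tss <- make_track("chrT", 0, "+", 5)
  p2 <- metagene_transcript_profile(tss, ann, n_bins = 20)
  expect_equal(p2$profile$sum_signal[1], 5)
  expect_equal(sum(p2$profile$sum_signal[-1]), 0)

  # minus-strand TSS is the genomically rightmost base
  ann_m <- tiny_annotation(list(
    t1 = list(strand = "-", exons = list(c(0, 100), c(200, 300)))))
  tss_m <- make_track("chrT", 299, "-", 5)
  p3 <- metagene_transcript_profile(tss_m, ann_m, n_bins = 20)
  expect_equal(p3$profile$sum_signal[1], 5)
})

test_that("signal on the wrong strand or in introns does not contribute", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "+", exons = list(c(0, 100), c(200, 300)))))
  trk <- make_track("chrT", c(50, 150, 60), c("+", "+", "-"), c(2, 7, 9))
  prof <- metagene_transcript_profile(trk, ann, n_bins = 10)
  expect_equal(sum(prof$profile$sum_signal), 2)   # intron + wrong strand out
})

test_that("transcripts shorter than the bin count use fractional binning", {
  ann <- tiny_annotation(list(short = list(strand = "+",
                                           exons = list(c(0, 4)))))
  trk <- make_track("chrT", 0:3, "+", rep(1, 4))
  prof <- metagene_transcript_profile(trk, ann, n_bins = 8)
  expect_equal(prof$profile$sum_signal, rep(0.5, 8))
})

test_that("exon-anchored profiles apply the strict >200 nt filter", {
  ann <- tiny_annotation(list(
    a = list(strand = "+", exons = list(c(0, 150), c(1000, 1201),
                                        c(2000, 2400))),
    b = list(strand = "+", exons = list(c(5000, 5200), c(6000, 6300)))))
  # internal exon of a: length 201 -> included; first exon of b: 200 -> out
  trk <- make_track("chrT", c(1000, 5000), "+", c(4, 9))
  internal <- exon_anchored_profile(trk, ann, "internal",
                                    flank_bins = 10, body_bins = 20)
  expect_identical(internal$n, 1L)
  expect_equal(sum(internal$profile$sum_signal), 4)
  first <- suppressWarnings(
    exon_anchored_profile(trk, ann, "first", flank_bins = 10,
                          body_bins = 20))
  expect_identical(first$n, 0L)        # 150 and 200 both fail > 200
  expect_warning(exon_anchored_profile(make_track("chrT", 1, "+", 1),
                                       tiny_annotation(list(
                                         m = list(strand = "+",
                                                  exons = list(c(0, 50))))),
                                       "monoexonic"),
                 "no monoexonic exons")
})

test_that("averaging identical exons equals the single-exon profile", {
  ann1 <- tiny_annotation(list(
    a = list(strand = "+", exons = list(c(0, 250), c(1000, 1250),
                                        c(2000, 2250)))))
  ann2 <- tiny_annotation(list(
    a = list(strand = "+", exons = list(c(0, 250), c(1000, 1250),
                                        c(2000, 2250))),
    b = list(strand = "+", exons = list(c(5000, 5250), c(6000, 6250),
                                        c(7000, 7250)))))
  trk1 <- make_track("chrT", c(1005, 1100), "+", c(3, 2))
  trk2 <- make_track("chrT", c(1005, 1100, 6005, 6100), "+",
                     c(3, 2, 3, 2))
  p1 <- exon_anchored_profile(trk1, ann1, "internal", flank_bins = 20,
                              body_bins = 30)
  p2 <- exon_anchored_profile(trk2, ann2, "internal", flank_bins = 20,
                              body_bins = 30)
  expect_equal(p2$profile$mean_signal, p1$profile$mean_signal)
  expect_identical(p2$n, 2L)
})

test_that("junction offsets anchor at the last exonic base", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "+", exons = list(c(0, 100), c(200, 300),
                                         c(400, 500)))))
  # 3'-terminal base of internal exon [200,300) is 299 -> offset 1
  trk <- make_track("chrT", 299, "+", 6)
  h <- junction_offset_histogram(trk, ann, max_offset = 10)
  expect_equal(h$count[1], 6)
  expect_equal(sum(h$count[-1]), 0)

  # last exons have no downstream junction
  trk_last <- make_track("chrT", 499, "+", 4)
  h2 <- junction_offset_histogram(trk_last, ann, max_offset = 10)
  expect_equal(sum(h2$count), 0)
})

test_that("minus-strand offsets count from the exon's genomic left end", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "-", exons = list(c(0, 100), c(200, 300)))))
  # internal/first exon in transcript orientation is [200,300);
  # its 3' end (junction side) is genomic start 200; k = 3 -> pos 202
  trk <- make_track("chrT", 202, "-", 2)
  h <- junction_offset_histogram(trk, ann, max_offset = 10)
  expect_equal(h$count[3], 2)
  expect_equal(sum(h$count[-3]), 0)
})

test_that("simulated fixed-offset conversions round-trip through the caller", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 40,
                                                   seed = 19))
  sim <- simulate_clip(ann, clip_sim_config(offset_distribution = 27,
                                            seed = 4))
  trk <- call_conversions(sim$pileup)
  h <- junction_offset_histogram(trk, ann, max_offset = 50)
  expect_gt(h$count[27], 0)
  expect_equal(sum(h$count[-27]), 0)
})

test_that("simulated minus-strand events are reference A with g mismatches", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "-", exons = list(c(0, 100), c(200, 300)))))
  sim <- simulate_clip(ann, clip_sim_config(offset_distribution = 5,
                                            conversion_rate = 1,
                                            events_per_junction = 2,
                                            seed = 2))
  f <- strsplit(sim$pileup[1], "\t")[[1]]
  expect_identical(f[3], "A")
  expect_true(grepl("^g+$", f[5]))
  expect_identical(as.integer(f[2]) - 1L, 204L)   # start + offset - 1
})

test_that("zero conversion rate yields an empty conversion track", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 20,
                                                   seed = 3))
  sim <- simulate_clip(ann, clip_sim_config(conversion_rate = 0, seed = 6))
  expect_identical(nrow(call_conversions(sim$pileup)), 0L)
  expect_identical(nrow(sim$bed), 0L)
})

test_that("generators are deterministic and BED output matches the track", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 25,
                                                   seed = 14))
  cfg <- clip_sim_config(seed = 8)
  s1 <- simulate_clip(ann, cfg); s2 <- simulate_clip(ann, cfg)
  expect_identical(s1$pileup, s2$pileup)
  expect_identical(s1$truth, s2$truth)

  # BED conversion sites agree with the pileup-called track
  path <- withr::local_tempfile(fileext = ".bed")
  write_clip_sim(s1, bed_path = path)
  bed_trk <- load_track_bed(path)
  conv_trk <- call_conversions(s1$pileup)
  expect_equal(as.data.frame(bed_trk), as.data.frame(conv_trk))
})

test_that("profiles are invariant under coordinate reflection + strand flip", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 30,
                                                   seed = 23))
  sim <- simulate_clip(ann, clip_sim_config(seed = 31))
  trk <- call_conversions(sim$pileup)
  L <- max(ann$exons$end) + 1000L
  ann_m <- mirror_annotation(ann, L)
  trk_m <- mirror_track(trk, L)

  expect_identical(
    metagene_transcript_profile(trk, ann, 40)$profile,
    metagene_transcript_profile(trk_m, ann_m, 40)$profile)
  expect_identical(
    junction_offset_histogram(trk, ann, 50),
    junction_offset_histogram(trk_m, ann_m, 50))
  for (cat in c("first", "internal", "last")) {
    expect_identical(
      exon_anchored_profile(trk, ann, cat, min_exon_len = 100,
                            flank_bins = 20, body_bins = 30)$profile,
      exon_anchored_profile(trk_m, ann_m, cat, min_exon_len = 100,
                            flank_bins = 20, body_bins = 30)$profile)
  }
})
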