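de_fixture <- function() {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tbaseMean\tlog2FoldChange\tpadj",
               "t1\t100\t-1\t0.05",
               "t2\t200\t-5\t0.2",
               "t3\t300\t2\t0.01",
               "t4\t400\t3\tNA",
               "t5\t150\t0.1\t0.9"), path)
  path
}

test_that("direction assignment follows the FDR cutoff", {
  t <- load_de_table(de_fixture(), fdr_level = 0.1)
  dir <- setNames(t$direction, t$id)
  expect_identical(dir[["t1"]], "down")      # padj 0.05, lfc < 0
  expect_identical(dir[["t2"]], "unchanged") # padj 0.2 above cutoff
  expect_identical(dir[["t3"]], "up")
  expect_identical(dir[["t4"]], "unchanged") # untested (padj NA)
  expect_identical(dir[["t5"]], "unchanged")
})

test_that("missing required columns are a hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tbaseMean\tpadj", "t1\t10\t0.5"), path)
  expect_error(load_de_table(path), "log2FoldChange")
})

test_that("exon counts are attached from the annotation, orphans dropped", {
  ann <- tiny_annotation(list(
    t1 = list(strand = "+", exons = list(c(0, 10), c(20, 30), c(40, 50))),
    t3 = list(strand = "-", exons = list(c(100, 200)))))
  t <- load_de_table(de_fixture())
  expect_message(t2 <- attach_exon_counts(t, ann), "dropped 3")
  expect_setequal(t2$id, c("t1", "t3"))
  expect_identical(t2$exon_count[t2$id == "t1"], 3L)
  expect_identical(t2$exon_count[t2$id == "t3"], 1L)
})

test_that("per-direction ECDFs step over integer exon counts", {
  t <- de_table(data.frame(id = paste0("x", 1:5),
                           baseMean = 100, log2FoldChange = c(1, 1, 1, -1, -1),
                           padj = 0.01), fdr_level = 0.1)
  t$exon_count <- c(1, 1, 2, 4, 4)
  e <- exon_count_ecdf(t)
  expect_equal(e$up(1), 2 / 3)
  expect_equal(e$up(2), 1)
  expect_equal(e$up(0.5), 0)
  expect_equal(e$down(4), 1)
  t_onesided <- t[t$direction == "up", ]
  expect_error(exon_count_ecdf(t_onesided), "down")
})

test_that("Mann-Whitney matches hand enumeration on the 2v2 example", {
  r <- mann_whitney(c(1, 2), c(10, 11), mode = "exact")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
})

test_that("identical samples give the null U and p near 1", {
  x <- c(3, 5, 5, 8)
  r <- mann_whitney(x, x, mode = "exact")
  expect_equal(unname(r$statistic), length(x)^2 / 2)
  expect_equal(r$p.value, 1)
})

test_that("exact p equals brute-force enumeration on random small samples", {
  set.seed(55)
  for (i in 1:12) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:8, nx, replace = TRUE)   # ties likely
    y <- sample(1:8, ny, replace = TRUE)
    got <- mann_whitney(x, y, mode = "exact")
    want <- oracle_mw_exact(x, y)
    expect_equal(unname(got$statistic), want$U)
    expect_equal(got$p.value, want$p, tolerance = 1e-12)
  }
})

test_that("exact p agrees with wilcox.test on tie-free samples", {
  set.seed(77)
  for (i in 1:8) {
    x <- sample(1:1000, 6); y <- sample(1001:2000, 6)
    got <- mann_whitney(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("U_x + U_y = n_x * n_y and the normal path is close to exact", {
  set.seed(91)
  for (i in 1:10) {
    x <- rpois(10, 6) + 1; y <- rpois(10, 8) + 1
    ux <- unname(mann_whitney(x, y, mode = "normal")$statistic)
    uy <- unname(mann_whitney(y, x, mode = "normal")$statistic)
    expect_equal(ux + uy, length(x) * length(y))
  }
  x <- c(2, 9, 14, 30, 41, 55, 67, 71, 88, 93)
  y <- c(5, 12, 19, 33, 47, 52, 69, 80, 90, 99)
  pe <- mann_whitney(x, y, mode = "exact")$p.value
  pn <- mann_whitney(x, y, mode = "normal")$p.value
  expect_lt(abs(pe - pn), 0.01)
})

test_that("exact mode refuses combinatorial blow-ups", {
  expect_error(mann_whitney(1:11, 12:22, mode = "exact"), "refused")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("expression matching pairs identical baseMean multisets fully", {
  t <- de_table(data.frame(
    id = paste0("x", 1:8), baseMean = rep(c(10, 50, 200, 1000), 2),
    log2FoldChange = rep(c(2, -2), each = 4), padj = 0.01),
    fdr_level = 0.1)
  m <- expression_match(t, caliper_log10 = 0, seed = 1)
  expect_identical(nrow(m), 8L)
  expect_identical(sum(m$direction == "up"), sum(m$direction == "down"))

  # no exact duplicates with a zero caliper -> error
  t$baseMean <- seq(10, 80, 10)
  expect_error(expression_match(t, caliper_log10 = 0, seed = 1),
               "caliper")
})

test_that("matching balances expression on a skewed instance", {
  set.seed(8)
  n <- 150
  up <- data.frame(id = sprintf("u%03d", 1:n),
                   baseMean = 10^rnorm(n, 1.6, 0.4),
                   log2FoldChange = 2, padj = 0.01)
  dn <- data.frame(id = sprintf("d%03d", 1:n),
                   baseMean = 10^rnorm(n, 2.4, 0.4),
                   log2FoldChange = -2, padj = 0.01)
  t <- de_table(rbind(up, dn), fdr_level = 0.1)
  m <- expression_match(t, caliper_log10 = 0.1, seed = 2)
  bm_up <- log10(m$baseMean[m$direction == "up"])
  bm_dn <- log10(m$baseMean[m$direction == "down"])
  expect_gt(mann_whitney(bm_up, bm_dn, mode = "normal")$p.value, 0.5)

  # matching reduces the between-group baseMean KS distance
  ks_pre <- ks.test(log10(t$baseMean[t$direction == "up"]),
                    log10(t$baseMean[t$direction == "down"]))$statistic
  ks_post <- ks.test(bm_up, bm_dn)$statistic
  expect_lt(ks_post, ks_pre)
})

test_that("simulated DE tables are deterministic with sane padj values", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 120,
                                                   seed = 2))
  cfg <- de_sim_config(seed = 77)
  s1 <- simulate_de_table(ann, cfg)
  expect_identical(s1$table, simulate_de_table(ann, cfg)$table)
  padj <- s1$table$padj
  expect_true(all(padj >= 0 & padj <= 1, na.rm = TRUE))
  # direction calls agree with planted truth
  expect_identical(s1$table$direction, s1$truth$direction)
})

test_that("the exon-bias wrapper combines test, ECDFs and matching", {
  ann <- simulate_annotation(annotation_sim_config(n_transcripts = 600,
                                                   seed = 6))
  sim <- simulate_de_table(ann, de_sim_config(
    effect_model = list(p_up = 0.2,
                        p_down = function(k) ifelse(k >= 8, 0.5, 0.05),
                        lfc_mean = 1.5, lfc_sd = 0.5),
    seed = 10))
  t <- attach_exon_counts(sim$table, ann)
  bt <- exon_bias_test(t)
  expect_identical(bt$n_up, sum(t$direction == "up"))
  expect_true(bt$p < 0.01)   # strong planted threshold effect
  expect_s3_class(bt$test, "htest")
  bm <- exon_bias_test(t, match = TRUE, caliper_log10 = 0.3, seed = 4)
  expect_identical(bm$n_up, bm$n_down)
  expect_false(is.null(bm$matched_ids))
})
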