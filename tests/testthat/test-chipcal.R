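mk_models <- function(starts, ends, chrom = "c1", strand = NULL) {
  n <- length(starts)
  if (is.null(strand)) strand <- rep("+", n)
  df <- data.frame(gene_id = sprintf("G%03d", seq_len(n)),
                   tx_id = sprintf("G%03d.t1", seq_len(n)),
                   chrom = chrom, strand = strand,
                   start = as.integer(starts), end = as.integer(ends),
                   case = "plain", stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

grs <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

test_that("extended gene regions pad, clamp and merge", {
  cs <- c(c1 = 100000)
  ext <- build_extended_regions(mk_models(10000, 20000), 5000, cs)
  expect_equal(grs(ext), data.frame(start = 5000L, end = 25000L))

  ext2 <- build_extended_regions(mk_models(2000, 4000), 5000, cs)
  expect_equal(grs(ext2)$start, 0L)

  ext3 <- build_extended_regions(mk_models(c(12000, 14000),
                                           c(13000, 15000)), 5000, cs)
  expect_equal(grs(ext3), data.frame(start = 7000L, end = 20000L))

  expect_error(build_extended_regions(mk_models(1, 2, chrom = "cX"),
                                      5000, cs), "cX")
})

test_that("intergenic complement is exact and partitions the chromosome", {
  cs <- c(c1 = 100000)
  ext <- build_extended_regions(mk_models(10000, 20000), 5000, cs)
  ig <- intergenic_complement(ext)
  expect_equal(grs(ig), data.frame(start = c(0L, 25000L),
                                   end = c(5000L, 100000L)))
  expect_equal(sum(GenomicRanges::width(ext)) +
                 sum(GenomicRanges::width(ig)), 100000)

  # extended covering everything leaves nothing intergenic
  ext_all <- build_extended_regions(mk_models(0, 100000), 5000, cs)
  expect_equal(length(intergenic_complement(ext_all)), 0L)

  # blacklisted artefact regions are carved out of the intergenic set
  bl <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  ig_bl <- intergenic_complement(ext, blacklist = bl)
  expect_equal(grs(ig_bl), data.frame(start = c(1000L, 25000L),
                                      end = c(5000L, 100000L)))

  # random interval sets vs per-base membership on a 10 kb chromosome
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- sample(1:6, 1)
      st <- sort(sample(seq(0, 9000, by = 250), n))
      en <- pmin(st + sample(200:1500, n, replace = TRUE), 10000)
      keep <- c(TRUE, st[-1] > cummax(en[-n]))  # avoid overlaps for oracle
      st <- st[keep]; en <- en[keep]
      m <- mk_models(st, en)
      ext <- build_extended_regions(m, 500, c(c1 = 10000))
      ig <- intergenic_complement(ext)
      mask <- oracle_complement_mask(pmax(st - 500, 0),
                                     pmin(en + 500, 10000), 10000)
      ig_mask <- logical(10000)
      df <- grs(ig)
      for (i in seq_len(nrow(df)))
        if (df$end[i] > df$start[i])
          ig_mask[(df$start[i] + 1):df$end[i]] <- TRUE
      expect_identical(ig_mask, mask)
    }
  })
})

test_that("intergenic scaling factors use the geometric-mean reference", {
  ig <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10000))
  mk_reads <- function(n, start0 = 100) {
    data.frame(chrom = "c1", start = seq(start0, by = 3, length.out = n),
               end = seq(start0, by = 3, length.out = n) + 50,
               name = ".", score = 0, strand = "+",
               stringsAsFactors = FALSE)
  }
  f <- intergenic_scaling_factors(list(a = mk_reads(500),
                                       b = mk_reads(500)), ig)
  expect_equal(as.numeric(f), c(1, 1))
  f2 <- intergenic_scaling_factors(list(a = mk_reads(1000),
                                        b = mk_reads(2000)), ig)
  expect_equal(as.numeric(f2), c(sqrt(2), 1 / sqrt(2)))

  outside <- mk_reads(100, start0 = 20000)
  expect_error(intergenic_scaling_factors(list(mk_reads(10), outside),
                                          ig), "zero intergenic")

  # 5'-end convention: same interval, strand decides which end is tested
  straddle_plus <- data.frame(chrom = "c1", start = 9990, end = 10040,
                              name = ".", score = 0, strand = "+")
  straddle_minus <- transform(straddle_plus, strand = "-")
  cnt <- attr(intergenic_scaling_factors(
    list(rbind(straddle_plus, straddle_plus),
         rbind(straddle_plus, straddle_minus)), ig),
    "intergenic_count")
  expect_equal(unname(cnt), c(2, 1))  # minus 5' end (10039) lies outside
})

test_that("binned coverage extends single-end reads in orientation", {
  cs <- c(c1 = 1000)
  rd <- data.frame(chrom = "c1", start = 100, end = 150, name = ".",
                   score = 0, strand = "+")
  cov <- binned_coverage(rd, cs, bin = 20, extend = 200)
  covered <- which(cov$score > 0)
  expect_equal(covered, (100 %/% 20 + 1):(299 %/% 20 + 1))  # [100, 300)

  rd_m <- data.frame(chrom = "c1", start = 400, end = 450, name = ".",
                     score = 0, strand = "-")
  cov_m <- binned_coverage(rd_m, cs, bin = 20, extend = 200)
  expect_equal(which(cov_m$score > 0),
               (250 %/% 20 + 1):(449 %/% 20 + 1))  # [250, 450)

  expect_true(all(binned_coverage(rd[0, ], cs)$score == 0))
  cov2 <- binned_coverage(rbind(rd, rd), cs)
  expect_equal(cov2$score, 2 * cov$score)

  # paired mode takes fragments as given
  cov_p <- binned_coverage(rd, cs, bin = 20, paired = TRUE)
  expect_equal(which(cov_p$score > 0), (100 %/% 20 + 1):(149 %/% 20 + 1))
})

test_that("scaling is elementwise and validated", {
  cs <- c(c1 = 1000)
  rd <- data.frame(chrom = "c1", start = 100, end = 150, name = ".",
                   score = 0, strand = "+")
  cov <- binned_coverage(rd, cs)
  expect_equal(apply_scaling(cov, 1)$score, cov$score)
  expect_equal(apply_scaling(cov, 0.5)$score, cov$score * 0.5)
  expect_error(apply_scaling(cov, 0), "positive")
  expect_equal(coverage_difference(apply_scaling(cov, 2), cov)$score,
               cov$score)
})

test_that("fpkm follows the closed formula", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(100, 1000, 2e6), 50)
  expect_error(fpkm(1, 0, 10), "lengths")
})

test_that("expression classes use interpolated quantiles of expressed genes", {
  fp <- c(rep(0, 10), 1:100)
  cls <- classify_expression(fp)
  expect_equal(attr(cls, "q5"), 5.95)
  expect_equal(attr(cls, "q95"), 95.05)
  expect_true(all(cls[1:10] == "silent"))
  expect_equal(as.character(cls[fp == 100]), "high")
  expect_equal(as.character(cls[fp == 3]), "low")
  expect_equal(as.character(cls[fp == 50]), "medium")

  # equal FPKM everywhere: q5 = q95, all medium
  cls2 <- classify_expression(rep(2, 30))
  expect_true(all(cls2 == "medium"))

  expect_error(classify_expression(c(rep(0, 30), 1:5)), "too few")
})

test_that("metagene matrix has scale-regions semantics and orientation", {
  cs <- c(c1 = 10000)
  m <- mk_models(4000, 6000)
  # uniform coverage -> flat profile
  cov <- binned_coverage(data.frame(chrom = "c1", start = 1, end = 9999,
                                    name = ".", score = 0, strand = "+"),
                         cs, bin = 20, paired = TRUE)
  mg <- metagene_matrix(cov, m, flank = 1000, n_body_bins = 50)
  expect_equal(ncol(mg$matrix), 150)
  expect_true(sd(mg$profile) < 1e-12)

  # body-only enrichment shows up between the TSS and TES columns only
  cov2 <- cov
  cov2$score <- ifelse(GenomicRanges::start(cov2) > 4000 &
                         GenomicRanges::end(cov2) <= 6000, 10, 0)
  mg2 <- metagene_matrix(cov2, m, flank = 1000, n_body_bins = 50)
  expect_true(all(mg2$profile[51:100] == 10))
  expect_true(all(mg2$profile[c(1:50, 101:150)] == 0))

  # minus-strand gene: 5'-skewed coverage appears on the left of its row
  m_m <- mk_models(4000, 6000, strand = "-")
  cov3 <- cov
  cov3$score <- ifelse(GenomicRanges::start(cov3) > 5800 &
                         GenomicRanges::end(cov3) <= 6000, 7, 0)
  mg3 <- metagene_matrix(cov3, m_m, flank = 1000, n_body_bins = 50)
  body3 <- mg3$matrix[1, 51:100]
  expect_true(all(body3[1:5] == 7))
  expect_true(all(body3[6:50] == 0))
})

test_that("calibration recovers a programmed binding ratio and depth
           invariance", {
  cfg <- sim_config(seed = 77, chrom_sizes = c(c1 = 200000))
  cs <- cfg$chrom_sizes
  models <- gen_gene_models(cfg, n_genes = 6, edge_cases = FALSE)
  expr <- stats::setNames(rep(2, 6), unique(models$gene_id))
  ext <- build_extended_regions(models, 5000, cs)
  ig <- intergenic_complement(ext)

  mk <- function(scale, depth, seed)
    gen_chip_reads(models, expr, background_density = 4000,
                   binding_scale = scale, depth = depth,
                   chrom_sizes = cs, seed = seed)
  rA <- mk(1, 1, 301); rB <- mk(0.5, 1, 302); rC <- mk(1, 2, 303)
  f <- intergenic_scaling_factors(list(A = rA, B = rB, C = rC), ig)
  covA <- apply_scaling(binned_coverage(rA, cs), f[["A"]])
  covB <- apply_scaling(binned_coverage(rB, cs), f[["B"]])
  covC <- apply_scaling(binned_coverage(rC, cs), f[["C"]])

  ratio <- gene_body_mean_coverage(covB, models) /
    gene_body_mean_coverage(covA, models)
  expect_equal(ratio, 0.5, tolerance = 0.1)

  # depth-doubled sample matches the original on intergenic bins
  ig_sel <- IRanges::overlapsAny(covA, ig, type = "within")
  mard <- mean(abs(covC$score[ig_sel] - covA$score[ig_sel]) /
                 mean(covA$score[ig_sel]))
  expect_lt(mard, 0.05)
})

test_that("gene-body signal rises with expression class on synthetic data", {
  cfg <- sim_config(seed = 55, chrom_sizes = c(c1 = 300000))
  cs <- cfg$chrom_sizes
  models <- gen_gene_models(cfg, n_genes = 12, edge_cases = FALSE)
  gids <- unique(models$gene_id)
  expr <- stats::setNames(rep(c(0.2, 1, 4), each = 4), gids)
  reads <- gen_chip_reads(models, expr, background_density = 500,
                          binding_scale = 1, chrom_sizes = cs, seed = 56)
  cov <- binned_coverage(reads, cs)
  by_gene <- vapply(gids, function(g)
    gene_body_mean_coverage(cov, models[models$gene_id == g, ]),
    numeric(1))
  grp <- rep(c("low", "medium", "high"), each = 4)
  med <- tapply(by_gene, grp, median)
  expect_lt(med[["low"]], med[["medium"]])
  expect_lt(med[["medium"]], med[["high"]])
})
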