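test_that("gene models respect chromosome bounds and carry edge cases", {
  cfg <- sim_config(seed = 19)
  m <- gen_gene_models(cfg, n_genes = 150)
  expect_true(all(m$start >= 0))
  expect_true(all(m$end <= cfg$chrom_sizes[m$chrom]))
  expect_true(all(m$end > m$start))

  # gene bodies never nest or overlap across genes
  sp <- split(m, m$chrom)
  for (chrom_m in sp) {
    spans <- do.call(rbind, lapply(split(chrom_m, chrom_m$gene_id),
      function(g) c(min(g$start), max(g$end))))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  }

  # constructed cases present, with the promised structure
  tie <- m[m$case == "tie" & m$strand == "+", ]
  expect_equal(nrow(tie), 2)
  expect_equal(length(unique(tie$start)), 2)
  ss <- m[m$case == "shared_start" & m$strand == "+", ]
  expect_equal(length(unique(ss$start)), 1)
  expect_equal(length(unique(ss$end)), 2)
  ssm <- m[m$case == "shared_start" & m$strand == "-", ]
  expect_equal(length(unique(ssm$end)), 1)
  edge_start <- m[m$case == "chrom_start_edge", ]
  expect_true(all(edge_start$start < 5000))
  edge_end <- m[m$case == "chrom_end_edge", ]
  expect_true(all(cfg$chrom_sizes[edge_end$chrom] - edge_end$end < 5000))

  # single gene on a small chromosome stays inside it
  cfg1 <- sim_config(seed = 1, chrom_sizes = c(mini = 10000))
  m1 <- gen_gene_models(cfg1, n_genes = 1, edge_cases = FALSE)
  expect_true(all(m1$start >= 0 & m1$end <= 10000))

  # chromosome shorter than a gene is rejected
  expect_error(gen_gene_models(sim_config(chrom_sizes = c(tiny = 3000)),
                               n_genes = 1), "too short")
})

test_that("3'-end tracks stay in gene bodies on the gene strand", {
  cfg <- sim_config(seed = 23)
  m <- gen_gene_models(cfg, n_genes = 30)
  tr <- gen_threeprime_track(m, rate = 50, seed = 23)

  m_plain <- gen_gene_models(cfg, n_genes = 10, edge_cases = FALSE)
  expect_equal(nrow(gen_threeprime_track(m_plain, rate = 0, seed = 23)), 0)

  spans <- split(m, m$gene_id)
  for (i in seq_len(nrow(tr))) {
    hit <- FALSE
    for (g in spans) {
      if (g$chrom[1] == tr$chrom[i] && g$strand[1] == tr$strand[i] &&
          tr$pos[i] >= min(g$start) && tr$pos[i] < max(g$end)) hit <- TRUE
    }
    if (!hit) break
  }
  expect_true(hit)

  # minus-strand gene contributes only minus-strand counts
  mm <- m[m$strand == "-", ]
  trm <- gen_threeprime_track(mm, rate = 50, seed = 24)
  expect_true(all(trm$strand == "-"))

  # Poisson total: 1 kb gene at rate 100 -> 100 +- 3 sd
  one <- data.frame(gene_id = "G1", tx_id = "G1.t1", chrom = "c1",
                    strand = "+", start = 0L, end = 1000L, case = "plain",
                    stringsAsFactors = FALSE)
  class(one) <- c("gene_models", "data.frame")
  tot <- sum(gen_threeprime_track(one, rate = 100, seed = 25)$count)
  expect_lt(abs(tot - 100), 3 * sqrt(100))

  # determinism
  expect_identical(gen_threeprime_track(m, rate = 50, seed = 23),
                   gen_threeprime_track(m, rate = 50, seed = 23))
})

test_that("ChIP read generator separates signal from background", {
  cfg <- sim_config(seed = 29, chrom_sizes = c(c1 = 150000))
  cs <- cfg$chrom_sizes
  m <- gen_gene_models(cfg, n_genes = 5, edge_cases = FALSE)
  gids <- unique(m$gene_id)
  expr <- stats::setNames(rep(1, 5), gids)
  sp <- hypertx:::gene_spans(m)
  in_body <- function(reads) {
    hit <- rep(FALSE, nrow(reads))
    for (i in seq_len(nrow(sp)))
      hit <- hit | (reads$start >= sp$start[i] & reads$start < sp$end[i])
    hit
  }

  # binding_scale 0: background only
  r0 <- gen_chip_reads(m, expr, background_density = 300,
                       binding_scale = 0, chrom_sizes = cs, seed = 1)
  expect_false(any(in_body(r0)))

  # halving binding_scale halves the body/background density ratio
  r1 <- gen_chip_reads(m, expr, background_density = 300,
                       binding_scale = 1, chrom_sizes = cs, seed = 2)
  r05 <- gen_chip_reads(m, expr, background_density = 300,
                        binding_scale = 0.5, chrom_sizes = cs, seed = 3)
  ratio_of <- function(r) sum(in_body(r)) / sum(!in_body(r))
  expect_equal(ratio_of(r05) / ratio_of(r1), 0.5, tolerance = 0.1)

  # doubling depth doubles the background count within sampling error
  r2 <- gen_chip_reads(m, expr, background_density = 300,
                       binding_scale = 1, depth = 2, chrom_sizes = cs,
                       seed = 4)
  expect_equal(sum(!in_body(r2)) / sum(!in_body(r1)), 2,
               tolerance = 0.05)

  expect_error(gen_chip_reads(m, expr, background_density = 0,
                              chrom_sizes = cs), "background_density")
})

test_that("file round-trips preserve the core objects", {
  cfg <- sim_config(seed = 37, n_genes = 40, n_spikein = 8)
  sim <- gen_spikein_counts(cfg)
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$matrix, cp, sp)
  back <- read_counts_tsv(cp, sp)
  expect_identical(back$counts, sim$matrix$counts)
  expect_identical(back$is_spikein, sim$matrix$is_spikein)

  m <- gen_gene_models(cfg, n_genes = 20)
  tr <- gen_threeprime_track(m, rate = 40, seed = 37,
                             chrom_sizes = cfg$chrom_sizes)
  prefix <- withr::local_tempfile()
  write_bedgraph_pair(tr, prefix)
  tr2 <- read_bedgraph_pair(paste0(prefix, "_plus.bedGraph"),
                            paste0(prefix, "_minus.bedGraph"),
                            chrom_sizes = cfg$chrom_sizes)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))

  gm <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(m, gm)
  expect_equal(as.data.frame(read_gene_models(gm)), as.data.frame(m))

  p <- tweezer_params()
  scan <- gen_force_scan(p, TRUE, seed = 38)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_force_scan_tsv(scan, fp)
  scan2 <- read_force_scan_tsv(fp)
  expect_equal(scan2$height_nm, scan$height_nm, tolerance = 1e-6)
  expect_equal(summarize_scan(scan2)$mean_nm, summarize_scan(scan)$mean_nm,
               tolerance = 1e-6)
})

test_that("GTF export and import agree on coordinates", {
  skip_if_not_installed("rtracklayer")
  cfg <- sim_config(seed = 41)
  m <- gen_gene_models(cfg, n_genes = 10)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models_gtf(m, gtf)
  m2 <- read_gene_models_gtf(gtf)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
  expect_equal(m2$strand, m$strand)
  expect_equal(m2$gene_id, m$gene_id)
})
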