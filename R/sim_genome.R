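#' Strand-aware transcription start site of each transcript
#'
#' Transcripts are stored 0-based half-open (`start` < `end`). On the plus
#' strand the TSS is `start`; on the minus strand it is `end - 1`.
#'
#' @param models A `gene_models` data frame (see [gen_gene_models()]).
#' @return Integer vector of TSS positions.
#' @export
tx_tss <- function(models) {
  ifelse(models$strand == "+", models$start, models$end - 1L)
}

#' Strand-aware transcription end site of each transcript
#' @inheritParams tx_tss
#' @return Integer vector of TES positions.
#' @export
tx_tes <- function(models) {
  ifelse(models$strand == "+", models$end - 1L, models$start)
}

#' Simulate a gene annotation with constructed edge cases
#'
#' Genes are laid down sequentially along the configured chromosomes with
#' random lengths and gaps, alternating strands, so that gene bodies never
#' nest or overlap. When `edge_cases = TRUE` the annotation deterministically
#' contains the situations that exercise dominant-TSS tie-breaking:
#' multi-TSS genes whose proximal windows will receive tied counts (both
#' strands), transcripts sharing a start position with different lengths
#' (both strands), and genes within 5 kb of a chromosome end.
#'
#' @param cfg A [sim_config()]; supplies the seed and chromosome sizes.
#' @param n_genes Number of genes to place (default 200).
#' @param edge_cases Insert the constructed edge-case genes?
#' @return A `gene_models` data frame with columns `gene_id`, `tx_id`,
#'   `chrom`, `strand`, `start`, `end`, `case` (coordinates 0-based
#'   half-open).
#' @export
gen_gene_models <- function(cfg, n_genes = 200L, edge_cases = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  local_stream(cfg$seed, "gene_models")
  cs <- cfg$chrom_sizes
  min_len <- 1000L
  max_len <- 4000L
  if (any(cs < max_len + 2000L))
    stop("gene longer than chromosome: chromosome(s) too short for ",
         "requested gene lengths", call. = FALSE)

  # special-case assignment: gene index -> (case, forced strand)
  special <- list()
  if (edge_cases && n_genes >= 6L) {
    special <- list(`3` = c("tie", "+"), `4` = c("tie", "-"),
                    `5` = c("shared_start", "+"),
                    `6` = c("shared_start", "-"))
  }

  rows <- list()
  chrom_i <- 1L
  cursor <- 1000L  # first gene on each chromosome sits near the start edge
  last_on_chrom <- integer(length(cs))
  for (i in seq_len(n_genes)) {
    len <- sample(min_len:max_len, 1L)
    repeat {
      if (chrom_i > length(cs))
        stop("chromosomes exhausted: reduce n_genes or enlarge chrom_sizes",
             call. = FALSE)
      if (cursor + len <= cs[[chrom_i]] - 1000L) break
      chrom_i <- chrom_i + 1L
      cursor <- 1000L
    }
    sp <- special[[as.character(i)]]
    strand <- if (!is.null(sp)) sp[2] else sample(c("+", "-"), 1L)
    case <- if (!is.null(sp)) sp[1] else
      if (cursor == 1000L) "chrom_start_edge" else "plain"
    gid <- sprintf("SIMG%05d", i)
    start <- cursor
    end <- cursor + len
    tx <- switch(case,
      tie = {
        # two transcripts, TSSs 400 bp apart so proximal windows are disjoint
        if (strand == "+")
          data.frame(start = c(start, start + 400L), end = c(end, end))
        else
          data.frame(start = c(start, start), end = c(end, end - 400L))
      },
      shared_start = {
        # equal TSS, different transcript lengths
        half <- len %/% 2L
        if (strand == "+")
          data.frame(start = c(start, start), end = c(end, start + half))
        else
          data.frame(start = c(start, end - half), end = c(end, end))
      },
      {
        if (stats::runif(1) < 0.3 && len > 900L) {
          shift <- sample(300:600, 1L)  # second TSS downstream of the first
          if (strand == "+")
            data.frame(start = c(start, start + shift), end = c(end, end))
          else
            data.frame(start = c(start, start), end = c(end, end - shift))
        } else data.frame(start = start, end = end)
      })
    rows[[i]] <- data.frame(
      gene_id = gid,
      tx_id = sprintf("%s.t%d", gid, seq_len(nrow(tx))),
      chrom = names(cs)[chrom_i],
      strand = strand,
      start = as.integer(tx$start),
      end = as.integer(tx$end),
      case = case,
      stringsAsFactors = FALSE)
    last_on_chrom[chrom_i] <- i
    cursor <- end + sample(6000:12000, 1L)
  }
  models <- do.call(rbind, rows)

  if (edge_cases) {
    # shift the last gene of each populated chromosome to within 1 kb of the
    # chromosome end (gaps only widen, so bodies stay non-overlapping)
    for (ci in which(last_on_chrom > 0L)) {
      gid <- sprintf("SIMG%05d", last_on_chrom[ci])
      sel <- models$gene_id == gid
      if (models$case[sel][1] %in% c("tie", "shared_start")) next
      shift <- as.integer(cs[[ci]] - 1000L - max(models$end[sel]))
      if (shift > 0L) {
        models$start[sel] <- models$start[sel] + shift
        models$end[sel] <- models$end[sel] + shift
        models$case[sel] <- "chrom_end_edge"
      }
    }
  }
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Simulate a strand-specific nascent 3'-end track over gene models
#'
#' Reads land only within gene bodies, on the gene's strand, with a
#' promoter-proximal component concentrated in the first 150 nt downstream
#' of each TSS (a common feature of nascent run-on signal; the split between
#' promoter and body reads is a modelling choice). Genes tagged `tie` or
#' `shared_start` receive deterministic counts — exactly `tie_count` reads at
#' each transcript TSS plus a fixed body pulse — so dominant-TSS tie-breaking
#' is exercised reproducibly.
#'
#' @param models A `gene_models` data frame.
#' @param rate Expected reads per kb of gene body (>= 0).
#' @param seed Integer seed.
#' @param promoter_fraction Fraction of a gene's reads placed in the
#'   TSS-proximal windows of its transcripts.
#' @param tie_count Deterministic proximal count given to each transcript of
#'   a `tie`/`shared_start` gene.
#' @param chrom_sizes Optional named vector recorded on the track.
#' @return A [threeprime_track()].
#' @export
gen_threeprime_track <- function(models, rate = 100, seed = 1L,
                                 promoter_fraction = 0.3, tie_count = 25L,
                                 chrom_sizes = NULL) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  local_stream(seed, "threeprime_track")
  out <- list()
  for (gid in unique(models$gene_id)) {
    g <- models[models$gene_id == gid, , drop = FALSE]
    strand <- g$strand[1]
    chrom <- g$chrom[1]
    span <- c(min(g$start), max(g$end))
    len <- span[2] - span[1]
    tss <- tx_tss(g)
    if (g$case[1] %in% c("tie", "shared_start")) {
      pos <- rep(unique(tss), each = tie_count)
      body_pos <- if (strand == "+") span[2] - 100L else span[1] + 100L
      pos <- c(pos, rep(body_pos, 5L))
      cnt <- rep(1L, length(pos))
    } else {
      n <- stats::rpois(1L, rate * len / 1000)
      if (n == 0L) next
      n_prom <- stats::rbinom(1L, n, promoter_fraction)
      prom_pos <- integer(0)
      if (n_prom > 0L) {
        which_tx <- sample.int(nrow(g), n_prom, replace = TRUE)
        off <- sample.int(151L, n_prom, replace = TRUE) - 1L
        prom_pos <- if (strand == "+") tss[which_tx] + off else
          tss[which_tx] - off
      }
      body_pos <- span[1] + sample.int(len, n - n_prom, replace = TRUE) - 1L
      pos <- pmin(pmax(c(prom_pos, body_pos), span[1]), span[2] - 1L)
      cnt <- rep(1L, length(pos))
    }
    out[[gid]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                             strand = strand, count = cnt,
                             stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(),
               strand = character(), count = integer())
  threeprime_track(df, chrom_sizes = chrom_sizes)
}

#' Simulate ChIP-seq reads with expression-proportional gene-body enrichment
#'
#' Gene bodies receive specific reads at a density proportional to
#' `expression * binding_scale`; everywhere outside the gene bodies a
#' uniform non-specific background of `background_density` reads per kb is
#' laid down. Total depth scales with `depth`. Read 5' ends stay within the
#' region they were assigned to.
#'
#' @param models A `gene_models` data frame.
#' @param expression Named numeric vector (per gene) of specific reads per
#'   bp of gene body at `binding_scale = 1`, `depth = 1`.
#' @param background_density Background reads per kb (> 0).
#' @param binding_scale Multiplier on specific gene-body density (>= 0).
#' @param depth Global depth multiplier (> 0).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return A BED6-style data frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @export
gen_chip_reads <- function(models, expression, background_density,
                           binding_scale = 1, depth = 1, chrom_sizes,
                           read_length = 50L, seed = 1L) {
  if (background_density <= 0)
    stop("`background_density` must be > 0", call. = FALSE)
  if (binding_scale < 0) stop("`binding_scale` must be >= 0", call. = FALSE)
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  local_stream(seed, "chip_reads")

  genes <- gene_spans(models)
  reads <- list()
  # specific gene-body reads
  for (i in seq_len(nrow(genes))) {
    e <- expression[[genes$gene_id[i]]]
    if (is.null(e) || is.na(e)) e <- 0
    len <- genes$end[i] - genes$start[i]
    n <- stats::rpois(1L, e * binding_scale * len * depth)
    if (n == 0L) next
    start <- genes$start[i] +
      sample.int(max(len - read_length, 1L), n, replace = TRUE) - 1L
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = genes$chrom[i], start = start, end = start + read_length,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  # uniform background over the complement of gene bodies
  for (chrom in names(chrom_sizes)) {
    gsel <- genes[genes$chrom == chrom, , drop = FALSE]
    iv <- interval_complement(gsel$start, gsel$end, chrom_sizes[[chrom]])
    iv <- iv[iv$end - iv$start > read_length, , drop = FALSE]
    if (!nrow(iv)) next
    widths <- iv$end - iv$start - read_length
    n <- stats::rpois(1L, background_density / 1000 * sum(widths) * depth)
    if (n == 0L) next
    which_iv <- sample.int(nrow(iv), n, replace = TRUE, prob = widths)
    start <- iv$start[which_iv] +
      floor(stats::runif(n) * widths[which_iv])
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + read_length),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  df <- if (length(reads)) do.call(rbind, reads) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             name = sprintf("read%07d", seq_len(nrow(df))),
             score = 0L, strand = df$strand, stringsAsFactors = FALSE)
}

# One row per gene: the union span of its transcripts.
gene_spans <- function(models) {
  sp <- do.call(rbind, lapply(split(seq_len(nrow(models)), models$gene_id),
    function(ix) {
      data.frame(gene_id = models$gene_id[ix[1]],
                 chrom = models$chrom[ix[1]],
                 strand = models$strand[ix[1]],
                 start = min(models$start[ix]),
                 end = max(models$end[ix]),
                 stringsAsFactors = FALSE)
    }))
  rownames(sp) <- NULL
  sp[order(match(sp$gene_id, unique(models$gene_id))), , drop = FALSE]
}

# Complement of [start, end) intervals within [0, size); plain data frame.
interval_complement <- function(start, end, size) {
  if (!length(start))
    return(data.frame(start = 0L, end = as.integer(size)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  gaps_start <- c(0L, end)
  gaps_end <- c(start, as.integer(size))
  keep <- gaps_end > gaps_start
  data.frame(start = as.integer(gaps_start[keep]),
             end = as.integer(gaps_end[keep]))
}
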