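#' Extended gene regions (gene body plus flanking pads)
#'
#' Each gene's span is padded `pad` bp upstream of the TSS and `pad` bp
#' downstream of the TES (equivalently, the span is extended by `pad` on
#' both sides, irrespective of strand), clamped to chromosome bounds, and
#' the padded intervals merged across genes. The complement of this set
#' defines the intergenic background used for calibration.
#'
#' @param models A `gene_models` data frame.
#' @param pad Pad in bp on each side (default 5000).
#' @param chrom_sizes Named vector of chromosome lengths covering every
#'   chromosome in `models`.
#' @return A sorted, reduced [GenomicRanges::GRanges] with seqlengths set.
#' @export
build_extended_regions <- function(models, pad = 5000L, chrom_sizes) {
  missing_chr <- setdiff(unique(models$chrom), names(chrom_sizes))
  if (length(missing_chr))
    stop("chromosome(s) missing from chrom_sizes: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  sp <- gene_spans(models)
  start <- pmax(sp$start - pad, 0L)
  end <- pmin(sp$end + pad, as.integer(chrom_sizes[sp$chrom]))
  gr <- GenomicRanges::GRanges(
    seqnames = sp$chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    seqlengths = chrom_sizes_vec(chrom_sizes))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Intergenic complement of the extended gene regions
#'
#' Exact per-chromosome set complement (0-based half-open semantics at the
#' file level; represented as 1-based closed `GRanges` internally).
#'
#' @param ext Output of [build_extended_regions()] (seqlengths required).
#' @param chrom_sizes Optional named lengths overriding `seqlengths(ext)`.
#' @param blacklist Optional `GRanges` of artefact regions to exclude from
#'   the intergenic set (they are neither genic nor usable background).
#' @return A `GRanges` of intergenic intervals.
#' @export
intergenic_complement <- function(ext, chrom_sizes = NULL,
                                  blacklist = NULL) {
  if (!is.null(chrom_sizes))
    GenomeInfoDb::seqlengths(ext) <- chrom_sizes_vec(chrom_sizes)[
      GenomeInfoDb::seqlevels(ext)]
  if (any(is.na(GenomeInfoDb::seqlengths(ext))))
    stop("chromosome lengths required to take a complement", call. = FALSE)
  gp <- GenomicRanges::gaps(ext)
  # gaps() emits rows for the +/- strands of an unstranded input too
  gp <- gp[GenomicRanges::strand(gp) == "*"]
  if (!is.null(blacklist))
    gp <- GenomicRanges::setdiff(gp, blacklist, ignore.strand = TRUE)
  gp
}

chrom_sizes_vec <- function(chrom_sizes) {
  stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
}

# BED6 data frame -> GRanges (0-based half-open -> 1-based closed)
bed_to_granges <- function(reads, chrom_sizes = NULL) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand,
    seqlengths = if (is.null(chrom_sizes)) NULL else
      chrom_sizes_vec(chrom_sizes))
}

#' Intergenic-background scaling factors
#'
#' Counts, for each sample, the reads whose 5' end lies in an intergenic
#' interval (the 5' end is the read start on the plus strand and the last
#' base on the minus strand), then sets
#' `factor_j = geometric_mean(C) / C_j`, so that multiplying each sample's
#' coverage by its factor equalises the non-specific background across
#' libraries while preserving genuine global binding differences.
#'
#' @param reads A list of BED6 data frames, one per sample (named).
#' @param intergenic A `GRanges` of intergenic intervals.
#' @return Named numeric vector of scaling factors; attribute
#'   `intergenic_count` carries the raw counts.
#' @export
intergenic_scaling_factors <- function(reads, intergenic) {
  if (inherits(reads, "data.frame")) reads <- list(reads)
  counts <- vapply(reads, function(df) {
    p5 <- ifelse(df$strand == "-", df$end - 1L, df$start)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(p5 + 1L, width = 1L))
    sum(IRanges::overlapsAny(gr, intergenic))
  }, numeric(1))
  if (any(counts == 0))
    stop("sample(s) with zero intergenic reads: ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  f <- exp(mean(log(counts))) / counts
  if (!is.null(names(reads))) names(f) <- names(reads)
  attr(f, "intergenic_count") <- counts
  f
}

#' Binned fragment coverage
#'
#' Single-end reads are extended to `extend` bp in their orientation (the
#' paired mode takes the given intervals as fragments); the value of each
#' fixed-width bin is the number of extended fragments overlapping it.
#'
#' @param reads BED6 data frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin Bin width in bp (default 20).
#' @param extend Fragment extension for single-end reads (default 200);
#'   ignored when `paired = TRUE`.
#' @param paired Treat intervals as complete fragments?
#' @return A `GRanges` of tiling bins with a numeric `score` column.
#' @export
binned_coverage <- function(reads, chrom_sizes, bin = 20L, extend = 200L,
                            paired = FALSE) {
  sizes <- chrom_sizes_vec(chrom_sizes)
  if (paired) {
    fs <- reads$start
    fe <- reads$end
  } else {
    fs <- ifelse(reads$strand == "-", reads$end - extend, reads$start)
    fe <- ifelse(reads$strand == "-", reads$end, reads$start + extend)
  }
  fs <- pmax(fs, 0L)
  fe <- pmin(fe, sizes[as.character(reads$chrom)])
  frags <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(fs + 1L, fe))
  bins <- GenomicRanges::tileGenome(sizes, tilewidth = bin,
                                    cut.last.tile.in.chrom = TRUE)
  bins$score <- GenomicRanges::countOverlaps(bins, frags)
  bins
}

#' Apply a calibration factor to a coverage track
#'
#' @param cov A `GRanges` with a `score` column.
#' @param factor Positive scaling factor.
#' @return The track with `score` multiplied elementwise.
#' @export
apply_scaling <- function(cov, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("`factor` must be a single positive number", call. = FALSE)
  cov$score <- cov$score * factor
  cov
}

#' Difference of two calibrated coverage tracks
#'
#' Simple bin-wise subtraction (`a - b`) over a shared bin grid, for
#' difference-style browser tracks.
#'
#' @param a,b `GRanges` coverage tracks on identical bins.
#' @return A `GRanges` with the difference in `score`.
#' @export
coverage_difference <- function(a, b) {
  if (length(a) != length(b) ||
      !all(GenomicRanges::start(a) == GenomicRanges::start(b)))
    stop("tracks must share the same bin grid", call. = FALSE)
  a$score <- a$score - b$score
  a
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count * 1e9 / (length * total)`.
#'
#' @param counts Per-gene read counts.
#' @param lengths Gene lengths in bp (> 0).
#' @param total Total mapped reads in the library (> 0).
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(counts, lengths, total) {
  if (any(lengths <= 0)) stop("lengths must be > 0", call. = FALSE)
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  counts * 1e9 / (lengths * total)
}

#' Expression classes from mean FPKM
#'
#' Genes with zero mean FPKM are `silent`. For expressed genes the 5th and
#' 95th quantiles (linear-interpolation definition) are computed, and genes
#' are `high` strictly above the 95th, `low` strictly below the 5th, and
#' `medium` otherwise.
#'
#' @param mean_fpkm Named numeric vector of mean FPKM per gene.
#' @param min_expressed Minimum number of expressed genes required for the
#'   quantiles to be meaningful (default 20).
#' @return Factor with levels silent/low/medium/high; attributes `q5`,
#'   `q95`.
#' @export
classify_expression <- function(mean_fpkm, min_expressed = 20L) {
  expressed <- mean_fpkm > 0
  if (sum(expressed) < min_expressed)
    stop("too few expressed genes (", sum(expressed), ") to compute ",
         "stable quantiles", call. = FALSE)
  q <- stats::quantile(mean_fpkm[expressed], c(0.05, 0.95), type = 7,
                       names = FALSE)
  cls <- rep("medium", length(mean_fpkm))
  cls[!expressed] <- "silent"
  cls[expressed & mean_fpkm > q[2]] <- "high"
  cls[expressed & mean_fpkm < q[1]] <- "low"
  out <- factor(cls, levels = c("silent", "low", "medium", "high"))
  names(out) <- names(mean_fpkm)
  attr(out, "q5") <- q[1]
  attr(out, "q95") <- q[2]
  out
}

#' Mean calibrated coverage over gene bodies
#'
#' Averages the `score` of coverage bins lying fully within gene bodies,
#' optionally shrinking each body by `margin` bp on both sides so that
#' background fragments extending across the body boundary do not dilute
#' the specific signal.
#'
#' @param cov Binned coverage `GRanges`.
#' @param models A `gene_models` data frame.
#' @param margin Bp trimmed from each body end (default 200, the fragment
#'   extension).
#' @return Mean score over the selected bins.
#' @export
gene_body_mean_coverage <- function(cov, models, margin = 200L) {
  sp <- gene_spans(models)
  body <- GenomicRanges::GRanges(
    sp$chrom,
    IRanges::IRanges(pmin(sp$start + margin + 1L, sp$end),
                     pmax(sp$end - margin, sp$start + 1L)))
  sel <- IRanges::overlapsAny(cov, body, type = "within")
  mean(cov$score[sel])
}

#' Metagene matrix in scale-regions mode
#'
#' Each gene body is resampled to `n_body_bins` columns by mean pooling of
#' the coverage bins it spans; `flank` bp on each side are appended at the
#' native bin width. Minus-strand genes are reversed so the TSS is always
#' the leftmost body column. Bodies shorter than `n_body_bins` coverage
#' bins fall back to linear interpolation (reported via a message).
#'
#' @param cov Binned coverage `GRanges` from [binned_coverage()] (scaled or
#'   raw).
#' @param models A `gene_models` data frame.
#' @param flank Flank in bp on each side (default 2000).
#' @param n_body_bins Number of body columns (default 100).
#' @return List with `matrix` (genes x columns, NA outside chromosome
#'   bounds) and `profile` (column means over genes, NAs removed).
#' @export
metagene_matrix <- function(cov, models, flank = 2000L,
                            n_body_bins = 100L) {
  bw <- GenomicRanges::width(cov)[1]
  n_flank <- as.integer(flank %/% bw)
  chroms <- as.character(GenomicRanges::seqnames(cov))
  score_by_chrom <- split(cov$score, chroms)
  # bins are consecutive within a chromosome; index = floor(pos / bw) + 1
  sp <- gene_spans(models)
  n_col <- n_body_bins + 2L * n_flank
  mat <- matrix(NA_real_, nrow(sp), n_col,
                dimnames = list(sp$gene_id, NULL))
  n_interp <- 0L
  for (i in seq_len(nrow(sp))) {
    sc <- score_by_chrom[[sp$chrom[i]]]
    b0 <- sp$start[i] %/% bw
    b1 <- (sp$end[i] - 1L) %/% bw
    body <- sc[(b0 + 1L):(b1 + 1L)]
    if (length(body) >= n_body_bins) {
      grp <- floor((seq_along(body) - 1L) * n_body_bins / length(body))
      pooled <- as.numeric(tapply(body, grp, mean))
    } else {
      n_interp <- n_interp + 1L
      pooled <- stats::approx(seq_along(body), body,
                              xout = seq(1, length(body),
                                         length.out = n_body_bins))$y
    }
    up_idx <- if (n_flank > 0L) seq(b0 - n_flank, b0 - 1L) else integer(0)
    dn_idx <- if (n_flank > 0L) seq(b1 + 1L, b1 + n_flank) else integer(0)
    grab <- function(idx) {
      v <- rep(NA_real_, length(idx))
      ok <- idx >= 0L & idx < length(sc)
      v[ok] <- sc[idx[ok] + 1L]
      v
    }
    row <- c(grab(up_idx), pooled, grab(dn_idx))
    if (sp$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  if (n_interp > 0L)
    message(n_interp, " gene(s) shorter than n_body_bins coverage bins; ",
            "interpolated linearly")
  list(matrix = mat, profile = colMeans(mat, na.rm = TRUE))
}
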