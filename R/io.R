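#' Write / read a spike-in count matrix as TSV
#'
#' The table has columns `gene_id`, `is_spikein`, then one integer column
#' per sample; sample conditions go in a companion sample sheet
#' (`sample`, `condition`).
#'
#' @param m A [spikein_counts()] object.
#' @param counts_path,samples_path Output file paths.
#' @return Invisibly, the paths written.
#' @export
write_counts_tsv <- function(m, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(m$counts),
                   is_spikein = m$is_spikein,
                   m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sample = colnames(m$counts),
                   condition = as.character(m$condition))
  utils::write.table(ss, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ss <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, ss$sample, drop = FALSE])
  rownames(counts) <- df$gene_id
  spikein_counts(counts, df$is_spikein, ss$condition)
}

#' Write / read a strand pair of bedGraph files for a 3'-end track
#'
#' Writes `<prefix>_plus.bedGraph` and `<prefix>_minus.bedGraph` with
#' single-base intervals (0-based half-open).
#'
#' @param track A [threeprime_track()].
#' @param prefix Path prefix for the two files.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(track, prefix) {
  paths <- paste0(prefix, c("_plus.bedGraph", "_minus.bedGraph"))
  for (k in 1:2) {
    st <- c("+", "-")[k]
    sub <- track[track$strand == st, , drop = FALSE]
    bg <- data.frame(chrom = sub$chrom, start = sub$pos,
                     end = sub$pos + 1L, count = sub$count)
    utils::write.table(bg, paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_bedgraph_pair
#' @param plus_path,minus_path Paths of the two bedGraph files.
#' @param chrom_sizes Optional named lengths recorded on the track.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes = NULL) {
  read_one <- function(path, strand) {
    if (file.size(path) == 0)
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), count = integer()))
    bg <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end",
                                          "count"))
    # expand multi-base intervals to per-base rows
    w <- bg$end - bg$start
    idx <- rep.int(seq_len(nrow(bg)), w)
    data.frame(chrom = bg$chrom[idx],
               pos = bg$start[idx] +
                 (sequence(w) - 1L),
               strand = strand, count = bg$count[idx],
               stringsAsFactors = FALSE)
  }
  threeprime_track(rbind(read_one(plus_path, "+"),
                         read_one(minus_path, "-")),
                   chrom_sizes = chrom_sizes)
}

#' Write / read BED6 intervals
#' @param reads BED6 data frame.
#' @param path File path.
#' @export
write_bed6 <- function(reads, path) {
  utils::write.table(reads[, c("chrom", "start", "end", "name", "score",
                               "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"))
}

#' Write / read a chrom.sizes file
#' @param chrom_sizes Named numeric vector.
#' @param path File path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes),
                                as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Write / read gene models
#'
#' The native exchange format is a transcript-level TSV (0-based half-open
#' coordinates). `write_gene_models_gtf()` additionally emits a minimal GTF
#' (1-based closed, `transcript` features); reading GTF requires the
#' rtracklayer package.
#'
#' @param models A `gene_models` data frame.
#' @param path File path.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(as.data.frame(models), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' @rdname write_gene_models
#' @export
write_gene_models_gtf <- function(models, path) {
  attr_col <- sprintf('gene_id "%s"; transcript_id "%s";',
                      models$gene_id, models$tx_id)
  lines <- paste(models$chrom, "hypertx", "transcript",
                 models$start + 1L, models$end, ".", models$strand, ".",
                 attr_col, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  df <- data.frame(gene_id = gr$gene_id,
                   tx_id = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   case = "plain",
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write / read a force-scan TSV
#' @param scan A `force_scan` data frame.
#' @param path File path.
#' @export
write_force_scan_tsv <- function(scan, path) {
  utils::write.table(scan[, c("tether_id", "branch", "force_pN",
                              "time_s", "height_nm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_scan_tsv
#' @export
read_force_scan_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("force_scan", "data.frame")
  out
}

#' Write / read trajectory frames as multi-model PDB
#'
#' Frames are written as MODEL/ENDMDL blocks of ATOM records; reading uses
#' bio3d's multi-model PDB parser. The donor / hydrogen / acceptor pair
#' annotation travels in a companion TSV ([write_pairs_tsv()]).
#'
#' @param frames A [frame_set()].
#' @param path File path.
#' @export
write_frames_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(frames$coords)[3]
  at <- frames$atoms
  resno <- as.integer(factor(at$residue, levels = unique(at$residue)))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frames$coords[, , f, drop = FALSE]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      at$atom_id, substr(at$name, 1, 4), "LIG", resno,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_frames_pdb
#' @param pairs_path Path of the pair-annotation TSV.
#' @export
read_frames_pdb <- function(path, pairs_path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # frames x (3 * n_atoms)
  n_atoms <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(n_atoms, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  pairs <- read_pairs_tsv(pairs_path)
  atoms <- data.frame(atom_id = seq_len(n_atoms),
                      name = pdb$atom$elety[seq_len(n_atoms)],
                      residue = paste0("PAIR",
                                       pdb$atom$resno[seq_len(n_atoms)]),
                      role = rep(c("donor", "hydrogen", "acceptor"),
                                 length.out = n_atoms),
                      stringsAsFactors = FALSE)
  frame_set(coords, atoms, pairs)
}

#' @rdname write_frames_pdb
#' @export
write_pairs_tsv <- function(frames, pairs_path) {
  utils::write.table(frames$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pairs_path)
}

#' @rdname write_frames_pdb
#' @export
read_pairs_tsv <- function(pairs_path) {
  # atom labels may contain primes (O5', O3'); disable quote handling
  utils::read.table(pairs_path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
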