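#' Strand-specific per-base 3'-end count track
#'
#' Stores counts of nascent-RNA 3' ends at single-base resolution, one row
#' per (chromosome, strand, position) with a positive count. Positions are
#' 0-based; plus- and minus-strand signal is kept separate, matching the
#' semantics of a strand-resolved bedGraph pair.
#'
#' @param df Data frame with columns `chrom`, `pos`, `strand`, `count`.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   present, lookups on chromosomes absent from it raise an error and
#'   window sums are clamped to chromosome bounds.
#' @return An object of class `threeprime_track` (a data frame).
#' @export
threeprime_track <- function(df = data.frame(chrom = character(),
                                             pos = integer(),
                                             strand = character(),
                                             count = integer()),
                             chrom_sizes = NULL) {
  need <- c("chrom", "pos", "strand", "count")
  if (!all(need %in% names(df)))
    stop("track needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("track counts must be non-negative")
  if (!all(df$strand %in% c("+", "-")))
    stop("track strand must be '+' or '-'")
  df <- df[df$count > 0, need, drop = FALSE]
  if (nrow(df)) {
    # collapse duplicate positions
    key <- paste(df$chrom, df$strand, df$pos, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(df$count, key)
      parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
      df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 3]),
                       strand = parts[, 2], count = as.integer(agg[, 1]),
                       stringsAsFactors = FALSE)
    }
    df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, chrom_sizes = chrom_sizes,
            class = c("threeprime_track", "data.frame"))
}

#' Sum several 3'-end tracks into a composite track
#'
#' Activity calling is done on signal combined across samples; this adds the
#' per-position counts of the supplied tracks.
#'
#' @param ... `threeprime_track` objects (or a single list of them).
#' @return A `threeprime_track`.
#' @export
combine_tracks <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1L && is.list(tracks[[1]]) &&
      !inherits(tracks[[1]], "threeprime_track"))
    tracks <- tracks[[1]]
  stopifnot(all(vapply(tracks, inherits, TRUE, "threeprime_track")))
  cs <- attr(tracks[[1]], "chrom_sizes")
  threeprime_track(do.call(rbind, lapply(tracks, as.data.frame)),
                   chrom_sizes = cs)
}

#' Swap the strands of a 3'-end track
#'
#' In paired-end nascent run-on protocols, read 1 reveals the RNA 3' end
#' but maps to the opposite strand; published combined tracks are
#' strand-swapped already. Use this on raw R1-derived tracks before
#' analysis.
#'
#' @param track A [threeprime_track()].
#' @return The track with `+` and `-` exchanged.
#' @export
swap_strands <- function(track) {
  cs <- attr(track, "chrom_sizes")
  df <- as.data.frame(track)
  df$strand <- ifelse(df$strand == "+", "-", "+")
  threeprime_track(df, chrom_sizes = cs)
}

# Sum of counts on one strand of one chromosome over the closed interval
# [from, to] (0-based, endpoint-inclusive).
track_window_sum <- function(track, chrom, strand, from, to) {
  cs <- attr(track, "chrom_sizes")
  if (!is.null(cs)) {
    if (!chrom %in% names(cs))
      stop("chromosome '", chrom, "' not present in track", call. = FALSE)
    from <- max(from, 0)
    to <- min(to, cs[[chrom]] - 1)
  } else {
    from <- max(from, 0)
  }
  if (to < from) return(0L)
  sel <- track$chrom == chrom & track$strand == strand &
    track$pos >= from & track$pos <= to
  sum(track$count[sel])
}
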