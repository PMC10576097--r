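#' TSS-proximal 3'-end counts per transcript
#'
#' Sums same-strand 3'-end counts in the strand-aware proximal window of
#' each transcript: `[TSS, TSS + window]` on the plus strand,
#' `[TSS - window, TSS]` on the minus strand, both endpoints inclusive in
#' the internal 0-based frame. Windows extending past chromosome ends are
#' clamped when the track carries chromosome sizes; a transcript on a
#' chromosome missing from those sizes is an error.
#'
#' @param models A `gene_models` data frame.
#' @param track A [threeprime_track()] (use [combine_tracks()] first to sum
#'   signal across samples).
#' @param window Window length in nt downstream of the TSS (default 150).
#' @return Integer vector of proximal counts, one per transcript row.
#' @export
proximal_window_count <- function(models, track, window = 150L) {
  tss <- tx_tss(models)
  vapply(seq_len(nrow(models)), function(i) {
    if (models$strand[i] == "+")
      track_window_sum(track, models$chrom[i], "+", tss[i], tss[i] + window)
    else
      track_window_sum(track, models$chrom[i], "-", tss[i] - window, tss[i])
  }, numeric(1))
}

#' Activity call from proximal counts
#'
#' A TSS with 9 or fewer proximal counts is inactive; 10 or more is active.
#'
#' @param counts Numeric vector of proximal-window counts.
#' @param min_count Minimum count deemed active (default 10).
#' @return Logical vector.
#' @export
call_active <- function(counts, min_count = 10L) {
  counts >= min_count
}

#' Collapse a gene's active transcripts to one dominant TSS
#'
#' The transcript with the highest proximal count wins. Ties on count go to
#' the TSS furthest upstream in a strand-aware sense (smallest coordinate on
#' the plus strand, largest on the minus strand). Transcripts sharing that
#' dominant start position are deduplicated by (1) the longest annotated
#' transcript, then (2) the lowest numerical portion of the identifier. A
#' gene with no active transcript yields no dominant TSS.
#'
#' @param gene_tx Data frame of one gene's transcripts (gene_models columns)
#'   with a `proximal_count` column.
#' @param min_count Activity threshold passed to [call_active()].
#' @return One-row data frame (`gene_id`, `tx_id`, `chrom`, `strand`,
#'   `dominant_tss`, `tes`, `proximal_count`) or `NULL` when inactive.
#' @export
collapse_dominant <- function(gene_tx, min_count = 10L) {
  act <- gene_tx[call_active(gene_tx$proximal_count, min_count), ,
                 drop = FALSE]
  if (!nrow(act)) return(NULL)
  tss <- tx_tss(act)
  top <- act$proximal_count == max(act$proximal_count)
  dom_tss <- if (act$strand[1] == "+") min(tss[top]) else max(tss[top])
  cand <- act[top & tss == dom_tss, , drop = FALSE]
  len <- cand$end - cand$start
  cand <- cand[len == max(len), , drop = FALSE]
  if (nrow(cand) > 1L) {
    num <- id_numeric_portion(cand$tx_id)
    cand <- cand[order(num), , drop = FALSE]
  }
  chosen <- cand[1L, , drop = FALSE]
  data.frame(gene_id = chosen$gene_id, tx_id = chosen$tx_id,
             chrom = chosen$chrom, strand = chosen$strand,
             dominant_tss = dom_tss, tes = tx_tes(chosen),
             proximal_count = chosen$proximal_count,
             stringsAsFactors = FALSE)
}

# Numerical portion of an identifier (digits concatenated), for the final
# deterministic tie-break.
id_numeric_portion <- function(ids) {
  as.numeric(gsub("[^0-9]", "", ids))
}

#' Full dominant-TSS refinement over an annotation
#'
#' Computes proximal counts on the composite track, applies the activity
#' threshold, and collapses each gene to its dominant TSS with the full
#' tie-break cascade. Distinct genes whose dominant TSSs land on the same
#' position are reported via a message and left unresolved (collapse is
#' within-gene only).
#'
#' @param models A `gene_models` data frame.
#' @param tracks A [threeprime_track()] or list of them (summed before
#'   calling).
#' @param min_count Activity threshold (default 10).
#' @param window Proximal window in nt (default 150).
#' @return Data frame of active genes with their dominant TSS (one row per
#'   gene), as described in [collapse_dominant()].
#' @export
protss_call <- function(models, tracks, min_count = 10L, window = 150L) {
  track <- if (inherits(tracks, "threeprime_track")) tracks else
    combine_tracks(tracks)
  models <- as.data.frame(models)
  models$proximal_count <- proximal_window_count(models, track, window)
  calls <- lapply(split(models, models$gene_id), collapse_dominant,
                  min_count = min_count)
  calls <- do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  if (is.null(calls))
    return(data.frame(gene_id = character(), tx_id = character(),
                      chrom = character(), strand = character(),
                      dominant_tss = integer(), tes = integer(),
                      proximal_count = numeric()))
  rownames(calls) <- NULL
  key <- paste(calls$chrom, calls$strand, calls$dominant_tss)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    message("dominant TSS position shared across distinct genes at: ",
            paste(dup, collapse = "; "), " (left unresolved)")
  }
  calls <- calls[order(calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Gene-body 3'-end counts for nascent differential expression
#'
#' For each active gene, sums same-strand 3'-end counts over the closed
#' interval from the dominant TSS to the TES of the dominant transcript
#' (strand-aware, both endpoints inclusive). Inactive genes are absent from
#' the input calls and therefore from the output.
#'
#' @param calls Output of [protss_call()].
#' @param track A [threeprime_track()] for one sample.
#' @return Data frame `gene_id`, `count`.
#' @export
gene_body_counts <- function(calls, track) {
  cnt <- vapply(seq_len(nrow(calls)), function(i) {
    lo <- min(calls$dominant_tss[i], calls$tes[i])
    hi <- max(calls$dominant_tss[i], calls$tes[i])
    track_window_sum(track, calls$chrom[i], calls$strand[i], lo, hi)
  }, numeric(1))
  data.frame(gene_id = calls$gene_id, count = cnt,
             stringsAsFactors = FALSE)
}
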