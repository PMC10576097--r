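# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration, sharing only the file-level conventions (0-based
# coordinates, inclusive windows) with the package — not its code paths.

# Step-up FDR adjustment, literal definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m / i * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# One-off hashed index of a track: key "chrom|strand|pos" -> count, so the
# per-position loops below stay feasible on multi-thousand-row tracks.
oracle_track_index <- function(track) {
  e <- new.env(hash = TRUE, size = nrow(track) * 2L)
  keys <- paste(track$chrom, track$strand, track$pos, sep = "|")
  for (i in seq_along(keys)) {
    prev <- if (exists(keys[i], e, inherits = FALSE))
      get(keys[i], e) else 0
    assign(keys[i], prev + track$count[i], e)
  }
  e
}

oracle_count_at <- function(idx, chrom, strand, pos) {
  key <- paste(chrom, strand, pos, sep = "|")
  if (exists(key, idx, inherits = FALSE)) get(key, idx) else 0
}

# Proximal window count by per-position loop (inclusive window).
oracle_proximal <- function(chrom, strand, tss, idx, window = 150) {
  rng <- if (strand == "+") tss:(tss + window) else (tss - window):tss
  total <- 0
  for (p in rng) total <- total + oracle_count_at(idx, chrom, strand, p)
  total
}

# Full dominant-TSS pipeline by explicit loops: activity at >= 10 counts,
# highest proximal count, ties to the strand-aware upstream TSS, shared
# starts to the longest transcript then the lowest numeric id portion.
oracle_protss <- function(models, track, window = 150, min_count = 10) {
  models <- as.data.frame(models)
  idx <- oracle_track_index(track)
  out <- list()
  for (gid in unique(models$gene_id)) {
    g <- models[models$gene_id == gid, , drop = FALSE]
    strand <- g$strand[1]
    tss <- if (strand == "+") g$start else g$end - 1
    cnt <- vapply(seq_len(nrow(g)), function(i)
      oracle_proximal(g$chrom[i], strand, tss[i], idx, window),
      numeric(1))
    keep <- cnt >= min_count
    if (!any(keep)) next
    g <- g[keep, , drop = FALSE]; tss <- tss[keep]; cnt <- cnt[keep]
    best <- which(cnt == max(cnt))
    dom_tss <- if (strand == "+") min(tss[best]) else max(tss[best])
    cand <- which(cnt == max(cnt) & tss == dom_tss)
    lens <- g$end[cand] - g$start[cand]
    cand <- cand[lens == max(lens)]
    if (length(cand) > 1) {
      nums <- as.numeric(gsub("[^0-9]", "", g$tx_id[cand]))
      cand <- cand[which.min(nums)]
    }
    i <- cand[1]
    tes <- if (strand == "+") g$end[i] - 1 else g$start[i]
    body <- 0
    for (p in min(dom_tss, tes):max(dom_tss, tes))
      body <- body + oracle_count_at(idx, g$chrom[i], strand, p)
    out[[gid]] <- data.frame(gene_id = gid, dominant_tss = dom_tss,
                             tes = tes, proximal_count = cnt[i],
                             body_count = body,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

# Per-base complement of [start, end) intervals within [0, size).
oracle_complement_mask <- function(start, end, size) {
  covered <- logical(size)
  for (i in seq_along(start))
    if (end[i] > start[i])
      covered[(start[i] + 1):end[i]] <- TRUE  # 1-based mask of 0-based bp
  !covered
}

# Hydrogen-bond occupancy by per-frame arithmetic on raw coordinates.
oracle_occupancy <- function(frames, max_dist = 3.5, min_ang = 135) {
  np <- nrow(frames$pairs)
  nf <- dim(frames$coords)[3]
  occ <- numeric(np)
  for (j in seq_len(np)) {
    di <- frames$pairs$donor_idx[j]
    hi <- frames$pairs$hydrogen_idx[j]
    ai <- frames$pairs$acceptor_idx[j]
    hits <- 0
    for (f in seq_len(nf)) {
      d <- frames$coords[di, , f]
      h <- frames$coords[hi, , f]
      a <- frames$coords[ai, , f]
      dist <- sqrt(sum((a - d)^2))
      hd <- d - h; ha <- a - h
      ang <- acos(max(-1, min(1, sum(hd * ha) /
                                sqrt(sum(hd^2) * sum(ha^2))))) * 180 / pi
      if (dist <= max_dist && ang >= min_ang) hits <- hits + 1
    }
    occ[j] <- 100 * hits / nf
  }
  occ
}

# Marko-Siggia closed form shared by simulation checks.
oracle_wlc_force <- function(frac, Lp = 50, kT = 4.114) {
  kT / Lp * (1 / (4 * (1 - frac)^2) - 0.25 + frac)
}

# Chi-squared upper tail via the regularised upper incomplete gamma,
# computed by numerical integration of the gamma density.
oracle_chisq_sf <- function(x, df) {
  stats::integrate(function(t) t^(df / 2 - 1) * exp(-t / 2),
                   lower = x, upper = Inf, rel.tol = 1e-12)$value /
    (2^(df / 2) * gamma(df / 2))
}
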