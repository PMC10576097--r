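#' Dwell summary: mean and standard deviation of bead height
#'
#' Each force step of a scan holds the tether for a fixed window (20 s in
#' the emulated protocol); the dwell is summarised by the arithmetic mean
#' and the sample standard deviation (n - 1 denominator) of the recorded
#' heights.
#'
#' @param heights Numeric vector of bead heights (nm); length >= 2.
#' @return Named vector `c(mean =, sd =)`.
#' @export
summarize_dwell <- function(heights) {
  if (length(heights) < 2L)
    stop("need at least 2 samples in the dwell window", call. = FALSE)
  c(mean = mean(heights), sd = stats::sd(heights))
}

#' Per-force dwell summaries of a force scan
#'
#' @param scan A `force_scan` data frame (columns `tether_id`, `branch`,
#'   `force_pN`, `time_s`, `height_nm`).
#' @return Data frame `branch`, `force_pN`, `mean_nm`, `sd_nm`, ordered as
#'   scanned.
#' @export
summarize_scan <- function(scan) {
  key <- paste(scan$branch, format(scan$force_pN, digits = 12))
  idx <- split(seq_len(nrow(scan)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(idx, function(ix) {
    s <- summarize_dwell(scan$height_nm[ix])
    data.frame(branch = scan$branch[ix[1]], force_pN = scan$force_pN[ix[1]],
               mean_nm = s[["mean"]], sd_nm = s[["sd"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Extract one branch as force -> mean height, forces as scanned.
branch_means <- function(scan, branch) {
  sm <- if (all(c("mean_nm", "force_pN") %in% names(scan)) &&
            !"height_nm" %in% names(scan)) scan else summarize_scan(scan)
  sm <- sm[sm$branch == branch, , drop = FALSE]
  if (!nrow(sm)) stop("scan has no '", branch, "' branch", call. = FALSE)
  sm
}

#' Compaction ratio of a protein-bound tether against naked DNA
#'
#' Per force, the mean bead height of the protein-incubated tether during
#' the force-increase scan divided by the mean naked-DNA height at the
#' corresponding force. Force grids must match exactly; no interpolation is
#' performed.
#'
#' @param protein_scan `force_scan` (raw or summarised) for the
#'   protein-incubated tether.
#' @param naked_scan `force_scan` for the naked-DNA reference.
#' @param branch Branch of the protein scan used (default `"increase"`,
#'   matching the definition; `"decrease"` offered for exploration).
#' @return Data frame `force_pN`, `ratio`.
#' @export
compaction_ratio <- function(protein_scan, naked_scan,
                             branch = c("increase", "decrease")) {
  branch <- match.arg(branch)
  p <- branch_means(protein_scan, branch)
  nk <- branch_means(naked_scan, branch)
  if (nrow(p) != nrow(nk) || any(p$force_pN != nk$force_pN))
    stop("force grids of the two scans do not match", call. = FALSE)
  if (any(nk$mean_nm == 0))
    stop("naked-DNA height is zero at some force", call. = FALSE)
  data.frame(force_pN = p$force_pN, ratio = p$mean_nm / nk$mean_nm)
}

#' Hysteresis between force-increase and force-decrease branches
#'
#' Per force, extension during the force-increase scan minus extension
#' during the force-decrease scan of the same tether. A persistent
#' protein-compacted state formed at low force shows up as a negative
#' hysteresis that survives into the increase branch.
#'
#' @param scan A `force_scan` containing both branches on a common force
#'   grid.
#' @return Data frame `force_pN`, `hysteresis_nm`.
#' @export
hysteresis <- function(scan) {
  inc <- branch_means(scan, "increase")
  dec <- branch_means(scan, "decrease")
  dec <- dec[match(inc$force_pN, dec$force_pN), , drop = FALSE]
  if (any(is.na(dec$mean_nm)))
    stop("branches do not share the force grid", call. = FALSE)
  data.frame(force_pN = inc$force_pN,
             hysteresis_nm = inc$mean_nm - dec$mean_nm)
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Computes the U statistic of group A (number of (a, b) pairs with a > b,
#' ties counted 1/2). The two-tailed p-value is exact — by enumeration of
#' all group assignments of the pooled data — whenever
#' `min(n_a, n_b) <= 8` and `n_a + n_b <= 20`; otherwise a normal
#' approximation with tie correction is used. The two-tailed value doubles
#' the smaller one-tailed tail probability, capped at 1.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) enumeration; `NULL`
#'   applies the size rule.
#' @return List with `U` (statistic of `a`), `p` (two-tailed), `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) sum(r[idx_a]) - na * (na + 1) / 2
  u <- u_of(seq_len(na))
  do_exact <- if (is.null(exact)) (min(na, nb) <= 8L && n <= 20L) else exact
  if (do_exact) {
    combos <- utils::combn(n, na)
    us <- apply(combos, 2L, u_of)
    p_lo <- mean(us <= u)
    p_hi <- mean(us >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = u, p = 1, method = "degenerate"))
    z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)  # continuity corrected
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method)
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic over an r x c contingency table against the
#' independence expectation, `df = (r - 1)(c - 1)`, upper-tail p-value.
#' Used e.g. to compare distributions of categorical outcomes (such as
#' neuronal firing subtypes) between cell lines.
#'
#' @param x Matrix of non-negative counts.
#' @return List `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(x) {
  x <- as.matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("zero marginal in the contingency table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  if (any(ht$expected <= 0))
    stop("all expected counts must be > 0", call. = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = chi_square_sf(unname(ht$statistic), unname(ht$parameter)),
       expected = ht$expected)
}

#' Chi-squared survival function (upper tail)
#'
#' @param x Non-negative quantile.
#' @param df Degrees of freedom.
#' @return Upper-tail probability P(X >= x).
#' @export
#' @examples
#' chi_square_sf(2, 2)  # exp(-1)
chi_square_sf <- function(x, df) {
  stats::pchisq(x, df, lower.tail = FALSE)
}
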