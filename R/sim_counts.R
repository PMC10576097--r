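#' Simulation configuration for spike-in anchored count experiments
#'
#' Bundles the knobs of the synthetic experiment emulated throughout the
#' package: a two-condition RNA-seq/PRO-seq style design in which exogenous
#' spike-ins are present at the same expected abundance in every library
#' while every endogenous gene is amplified by a global factor `g` in the
#' second condition (the signature of hypertranscription). Counts are
#' negative binomial with variance mu + dispersion * mu^2.
#'
#' @param seed Integer root seed; all generator streams derive from it.
#' @param n_genes Number of endogenous genes.
#' @param n_spikein Number of spike-in species (>= 3).
#' @param reps_per_condition Replicates per condition.
#' @param amplification Global fold-change `g` (> 0) applied to the expected
#'   counts of every endogenous gene in condition 2.
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha mu^2.
#' @param frac_true_de Fraction of endogenous genes carrying an additional
#'   gene-specific fold-change on top of `g`.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp used
#'   by the genomic generators.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 100, n_spikein = 10)
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_spikein = 92L,
                       reps_per_condition = 3L,
                       amplification = 1.5,
                       dispersion = 0.05,
                       frac_true_de = 0,
                       chrom_sizes = c(sim1 = 2e6, sim2 = 1.5e6)) {
  if (!is.numeric(amplification) || amplification <= 0)
    stop("`amplification` must be a positive real", call. = FALSE)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("`dispersion` must be a positive real", call. = FALSE)
  if (n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)
  if (n_spikein < 3) stop("`n_spikein` must be >= 3", call. = FALSE)
  if (frac_true_de < 0 || frac_true_de > 1)
    stop("`frac_true_de` must lie in [0, 1]", call. = FALSE)
  if (length(chrom_sizes) < 1 || is.null(names(chrom_sizes)))
    stop("`chrom_sizes` must be a named vector", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_spikein = as.integer(n_spikein),
                 reps_per_condition = as.integer(reps_per_condition),
                 amplification = amplification,
                 dispersion = dispersion,
                 frac_true_de = frac_true_de,
                 chrom_sizes = chrom_sizes),
            class = "sim_config")
}

#' Construct a spike-in count matrix object
#'
#' Container for gene-by-sample integer counts with a per-row spike-in flag
#' and a two-level condition label per sample.
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param is_spikein Logical vector, one flag per row.
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels.
#' @return An object of class `spikein_counts`.
#' @export
spikein_counts <- function(counts, is_spikein, condition) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (length(is_spikein) != nrow(counts))
    stop("`is_spikein` must have one entry per gene row")
  condition <- factor(condition)
  if (nlevels(condition) != 2L || length(condition) != ncol(counts))
    stop("`condition` must partition the samples into exactly two groups")
  if (any(table(condition) == 0L))
    stop("both condition groups must be non-empty")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  structure(list(counts = counts,
                 is_spikein = as.logical(is_spikein),
                 condition = condition),
            class = "spikein_counts")
}

#' @export
print.spikein_counts <- function(x, ...) {
  cat(sprintf("spikein_counts: %d genes (%d spike-ins) x %d samples (%s)\n",
              nrow(x$counts), sum(x$is_spikein), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Simulate a two-condition count matrix with constant spike-ins
#'
#' Spike-in rows have condition-independent expected counts drawn from a
#' log-uniform ladder spanning four orders of magnitude (mimicking a
#' commercial spike-in mix). Endogenous rows have their condition-2 expected
#' counts multiplied by the global amplification factor of `cfg`, and a
#' `frac_true_de` subset additionally carries a gene-specific fold-change.
#' Counts are drawn NB(mu, alpha) with variance mu + alpha mu^2.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `matrix` (a [spikein_counts()]) and `truth`
#'   (data.frame of per-gene expected base means and true condition-2
#'   fold-changes, spike-ins included with fold-change 1).
#' @export
#' @examples
#' sim <- gen_spikein_counts(sim_config(seed = 7, n_genes = 50,
#'                                      n_spikein = 8))
#' head(sim$truth)
gen_spikein_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_stream(cfg$seed, "spikein_counts")

  n_g <- cfg$n_genes
  n_s <- cfg$n_spikein
  reps <- cfg$reps_per_condition
  n_samp <- 2L * reps

  spike_mu <- 10^seq(log10(0.5), log10(5000), length.out = n_s)
  gene_mu <- 10^stats::runif(n_g, log10(5), log10(2000))

  gene_fc <- rep(1, n_g)
  n_de <- round(cfg$frac_true_de * n_g)
  if (n_de > 0) {
    idx <- sample.int(n_g, n_de)
    gene_fc[idx] <- 2^stats::rnorm(n_de, 0, 1)
  }
  fc2 <- gene_fc * cfg$amplification

  mu <- rbind(
    cbind(matrix(gene_mu, n_g, reps), matrix(gene_mu * fc2, n_g, reps)),
    matrix(spike_mu, n_s, n_samp)
  )
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = nrow(mu))
  gene_ids <- c(sprintf("SIMG%05d", seq_len(n_g)),
                sprintf("SPIKE%03d", seq_len(n_s)))
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("cond1_r%d", seq_len(reps)),
                        sprintf("cond2_r%d", seq_len(reps)))
  is_spike <- c(rep(FALSE, n_g), rep(TRUE, n_s))
  cond <- rep(c("cond1", "cond2"), each = reps)

  truth <- data.frame(gene_id = gene_ids,
                      is_spikein = is_spike,
                      base_mean = c(gene_mu, spike_mu),
                      true_fc = c(fc2, rep(1, n_s)),
                      stringsAsFactors = FALSE)
  list(matrix = spikein_counts(counts, is_spike, cond), truth = truth)
}
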