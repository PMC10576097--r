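#' Derive a generator-specific RNG seed from a root seed
#'
#' Every simulator in the package draws from its own stream, keyed by a
#' generator name (and an optional index), so that adding a new generator to
#' a workflow never perturbs the fixtures produced by existing ones. The
#' derivation is a small deterministic hash of the name folded into the root
#' seed, reduced modulo 2^31 - 1 so the result is always a valid R seed.
#'
#' @param seed Integer root seed.
#' @param stream Character name of the generator stream.
#' @param index Optional non-negative integer sub-stream index.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "counts")
#' derive_seed(1, "counts", 2)
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 +
                h * 7919 + as.numeric(index)) %% 2147483646 + 1)
}

# Seed the session RNG for the duration of the calling function only.
local_stream <- function(seed, stream, index = 0L,
                         envir = parent.frame()) {
  withr::local_seed(derive_seed(seed, stream, index), .local_envir = envir)
}
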