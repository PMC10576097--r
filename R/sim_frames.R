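#' Construct a trajectory frame set
#'
#' Container for multi-frame atomic coordinates with donor / hydrogen /
#' acceptor annotations. `coords` is an atoms x 3 x frames array in
#' Angstrom; `atoms` describes each atom (name, residue, role); `pairs`
#' lists candidate hydrogen bonds as row indices into `atoms`.
#'
#' @param coords Numeric array `[n_atoms, 3, n_frames]`.
#' @param atoms Data frame with columns `atom_id`, `name`, `residue`,
#'   `role` (donor / hydrogen / acceptor).
#' @param pairs Data frame with columns `pair_id`, `donor_idx`,
#'   `hydrogen_idx`, `acceptor_idx`, `donor_residue`, `acceptor_atom`.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(coords, atoms, pairs) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            nrow(atoms) == dim(coords)[1])
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, atoms = atoms, pairs = pairs),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d atoms, %d frames, %d annotated pairs\n",
              dim(x$coords)[1], dim(x$coords)[3], nrow(x$pairs)))
  invisible(x)
}

#' Simulate trajectory frames with programmed hydrogen-bond occupancies
#'
#' Each requested pair is realised as a donor / hydrogen / acceptor triplet
#' whose geometry is hydrogen bonded (distance drawn in [2.7, 3.3] A,
#' D-H...A angle in [155, 180] degrees) in a Bernoulli fraction of frames
#' matching the target occupancy, and clearly non-bonded otherwise: a
#' non-bonded frame violates the distance criterion by at least 0.2 A or
#' the angle criterion by at least 10 degrees. Pairs are spatially offset
#' from one another so triplets never mix.
#'
#' @param n_frames Number of frames (>= 1).
#' @param pairs Data frame with columns `donor_residue`, `acceptor_atom`,
#'   `occupancy` (target percentage in [0, 100]); one row per pair.
#' @param seed Integer seed.
#' @return A [frame_set()]; the truth occupancies are kept in
#'   `$pairs$target_occupancy`.
#' @export
#' @examples
#' fs <- gen_trajectory_frames(50, data.frame(
#'   donor_residue = "S467", acceptor_atom = "Thy117 OP1",
#'   occupancy = 91.57), seed = 1)
gen_trajectory_frames <- function(n_frames, pairs, seed = 1L) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  if (any(pairs$occupancy < 0 | pairs$occupancy > 100))
    stop("target occupancies must lie in [0, 100]", call. = FALSE)
  local_stream(seed, "trajectory_frames")
  np <- nrow(pairs)
  n_atoms <- 3L * np
  coords <- array(NA_real_, c(n_atoms, 3L, n_frames))
  for (j in seq_len(np)) {
    offset <- c(20 * (j - 1L), 0, 0)
    bonded <- stats::runif(n_frames) < pairs$occupancy[j] / 100
    for (f in seq_len(n_frames)) {
      if (bonded[f]) {
        dist <- stats::runif(1, 2.7, 3.3)
        ang <- stats::runif(1, 155, 180)
      } else if (stats::runif(1) < 0.5) {
        dist <- stats::runif(1, 3.7, 5.0)   # distance violated by >= 0.2 A
        ang <- stats::runif(1, 140, 180)
      } else {
        dist <- stats::runif(1, 2.7, 3.3)
        ang <- stats::runif(1, 60, 125)     # angle violated by >= 10 deg
      }
      coords[(3L * j - 2L):(3L * j), , f] <-
        sweep(hbond_triplet(dist, ang), 2L, offset, "+")
    }
  }
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    name = rep(c("N", "H", "O"), np),
    residue = rep(sprintf("PAIR%d", seq_len(np)), each = 3L),
    role = rep(c("donor", "hydrogen", "acceptor"), np),
    stringsAsFactors = FALSE)
  pair_tab <- data.frame(
    pair_id = sprintf("pair%d", seq_len(np)),
    donor_idx = 3L * seq_len(np) - 2L,
    hydrogen_idx = 3L * seq_len(np) - 1L,
    acceptor_idx = 3L * seq_len(np),
    donor_residue = pairs$donor_residue,
    acceptor_atom = pairs$acceptor_atom,
    target_occupancy = pairs$occupancy,
    stringsAsFactors = FALSE)
  frame_set(coords, atoms, pair_tab)
}

# Donor at origin, hydrogen 1 A along +x; acceptor placed so that the
# D-A distance is `dist` and the D-H...A angle (at the hydrogen) is `ang`
# degrees, in a random azimuthal plane.
hbond_triplet <- function(dist, ang) {
  d <- c(0, 0, 0)
  h <- c(1, 0, 0)
  phi <- stats::runif(1, 0, 2 * pi)
  w <- c(0, cos(phi), sin(phi))           # unit vector perpendicular to x
  theta <- ang * pi / 180
  v <- cos(theta) * c(-1, 0, 0) + sin(theta) * w  # direction H -> A
  bq <- 2 * v[1]                           # from |h + t v| = dist, |h| = 1
  tq <- (-bq + sqrt(bq^2 - 4 * (1 - dist^2))) / 2
  a <- h + tq * v
  rbind(d, h, a, deparse.level = 0)
}

#' Apply a rigid rotation + translation to every frame
#'
#' Utility for invariance checks: hydrogen-bond geometry must not change
#' under rigid-body motion of a frame.
#'
#' @param frames A [frame_set()].
#' @param rotation 3x3 orthogonal matrix.
#' @param translation Length-3 numeric.
#' @return Transformed `frame_set`.
#' @export
transform_frames <- function(frames, rotation = diag(3),
                             translation = c(0, 0, 0)) {
  coords <- frames$coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- coords[, , f] %*% t(rotation) +
      matrix(translation, dim(coords)[1], 3, byrow = TRUE)
  frame_set(coords, frames$atoms, frames$pairs)
}
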