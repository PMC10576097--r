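#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair counts as hydrogen bonded in a frame when the
#' donor-acceptor heavy-atom distance is at most `max_distance` AND the
#' bond angle is at least `min_angle`, both comparisons inclusive. The
#' angle is by default the conventional D-H...A angle measured at the
#' hydrogen; `angle_at = "donor"` switches to a donor-centred H-D-A
#' variant.
#'
#' @param max_distance Maximum heavy-atom distance in Angstrom (default
#'   3.5).
#' @param min_angle Minimum angle in degrees (default 135).
#' @param persistence Occupancy percentage a pair must strictly exceed to
#'   be retained by [persistence_filter()] (default 5).
#' @param angle_at `"hydrogen"` (default) or `"donor"`.
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 135,
                           persistence = 5,
                           angle_at = c("hydrogen", "donor")) {
  if (max_distance <= 0) stop("`max_distance` must be > 0", call. = FALSE)
  if (min_angle <= 0 || min_angle > 180)
    stop("`min_angle` must lie in (0, 180]", call. = FALSE)
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 persistence = persistence,
                 angle_at = match.arg(angle_at)),
            class = "hbond_criteria")
}

vec_angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Hydrogen-bond presence in a single frame
#'
#' @param d,h,a Numeric length-3 coordinates (Angstrom) of donor heavy
#'   atom, hydrogen, and acceptor heavy atom.
#' @param criteria A [hbond_criteria()].
#' @return `TRUE` when both the distance and angle criteria hold.
#' @export
#' @examples
#' detect_hbond(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))  # collinear, 2.8 A
detect_hbond <- function(d, h, a, criteria = hbond_criteria()) {
  if (any(!is.finite(c(d, h, a))))
    stop("missing or non-finite atom coordinates (is the hydrogen ",
         "mapped to its donor?)", call. = FALSE)
  dist_da <- sqrt(sum((a - d)^2))
  ang <- if (criteria$angle_at == "hydrogen")
    vec_angle_deg(d - h, a - h) else vec_angle_deg(h - d, a - d)
  dist_da <= criteria$max_distance && ang >= criteria$min_angle
}

# Per-frame presence matrix (frames x pairs) for a frame_set.
hbond_presence <- function(frames, criteria = hbond_criteria()) {
  stopifnot(inherits(frames, "frame_set"))
  np <- nrow(frames$pairs)
  nf <- dim(frames$coords)[3]
  pres <- matrix(FALSE, nf, np,
                 dimnames = list(NULL, frames$pairs$pair_id))
  for (j in seq_len(np)) {
    ix <- unlist(frames$pairs[j, c("donor_idx", "hydrogen_idx",
                                   "acceptor_idx")])
    for (f in seq_len(nf)) {
      xyz <- frames$coords[ix, , f]
      pres[f, j] <- detect_hbond(xyz[1, ], xyz[2, ], xyz[3, ], criteria)
    }
  }
  pres
}

#' Hydrogen-bond occupancy over an analysis window
#'
#' For each annotated donor-hydrogen-acceptor pair, the percentage of
#' analysed frames in which the bond is present. The analysis window is
#' the last `window_last` fraction of frames (mirroring restriction of the
#' analysis to the equilibrated tail of a trajectory); `window_last = 1`
#' analyses everything.
#'
#' @param frames A `frame_set` (see [gen_trajectory_frames()] /
#'   [read_frames_pdb()]).
#' @param criteria A [hbond_criteria()].
#' @param window_last Fraction (0, 1] of trailing frames to analyse.
#' @return Data frame `pair_id`, `donor_residue`, `acceptor_atom`,
#'   `occupancy` (percent), `n_frames`.
#' @export
occupancy <- function(frames, criteria = hbond_criteria(),
                      window_last = 1) {
  nf <- dim(frames$coords)[3]
  n_win <- as.integer(round(window_last * nf))
  if (window_last <= 0 || n_win < 1L)
    stop("empty analysis window", call. = FALSE)
  keep <- seq.int(nf - n_win + 1L, nf)
  pres <- hbond_presence(frames, criteria)[keep, , drop = FALSE]
  data.frame(pair_id = frames$pairs$pair_id,
             donor_residue = frames$pairs$donor_residue,
             acceptor_atom = frames$pairs$acceptor_atom,
             occupancy = 100 * colMeans(pres),
             n_frames = n_win,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Retain only persistent hydrogen bonds
#'
#' Keeps rows whose occupancy strictly exceeds the persistence threshold
#' ("more than 5%" by default), matching the reporting convention for
#' published occupancy tables.
#'
#' @param occ Output of [occupancy()].
#' @param threshold Occupancy percentage that must be exceeded (default 5).
#' @return Filtered data frame.
#' @export
persistence_filter <- function(occ, threshold = 5) {
  occ[occ$occupancy > threshold, , drop = FALSE]
}

#' First frame after which a contact count stays zero
#'
#' Descriptive unbinding statistic: the smallest 0-based frame index `i`
#' such that the per-frame contact count is zero from `i` onwards. Returns
#' `NA` when contacts persist to the final frame.
#'
#' @param contact_counts Integer vector of per-frame contact counts.
#' @return 0-based frame index, or `NA_integer_`.
#' @export
#' @examples
#' unbinding_time(c(3, 2, 1, 0, 0))  # 3
unbinding_time <- function(contact_counts) {
  if (!length(contact_counts)) return(NA_integer_)
  nz <- which(contact_counts > 0)
  if (!length(nz)) return(0L)
  if (max(nz) == length(contact_counts)) return(NA_integer_)
  as.integer(max(nz))  # 0-based index of the first all-zero tail frame
}
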