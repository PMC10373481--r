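resolve_region <- function(n, labels = NULL, l = NULL, region) {
  # region: vector of state labels, or list(min=, max=) interval on l
  if (is.list(region)) {
    if (is.null(l)) stop("interval regions need `l` values", call. = FALSE)
    l >= region$min & l <= region$max
  } else {
    if (is.null(labels)) stop("label regions need `labels`", call. = FALSE)
    labels %in% region
  }
}

#' Per-frame committor from a trajectory
#'
#' For each frame, scans forward in time: the committor is 1 if region A is
#' reached before region B, 0 if B is reached first, and undefined (`NA`)
#' when neither occurs before the trajectory ends.  Frames inside A get 1
#' and frames inside B get 0.  Regions are given either as sets of state
#' labels or as `list(min, max)` intervals on a CV series.
#'
#' @param labels Optional per-frame state labels.
#' @param l Optional per-frame CV values.
#' @param A,B Region definitions (label vectors or `list(min=, max=)`); must
#'   not overlap.
#' @return Numeric vector of 0, 1 or `NA`, one per frame.
#' @export
frame_committors <- function(labels = NULL, l = NULL, A, B) {
  n <- max(length(labels), length(l))
  in_A <- resolve_region(n, labels, l, A)
  in_B <- resolve_region(n, labels, l, B)
  if (any(in_A & in_B))
    stop("A and B definitions overlap", call. = FALSE)
  cm <- rep(NA_real_, n)
  nxt <- NA_real_  # committor of the next A/B visit at or after t
  for (t in n:1) {
    if (in_A[t]) nxt <- 1 else if (in_B[t]) nxt <- 0
    cm[t] <- nxt
  }
  cm
}

#' Committor binned along a reaction coordinate
#'
#' Averages defined per-frame committors within half-open bins
#' `[edge_k, edge_k+1)` of the coordinate, and attaches the free energy of
#' the coordinate histogram over the same bins.
#'
#' @param l Per-frame CV values.
#' @param committors Per-frame committors from [frame_committors()]
#'   (undefined values are excluded from both numerator and denominator).
#' @param n_bins Number of bins.
#' @param range Length-2 CV range; defaults to the data range.
#' @param temperature Temperature (K) for the free-energy column.
#' @return Tibble of class `committor_result` with columns `bin_lo`,
#'   `bin_hi`, `bin_mid`, `count` (defined committors in the bin), `p_c`,
#'   and `F` (kcal/mol, min-shifted; `NA` for empty bins).
#' @export
binned_committor <- function(l, committors, n_bins = 150, range = NULL,
                             temperature = 300) {
  stopifnot(length(l) == length(committors))
  if (is.null(range)) range <- base::range(l)
  if (diff(range) <= 0) stop("degenerate range", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- findInterval(l, edges, rightmost.closed = FALSE, left.open = FALSE)
  ok <- bin >= 1 & bin <= n_bins
  def <- ok & !is.na(committors)
  count <- tabulate(bin[def], n_bins)
  p_sum <- rep(0, n_bins)
  if (any(def)) {
    agg <- tapply(committors[def], bin[def], sum)
    p_sum[as.integer(names(agg))] <- agg
  }
  p_c <- ifelse(count > 0, p_sum / count, NA_real_)
  fes <- fes_histogram(l[ok], temperature = temperature, n_bins = n_bins,
                       range = range)
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                        count = count, p_c = p_c, F = fes$F)
  class(out) <- c("committor_result", class(out))
  out
}

#' Free energy from a (weighted) histogram
#'
#' \eqn{F(l) = -k_B T \ln P(l)} from the normalized, optionally weighted
#' histogram of the coordinate, min-shifted to zero.  Empty bins are
#' reported as `NA`, never infinite.
#'
#' @param l Per-frame CV values.
#' @param weights Optional non-negative frame weights (uniform when `NULL`).
#' @param temperature Temperature (K).
#' @param n_bins,range Binning controls (half-open bins).
#' @return Tibble of class `fes_result` with columns `q` (bin centers),
#'   `count`, `P`, `F`.
#' @export
fes_histogram <- function(l, weights = NULL, temperature = 300, n_bins = 150,
                          range = NULL) {
  if (is.null(weights)) weights <- rep(1, length(l))
  stopifnot(length(weights) == length(l), all(weights >= 0))
  if (is.null(range)) range <- base::range(l)
  if (diff(range) <= 0) stop("degenerate range", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- findInterval(l, edges)
  ok <- bin >= 1 & bin <= n_bins
  if (!any(ok)) stop("no samples fall inside the histogram range", call. = FALSE)
  w <- rep(0, n_bins)
  agg <- tapply(weights[ok], bin[ok], sum)
  w[as.integer(names(agg))] <- agg
  P <- w / sum(w)
  F <- ifelse(P > 0, -kB * temperature * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  out <- tibble::tibble(q = (edges[-1] + edges[-length(edges)]) / 2,
                        count = w, P = P, F = F)
  class(out) <- c("fes_result", class(out))
  out
}

#' Quasi-static reweighting factors from a bias series
#'
#' Final-bias reweighting: \eqn{w_t \propto \exp[V(Q_t)/k_B T]}, normalized
#' to mean one.  Appropriate when the bias changes slowly compared to the
#' sampling (e.g. late-stage well-tempered metadynamics).
#'
#' @param bias Per-frame bias energies (kcal/mol), evaluated with the final
#'   bias at each frame's CV value.
#' @param temperature Temperature (K).
#' @return Per-frame weights with mean 1.
#' @export
reweight_frames <- function(bias, temperature = 300) {
  w <- exp((bias - max(bias)) / (kB * temperature))
  w / mean(w)
}

#' Signed dihedral angle of four particles
#'
#' IUPAC convention: right-handed, cis = 0, value in `(-pi, pi]`.
#'
#' @param frame `N x 3` coordinate matrix.
#' @param i,j,k,l Particle indices (1-based).
#' @return Angle in radians.
#' @export
dihedral_angle <- function(frame, i, j, k, l) {
  cpp_dihedral(check_frame(frame), i, j, k, l)
}

#' Helicity order parameter: negative sum of phi dihedrals
#'
#' \eqn{\zeta' = -\sum_n \phi_n} over the supplied atom quadruples, each
#' signed dihedral in \eqn{(-\pi, \pi]}.  For an ideal right-handed 3-10
#' helix with \eqn{\phi = -57^\circ} summed over five central residues this
#' is about +5 rad; a mirror-image (left-handed) structure gives the exact
#' negation.
#'
#' @param frame `N x 3` coordinate matrix.
#' @param phi_quads Matrix with 4 columns: one atom quadruple per row.
#' @return Scalar, radians.
#' @export
zeta_prime <- function(frame, phi_quads) {
  frame <- check_frame(frame)
  phi_quads <- matrix(phi_quads, ncol = 4)
  -sum(apply(phi_quads, 1, function(q)
    cpp_dihedral(frame, q[1], q[2], q[3], q[4])))
}
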