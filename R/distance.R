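#' Distance discretization bins
#'
#' The 14-interval discretization of Cbeta-Cbeta distances used throughout:
#' `< 4` Angstrom, thirteen right-open 1-Angstrom intervals `[4,5), ...,
#' [15,16)`, and `>= 16` Angstrom.  Together the intervals partition
#' `[0, Inf)`.
#'
#' @return Object of class `distance_bins`: list with `boundaries` (the 13
#'   thresholds 4..16), `n_bins` (14) and `midpoints` (bin representative
#'   distances: 2.0 for the first bin, interval midpoints for interior bins,
#'   lower edge + 0.5 for the last).
#' @export
distance_bins <- function() {
  b <- 4:16
  structure(list(boundaries = b, n_bins = 14L,
                 midpoints = c(2, b[-length(b)] + 0.5, 16.5)),
            class = "distance_bins")
}

#' Discretize distances into the 14 standard bins
#'
#' @param d numeric vector/matrix of distances in Angstrom (non-negative,
#'   finite).
#' @param bins a [distance_bins()] object.
#' @return Integer bin indices in `1..14`, same shape as `d`.
#' @export
discretize_distance <- function(d, bins = distance_bins()) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  out <- findInterval(d, bins$boundaries) + 1L
  if (is.matrix(d)) dim(out) <- dim(d)
  out
}

#' Convert a predicted distance distribution into a DFIRE-referenced potential
#'
#' Given predicted probabilities `p(j, l, b)` that query residues `j` and `l`
#' fall into distance bin `b`, computes the statistical potential
#' `u(j, l, b) = -log(p(j, l, b) / p_ref(b))` against the distance-scaled
#' finite ideal-gas (DFIRE) reference state `p_ref(b) proportional to
#' r_b^alpha`, where `r_b` is the bin's representative distance, normalized
#' over the 14 bins.  Potentials are clipped to `[-clip, clip]` so that
#' zero-probability bins stay finite.  Lower potential means a more
#' favourable distance.
#'
#' @param p numeric array `n2 x n2 x 14`, rows summing to 1 over bins;
#'   symmetric in its first two indices.
#' @param alpha DFIRE exponent (default 1.61).
#' @param clip clipping magnitude (default 10).
#' @param bins a [distance_bins()] object.
#' @return Object of class `distance_potential`: list with `u` (same shape
#'   as `p`), `alpha`, `clip`, `p_ref`.
#' @export
dfire_potential <- function(p, alpha = 1.61, clip = 10, bins = distance_bins()) {
  stopifnot(is.array(p), length(dim(p)) == 3L, dim(p)[3] == bins$n_bins,
            dim(p)[1] == dim(p)[2])
  p_ref <- bins$midpoints^alpha
  p_ref <- p_ref / sum(p_ref)
  u <- -log(sweep(p, 3, p_ref, "/"))
  u <- pmin(pmax(u, -clip), clip)
  structure(list(u = u, alpha = alpha, clip = clip, p_ref = p_ref),
            class = "distance_potential")
}

#' @export
print.distance_potential <- function(x, ...) {
  cat(sprintf("DFIRE-referenced distance potential: %d query positions, %d bins, alpha = %.2f, clip = %.3g\n",
              dim(x$u)[1], dim(x$u)[3], x$alpha, x$clip))
  invisible(x)
}

#' Bin a template distance matrix
#'
#' @param dist symmetric `n1 x n1` matrix of template Cbeta-Cbeta distances
#'   in Angstrom (e.g. `TemplateRecord$dist`).
#' @param bins a [distance_bins()] object.
#' @return Integer matrix of bin indices, class `template_distance_bins`.
#' @export
template_distance_bins <- function(dist, bins = distance_bins()) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist),
            max(abs(dist - t(dist))) < 1e-6)
  structure(discretize_distance(dist, bins), class = "template_distance_bins")
}

## Pair score theta_ijkl^MM: minus the query-pair potential evaluated at the
## template pair's distance bin; template pairs beyond 16 Angstrom (the last
## bin) contribute nothing.
.pair_score <- function(u, tbins, i, j, k, l) {
  b <- tbins[i, k]
  if (b >= dim(u)[3]) return(0)
  -u[j, l, b]
}

#' Pairwise (distance) component of the threading objective
#'
#' Sums the pair scores `theta_ijkl^MM = -u(j, l, bin(i, k))` over all
#' unordered pairs of distinct matched positions `{(i,j), (k,l)}` of the
#' alignment.  Template pairs falling into the last (`>= 16` Angstrom) bin
#' contribute zero, as do self-pairs.
#'
#' @param a a valid `protein_alignment`.
#' @param u a [dfire_potential()] over query pairs.
#' @param tbins a [template_distance_bins()] matrix.
#' @return Numeric scalar (higher is better).
#' @export
pairwise_score <- function(a, u, tbins) {
  stopifnot(inherits(u, "distance_potential"),
            inherits(tbins, "template_distance_bins"))
  ap <- aligned_pairs(a) + 1L
  m <- nrow(ap)
  if (m < 2L) return(0)
  nb <- dim(u$u)[3]
  total <- 0
  for (r in 1:(m - 1L)) for (s in (r + 1L):m) {
    b <- tbins[ap[r, 1], ap[s, 1]]
    if (b < nb) total <- total - u$u[ap[r, 2], ap[s, 2], b]
  }
  total
}

## Matrix of pair scores theta_ijkl^MM over all (i, j) for one fixed matched
## pair (k, l): entry (i, j) is -u(j, l, bin(i, k)), zeroed where the
## template pair falls beyond 16 Angstrom (last bin) and on the degenerate
## rows i == k / columns j == l (self-pairs never arise within one valid
## alignment).  Used by the ADMM subproblems and the refiner input.
.pair_score_matrix <- function(u, tbins, k, l) {
  nb <- dim(u$u)[3]
  bcol <- tbins[, k]                    # template bins, length n1
  s <- -t(u$u[, l, ])[bcol, , drop = FALSE] # n1 x n2: -u[j, l, bcol[i]]
  s[bcol >= nb, ] <- 0
  s[k, ] <- 0
  s[, l] <- 0
  s
}

#' Threading objective (singleton + pairwise)
#'
#' Evaluates the distance-augmented threading score
#' `S = w * S_singleton + S_pairwise` of an alignment, where `S_singleton`
#' is the sum of emission scores over the alignment's triples and
#' `S_pairwise` is [pairwise_score()].  `w` defaults to 1 and may be raised
#' (e.g. to 20) when the template is clearly homologous, emphasizing the
#' sequence-derived singleton scores.
#'
#' @param a a valid `protein_alignment`.
#' @param theta a [score_table()].
#' @param u a [dfire_potential()]; `NULL` for a pure singleton objective.
#' @param tbins a [template_distance_bins()] matrix (required with `u`).
#' @param w singleton weight (default 1).
#' @return Object of class `threading_objective`: list with `s_total`,
#'   `s_singleton`, `s_pairwise`, `w`.
#' @export
threading_objective <- function(a, theta, u = NULL, tbins = NULL, w = 1) {
  validate_alignment(a)
  s1 <- score_alignment(a, theta, transition_model()) # zero transition scores
  s2 <- if (is.null(u)) 0 else pairwise_score(a, u, tbins)
  structure(list(s_total = w * s1 + s2, s_singleton = s1, s_pairwise = s2,
                 w = w),
            class = "threading_objective")
}

#' @export
print.threading_objective <- function(x, ...) {
  cat(sprintf("threading objective: S = %.6g (w = %.3g, singleton %.6g, pairwise %.6g)\n",
              x$s_total, x$w, x$s_singleton, x$s_pairwise))
  invisible(x)
}
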