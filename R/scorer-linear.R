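#' Linear emission scorer
#'
#' Builds a [score_table()] whose match score is an affine function of the
#' pairwise feature channels, `theta(i, j, M) = <weights, features(i, j)> +
#' bias`, with constant insertion penalties for `Ix`/`Iy` and zero head/tail
#' gap scores.  Serves both as a fast baseline scorer and as the exactly
#' trainable model of [train_mle()].
#'
#' @param features a [pair_features()] array (`n1 x n2 x C`).
#' @param weights numeric vector, one weight per feature channel.
#' @param bias scalar added to every match score.
#' @param gap_ix,gap_iy constant `Ix`/`Iy` emissions (gap penalties, usually
#'   negative).
#' @return A [score_table()].
#' @export
linear_score <- function(features, weights, bias = 0, gap_ix = 0, gap_iy = 0) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  nc <- dim(features)[3]
  if (length(weights) != nc)
    stop("need one weight per feature channel (", nc, ")")
  m <- matrix(0, dim(features)[1], dim(features)[2])
  for (c in seq_len(nc)) m <- m + weights[c] * features[, , c]
  score_table(m + bias, gap_ix = gap_ix, gap_iy = gap_iy)
}

## Parameter vector layout of the linear scorer:
## c(weights[1..C], bias, gap_ix, gap_iy)
.linear_theta <- function(par, features) {
  nc <- dim(features)[3]
  linear_score(features, par[seq_len(nc)], bias = par[nc + 1],
               gap_ix = par[nc + 2], gap_iy = par[nc + 3])
}

## Observed emission-cell indicator counts of a reference alignment, mapped
## with the same cell convention as the DP kernels.
.obs_cells <- function(ref, n1, n2) {
  s7 <- triple_internal_states(ref)
  ic <- pmax(cumsum(DX7[s7]), 1L)
  jc <- pmax(cumsum(DY7[s7]), 1L)
  u <- match(ref$triples$state, ALIGN_STATES)
  d <- array(0, dim = c(n1, n2, 5L))
  for (r in seq_along(u)) d[ic[r], jc[r], u[r]] <- d[ic[r], jc[r], u[r]] + 1
  d
}

## Observed collapsed transition counts (5x5) of a reference alignment.
.obs_transitions <- function(ref) {
  m <- matrix(0, 5, 5)
  u <- match(ref$triples$state, ALIGN_STATES)
  if (length(u) > 1L)
    for (k in seq_len(length(u) - 1L)) m[u[k], u[k + 1L]] <- m[u[k], u[k + 1L]] + 1
  m
}

## Gradient of the reference log-likelihood for the linear scorer: observed
## minus expected emission-cell counts, contracted with the features.
.linear_grad <- function(par, features, ref, tm, want_edges = FALSE) {
  theta <- .linear_theta(par, features)
  fb <- forward_backward(theta, tm, edges = want_edges)
  d <- .obs_cells(ref, theta$n1, theta$n2) - fb$post
  nc <- dim(features)[3]
  g <- numeric(nc + 3)
  dM <- d[, , 1]
  for (c in seq_len(nc)) g[c] <- sum(dM * features[, , c])
  g[nc + 1] <- sum(dM)
  g[nc + 2] <- sum(d[, , 2])
  g[nc + 3] <- sum(d[, , 3])
  list(grad = g, loglik = score_alignment(ref, theta, tm) - fb$logZ,
       edge_grad = if (want_edges) .obs_transitions(ref) - fb$edges else NULL)
}
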