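#' Emission score table theta(i, j, u)
#'
#' Container for per-cell emission scores of the alignment CRF: a real score
#' for every template position `i`, query position `j` and state `u`.  Gap
#' and flank states usually carry constant or zero scores (head/tail gaps are
#' zero by default so the alignment is local); a scorer fills the `M` (and
#' optionally `Ix`/`Iy`) slices.
#'
#' @param theta numeric array `n1 x n2 x 5` (states ordered M, Ix, Iy, Gh,
#'   Gt), or `n1 x n2` matrix taken as the `M` slice with all other states 0.
#' @param gap_ix,gap_iy constant emission added to the `Ix`/`Iy` slices when
#'   `theta` is given as a matrix.
#' @return Object of class `score_table` with elements `theta`, `n1`, `n2`.
#' @export
score_table <- function(theta, gap_ix = 0, gap_iy = 0) {
  if (is.matrix(theta)) {
    th <- array(0, dim = c(dim(theta), 5L))
    th[, , 1] <- theta
    th[, , 2] <- gap_ix
    th[, , 3] <- gap_iy
    theta <- th
  }
  stopifnot(is.array(theta), length(dim(theta)) == 3L, dim(theta)[3] == 5L,
            all(is.finite(theta)))
  dimnames(theta) <- list(NULL, NULL, ALIGN_STATES)
  structure(list(theta = theta, n1 = dim(theta)[1], n2 = dim(theta)[2]),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score table: %d x %d cells, 5 states; M scores in [%.3g, %.3g]\n",
              x$n1, x$n2, min(x$theta[, , 1]), max(x$theta[, , 1])))
  invisible(x)
}

#' @export
plot.score_table <- function(x, state = "M", ...) {
  u <- match.arg(state, ALIGN_STATES)
  graphics::image(seq_len(x$n1), seq_len(x$n2), x$theta[, , u],
                  xlab = "template position", ylab = "query position",
                  main = paste("emission scores,", u), useRaster = TRUE, ...)
  invisible(x)
}
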