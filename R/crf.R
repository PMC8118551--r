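#' Viterbi decoding of the alignment CRF
#'
#' Returns the valid alignment maximizing the total score (emissions plus
#' transition scores) by dynamic programming over the five-state model.
#' Ties are broken deterministically by state preference
#' M > Ix > Iy > Gh > Gt (template-consuming flank steps before
#' query-consuming ones).
#'
#' @param theta a [score_table()].
#' @param tm a [transition_model()].
#' @return List with elements `alignment` (a `protein_alignment`) and
#'   `score` (the maximal total score).
#' @export
viterbi <- function(theta, tm = transition_model()) {
  stopifnot(inherits(theta, "score_table"))
  ex <- expand_transitions(tm)
  res <- cpp_viterbi(theta$theta, c(theta$n1, theta$n2), ex$feasible, ex$score)
  a <- .path7_to_alignment(res$path, theta$n1, theta$n2)
  list(alignment = a, score = res$score)
}

.path7_to_alignment <- function(path, n1, n2) {
  s7 <- path[, 3]
  ii <- ifelse(DX7[s7] == 1L, path[, 1] - 1L, -1L)
  jj <- ifelse(DY7[s7] == 1L, path[, 2] - 1L, -1L)
  alignment(data.frame(i = ii, j = jj, state = ALIGN_STATES[S7_TO_S5[s7]]),
            n1, n2, validate = FALSE)
}

#' Forward-backward inference for the alignment CRF
#'
#' Computes the log partition function over all valid alignments and the
#' posterior expected indicator count for every emission cell `(i, j, u)`,
#' all in log space.  The `M` slice of the posterior is the match marginal
#' `p_match(i, j)`, the probability that template position `i` aligns to
#' query position `j`.
#'
#' @param theta a [score_table()].
#' @param tm a [transition_model()].
#' @param edges also accumulate the 5x5 expected transition counts (needed
#'   when training transition scores).
#' @return Object of class `posterior_table`: list with `p_match` (n1 x n2
#'   matrix), `post` (n1 x n2 x 5 expected counts), `logZ`, `edges`, `n1`,
#'   `n2`.
#' @export
forward_backward <- function(theta, tm = transition_model(), edges = FALSE) {
  stopifnot(inherits(theta, "score_table"))
  ex <- expand_transitions(tm)
  res <- cpp_forward_backward(theta$theta, c(theta$n1, theta$n2),
                              ex$feasible, ex$score, edges)
  structure(list(p_match = res$post[, , 1, drop = TRUE],
                 post = res$post, logZ = res$logZ,
                 edges = if (edges) res$edges else NULL,
                 n1 = theta$n1, n2 = theta$n2),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("CRF posteriors: %d x %d cells, logZ = %.6g, max p_match = %.4f\n",
              x$n1, x$n2, x$logZ, max(x$p_match)))
  invisible(x)
}

#' Maximum-expected-accuracy decoding
#'
#' Returns the valid alignment maximizing the expected number of correctly
#' aligned positions, i.e. the sum of posterior match probabilities over its
#' matched pairs, by dynamic programming over the same state space as
#' [viterbi()] (gap steps contribute zero; only the feasibility mask of `tm`
#' is used, all transition scores being irrelevant to the objective).
#'
#' @param post a `posterior_table` from [forward_backward()].
#' @param tm a [transition_model()] supplying the feasibility mask.
#' @return List with `alignment` and `objective` (the attained expected
#'   accuracy).
#' @export
maxacc_decode <- function(post, tm = transition_model()) {
  stopifnot(inherits(post, "posterior_table"))
  pm <- matrix(post$p_match, post$n1, post$n2)
  th <- score_table(pm)
  res <- viterbi(th, transition_model(feasible = tm$feasible))
  list(alignment = res$alignment, objective = res$score)
}

#' Log-likelihood of an alignment under the CRF
#'
#' The total score of the alignment minus the log partition function; always
#' `<= 0`, and `exp(loglik)` sums to one over all valid alignments.
#'
#' @param a a valid `protein_alignment`.
#' @param theta a [score_table()].
#' @param tm a [transition_model()].
#' @return Numeric scalar log-probability.
#' @export
loglik <- function(a, theta, tm = transition_model()) {
  validate_alignment(a, tm)
  score_alignment(a, theta, tm) - forward_backward(theta, tm)$logZ
}
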