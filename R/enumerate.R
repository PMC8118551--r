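#' Enumerate all valid alignments of two small proteins
#'
#' Exhaustively lists every valid alignment of a template of length `n1` and
#' a query of length `n2`.  Because valid alignments are canonical (one per
#' non-empty set of strictly increasing matched pairs), enumeration reduces
#' to enumerating such pair sets.  Intended as an independent oracle for the
#' dynamic-programming routines at small sizes; the count grows as
#' `choose(n1+n2, n1) - 1`, so keep `n1, n2 <= 6` or so.
#'
#' @param n1,n2 protein lengths.
#' @return List of `protein_alignment` objects.
#' @export
enumerate_alignments <- function(n1, n2) {
  out <- list()
  recurse <- function(pairs, i0, j0) {
    if (nrow(pairs) > 0L)
      out[[length(out) + 1L]] <<- alignment_from_pairs(pairs, n1, n2)
    if (i0 >= n1 || j0 >= n2) return(invisible())
    for (i in i0:(n1 - 1L)) for (j in j0:(n2 - 1L))
      recurse(rbind(pairs, c(i, j)), i + 1L, j + 1L)
  }
  recurse(matrix(integer(0), ncol = 2), 0L, 0L)
  out
}

## Emission context for a triple: gap triples read theta at the current
## consumed count on the unconsumed side, clamped to >= 1 (only head gaps,
## where nothing is consumed yet, hit the clamp).  Shared convention between
## this reference scorer and the DP kernels.
#' Score an alignment under a score table and transition model
#'
#' Sums the emission scores theta(i, j, u) over the alignment's triples plus
#' the transition scores of consecutive state pairs.  This is the exact
#' quantity the Viterbi decoder maximizes and the numerator of the CRF
#' log-likelihood.  Implemented as a direct walk over the triples,
#' independent of the dynamic-programming kernels.
#'
#' @param a a valid `protein_alignment`.
#' @param theta a [score_table()].
#' @param tm a [transition_model()].
#' @return Numeric scalar.
#' @export
score_alignment <- function(a, theta, tm = transition_model()) {
  stopifnot(inherits(theta, "score_table"),
            a$n1 == theta$n1, a$n2 == theta$n2)
  th <- theta$theta
  s7 <- triple_internal_states(a)
  ic <- cumsum(DX7[s7])
  jc <- cumsum(DY7[s7])
  u <- match(a$triples$state, ALIGN_STATES)
  em <- th[cbind(pmax(ic, 1L), pmax(jc, 1L), u)]
  total <- sum(em)
  if (length(u) > 1L)
    total <- total + sum(tm$score[cbind(S7_TO_S5[s7[-length(s7)]],
                                        S7_TO_S5[s7[-1]])])
  total
}
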