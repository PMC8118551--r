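#' @useDynLib threadcrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Five alignment states of the pairwise-alignment CRF.
## M  : two residues aligned
## Ix : insertion in the template (template residue unmatched, between matches)
## Iy : insertion in the query
## Gh : head gap (unpenalized flank before the first match)
## Gt : tail gap (unpenalized flank after the last match)
ALIGN_STATES <- c("M", "Ix", "Iy", "Gh", "Gt")

## Internal directional expansion: head/tail gaps consume exactly one residue
## of either protein per step, so Gh/Gt each split into a template-consuming
## (Hx/Tx) and a query-consuming (Hy/Ty) sub-state.  Within a flank all
## template-consuming steps precede query-consuming ones (the mirror of the
## "Ix before Iy" canonicalization), i.e. Hy->Hx and Ty->Tx are forbidden.
STATES7 <- c("M", "Ix", "Iy", "Hx", "Hy", "Tx", "Ty")
S7_TO_S5 <- c(1L, 2L, 3L, 4L, 4L, 5L, 5L)
DX7 <- c(1L, 1L, 0L, 1L, 0L, 1L, 0L) # template residues consumed per step
DY7 <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L) # query residues consumed per step
START7 <- c(1L, 4L, 5L)              # virtual start enters {M, Gh}
END7 <- c(1L, 6L, 7L)                # virtual end leaves {M, Gt}

## Transitions whose scores the model keeps fixed at zero so that flanking
## gaps are unpenalized (local alignment): M->Gt, Gh->M, Gh->Gh, Gt->Gt.
.ZERO_SCORED <- cbind(c(1L, 4L, 4L, 5L), c(5L, 1L, 4L, 5L))

.default_feasible <- function() {
  f <- matrix(FALSE, 5, 5, dimnames = list(ALIGN_STATES, ALIGN_STATES))
  f["M",  c("M", "Ix", "Iy", "Gt")] <- TRUE
  f["Ix", c("M", "Ix", "Iy")] <- TRUE
  f["Iy", c("M", "Iy")] <- TRUE      # Iy -> Ix forbidden (canonical order)
  f["Gh", c("M", "Gh")] <- TRUE      # Gh -> Gt forbidden (>= 1 match)
  f["Gt", "Gt"] <- TRUE
  f
}

#' Five-state transition model for the alignment CRF
#'
#' Builds the state-transition model over the states `M`, `Ix`, `Iy`, `Gh`,
#' `Gt`.  The default feasibility mask allows exactly 12 of the 25 ordered
#' state pairs: `M -> {M, Ix, Iy, Gt}`, `Ix -> {M, Ix, Iy}`, `Iy -> {M, Iy}`,
#' `Gh -> {M, Gh}` and `Gt -> Gt`.  `Iy -> Ix` is forbidden so that within a
#' mixed indel region template insertions always precede query insertions,
#' and `Gh -> Gt` is forbidden so that every alignment contains at least one
#' aligned pair.  The scores of `M -> Gt`, `Gh -> M`, `Gh -> Gh` and
#' `Gt -> Gt` are fixed at zero so head and tail gaps are unpenalized.
#'
#' @param score 5x5 numeric matrix of transition scores (rows = from state,
#'   columns = to state, in the order M, Ix, Iy, Gh, Gt).  Defaults to all
#'   zeros.  Entries at infeasible transitions must be zero, as must the four
#'   fixed-zero transitions above.
#' @param feasible 5x5 logical feasibility mask; defaults to the standard
#'   12-transition mask.
#' @return An object of class `transition_model` with elements `feasible`
#'   and `score`.
#' @examples
#' tm <- transition_model()
#' count_transitions(tm)
#' @export
transition_model <- function(score = NULL, feasible = NULL) {
  if (is.null(feasible)) feasible <- .default_feasible()
  stopifnot(is.matrix(feasible), dim(feasible) == c(5, 5))
  if (is.null(score)) score <- matrix(0, 5, 5)
  stopifnot(is.matrix(score), dim(score) == c(5, 5), all(is.finite(score)))
  dimnames(feasible) <- dimnames(score) <- list(ALIGN_STATES, ALIGN_STATES)
  if (any(score[!feasible] != 0))
    stop("transition scores must be 0 at infeasible transitions")
  if (any(score[.ZERO_SCORED] != 0))
    stop("scores of M->Gt, Gh->M, Gh->Gh and Gt->Gt are fixed at 0")
  structure(list(feasible = feasible, score = score),
            class = "transition_model")
}

#' Count feasible and forbidden transitions
#'
#' Enumerates the 25 ordered state pairs of a [transition_model()] and counts
#' how many are feasible and how many forbidden.  The default model has 12
#' feasible and 13 forbidden transitions.
#'
#' @param tm a [transition_model()].
#' @return Named integer vector `c(n_feasible =, n_forbidden =)`.
#' @export
count_transitions <- function(tm) {
  stopifnot(inherits(tm, "transition_model"))
  nf <- sum(tm$feasible)
  c(n_feasible = nf, n_forbidden = 25L - nf)
}

#' @export
print.transition_model <- function(x, ...) {
  ct <- count_transitions(x)
  cat("5-state alignment transition model:", ct[1], "feasible /",
      ct[2], "forbidden transitions\n")
  m <- ifelse(x$feasible, formatC(x$score, format = "g", digits = 4), ".")
  dimnames(m) <- dimnames(x$feasible)
  print(m, quote = FALSE)
  invisible(x)
}

## Expand a collapsed 5-state model to the 7 directional sub-states used by
## the DP and the validator.  Feasibility follows the collapsed mask plus the
## canonical directional orderings; scores are inherited from the collapsed
## pair (flank direction does not change the score).
expand_transitions <- function(tm) {
  f7 <- matrix(FALSE, 7, 7, dimnames = list(STATES7, STATES7))
  s7 <- matrix(0, 7, 7, dimnames = list(STATES7, STATES7))
  for (p in 1:7) for (q in 1:7) {
    ok <- tm$feasible[S7_TO_S5[p], S7_TO_S5[q]]
    if (p == 5L && q == 4L) ok <- FALSE # Hy -> Hx
    if (p == 7L && q == 6L) ok <- FALSE # Ty -> Tx
    f7[p, q] <- ok
    if (ok) s7[p, q] <- tm$score[S7_TO_S5[p], S7_TO_S5[q]]
  }
  list(feasible = f7, score = s7)
}
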