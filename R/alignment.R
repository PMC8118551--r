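#' Pairwise query-template alignment
#'
#' Constructs an alignment between a template of length `n1` and a query of
#' length `n2` as an ordered list of triples `(i, j, state)`.  Residue
#' indices are 0-based; `-1` marks the unconsumed side of an insertion or a
#' head/tail-gap triple.  A valid alignment consumes every template and query
#' position exactly once, contains at least one `M` (match) triple, and its
#' state sequence respects the transition feasibility mask (see
#' [transition_model()]); in particular, template-consuming gap steps precede
#' query-consuming ones within any indel region or flank, which makes the
#' representation canonical: a valid alignment is determined by its set of
#' matched pairs (see [alignment_from_pairs()]).
#'
#' @param triples data.frame with integer columns `i`, `j` and a character
#'   column `state` (values among `M`, `Ix`, `Iy`, `Gh`, `Gt`), one row per
#'   alignment step.
#' @param n1,n2 template and query lengths (residues).
#' @param validate check validity (default `TRUE`).
#' @param canonicalize if `TRUE`, rebuild the canonical triple ordering from
#'   the matched pairs before validating (repairs e.g. `Iy` before `Ix`).
#' @return Object of class `protein_alignment`: list with elements `triples`,
#'   `n1`, `n2`.
#' @seealso [alignment_from_pairs()], [aligned_pairs()], [evaluate_alignment()]
#' @export
alignment <- function(triples, n1, n2, validate = TRUE, canonicalize = FALSE) {
  triples <- as.data.frame(triples)
  stopifnot(all(c("i", "j", "state") %in% names(triples)))
  triples$i <- as.integer(triples$i)
  triples$j <- as.integer(triples$j)
  triples$state <- as.character(triples$state)
  rownames(triples) <- NULL
  a <- structure(list(triples = triples[c("i", "j", "state")],
                      n1 = as.integer(n1), n2 = as.integer(n2)),
                 class = "protein_alignment")
  if (canonicalize) {
    p <- a$triples[a$triples$state == "M", c("i", "j"), drop = FALSE]
    a <- alignment_from_pairs(as.matrix(p), n1, n2)
  }
  if (validate) validate_alignment(a)
  a
}

#' Canonical alignment from a set of matched pairs
#'
#' Every valid alignment is determined by its matched pairs: unmatched
#' template/query positions before the first match become head gaps, those
#' after the last match tail gaps, and interior runs become `Ix` then `Iy`
#' insertions (template side first).  This builds that canonical alignment.
#'
#' @param pairs two-column matrix of 0-based `(i, j)` matched positions,
#'   strictly increasing in both columns (any row order).
#' @param n1,n2 template and query lengths.
#' @return A valid `protein_alignment`.
#' @export
alignment_from_pairs <- function(pairs, n1, n2) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0L) stop("an alignment must contain at least one match")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) <= 0L))
    stop("matched pairs must be strictly increasing in both indices")
  if (pairs[1, 1] < 0L || pairs[nrow(pairs), 1] >= n1 ||
      pairs[1, 2] < 0L || pairs[nrow(pairs), 2] >= n2)
    stop("matched pair index out of range")
  ii <- integer(0); jj <- integer(0); ss <- character(0)
  emit <- function(ti, qj, st) {
    # template-consuming steps first, then query-consuming, then the match
    for (t in ti) { ii <<- c(ii, t); jj <<- c(jj, -1L); ss <<- c(ss, st) }
    for (q in qj) { ii <<- c(ii, -1L); jj <<- c(jj, q); ss <<- c(ss, st) }
  }
  prev <- c(-1L, -1L)
  for (r in seq_len(nrow(pairs))) {
    gap_t <- seq_len(pairs[r, 1] - prev[1] - 1L) + prev[1]
    gap_q <- seq_len(pairs[r, 2] - prev[2] - 1L) + prev[2]
    if (r == 1L) {
      emit(gap_t, gap_q, "Gh")
    } else {
      emit(gap_t, integer(0), "Ix")
      emit(integer(0), gap_q, "Iy")
    }
    ii <- c(ii, pairs[r, 1]); jj <- c(jj, pairs[r, 2]); ss <- c(ss, "M")
    prev <- pairs[r, ]
  }
  emit(seq_len(n1 - 1L - prev[1]) + prev[1],
       seq_len(n2 - 1L - prev[2]) + prev[2], "Gt")
  alignment(data.frame(i = ii, j = jj, state = ss), n1, n2, validate = FALSE)
}

## Map each triple to its directional internal state index (1..7).
triple_internal_states <- function(a) {
  st <- match(a$triples$state, ALIGN_STATES)
  s7 <- st # M, Ix, Iy keep indices 1..3
  s7[st == 4L] <- ifelse(a$triples$i[st == 4L] >= 0L, 4L, 5L)
  s7[st == 5L] <- ifelse(a$triples$i[st == 5L] >= 0L, 6L, 7L)
  s7
}

#' Validate an alignment
#'
#' Checks every structural invariant of the alignment representation and
#' stops with a message naming the first violated one.
#'
#' @param a a `protein_alignment`.
#' @param tm transition model giving the feasibility mask (default model).
#' @return `TRUE`, invisibly.
#' @export
validate_alignment <- function(a, tm = transition_model()) {
  tr <- a$triples
  fail <- function(msg) stop("invalid alignment: ", msg, call. = FALSE)
  if (nrow(tr) == 0L) fail("empty triple list")
  if (a$n1 < 1L || a$n2 < 1L) fail("protein lengths must be >= 1")
  if (!all(tr$state %in% ALIGN_STATES)) fail("unknown state label")
  isM <- tr$state == "M"
  if (!any(isM)) fail("no match state (>= 1 aligned pair required)")
  if (any(isM & (tr$i < 0L | tr$j < 0L)))
    fail("M triples must consume both proteins")
  one_sided <- !isM
  if (any(one_sided & ((tr$i >= 0L) == (tr$j >= 0L))))
    fail("non-match triples must consume exactly one protein (-1 on the other side)")
  if (any(tr$state == "Ix" & tr$i < 0L) || any(tr$state == "Iy" & tr$j < 0L))
    fail("Ix consumes template only; Iy consumes query only")
  ti <- tr$i[tr$i >= 0L]
  qj <- tr$j[tr$j >= 0L]
  if (any(ti >= a$n1) || any(qj >= a$n2)) fail("residue index out of range")
  if (!identical(ti, seq_len(a$n1) - 1L))
    fail("template positions must each be consumed exactly once, in order")
  if (!identical(qj, seq_len(a$n2) - 1L))
    fail("query positions must each be consumed exactly once, in order")
  ex <- expand_transitions(tm)
  s7 <- triple_internal_states(a)
  if (!s7[1] %in% START7) fail("alignment must start in M or a head gap")
  if (!s7[length(s7)] %in% END7) fail("alignment must end in M or a tail gap")
  if (length(s7) > 1L) {
    ok <- ex$feasible[cbind(s7[-length(s7)], s7[-1])]
    if (!all(ok)) {
      k <- which(!ok)[1]
      fail(sprintf("infeasible transition %s -> %s at step %d",
                   STATES7[s7[k]], STATES7[s7[k + 1]], k))
    }
  }
  invisible(TRUE)
}

#' Matched pairs of an alignment
#'
#' @param a a `protein_alignment`.
#' @return Integer matrix with columns `i`, `j`: the 0-based positions of all
#'   `M` triples, in alignment order.
#' @export
aligned_pairs <- function(a) {
  m <- a$triples[a$triples$state == "M", c("i", "j"), drop = FALSE]
  matrix(c(m$i, m$j), ncol = 2, dimnames = list(NULL, c("i", "j")))
}

#' Binary-variable representation of an alignment
#'
#' Encodes an alignment as the indicator array `z[i, j, u]` over
#' `i = -1..n1-1`, `j = -1..n2-1` and the five states (the interior holds the
#' `5*N1*N2` binary variables of the CRF formulation; the `-1` slices carry
#' the gap/insertion triples).  Exactly one indicator is set per triple.
#'
#' @param a a valid `protein_alignment`.
#' @return 0/1 array of dimension `(n1+1) x (n2+1) x 5` with dimnames giving
#'   the 0-based indices (`"-1"` first) and state labels.
#' @seealso [matrix_to_triples()]
#' @export
triples_to_matrix <- function(a) {
  validate_alignment(a)
  z <- array(0L, dim = c(a$n1 + 1L, a$n2 + 1L, 5L),
             dimnames = list(as.character(-1:(a$n1 - 1L)),
                             as.character(-1:(a$n2 - 1L)), ALIGN_STATES))
  idx <- cbind(a$triples$i + 2L, a$triples$j + 2L,
               match(a$triples$state, ALIGN_STATES))
  z[idx] <- 1L
  z
}

#' Reconstruct an alignment from its binary-variable representation
#'
#' Inverse of [triples_to_matrix()].  The indicator set must encode a single
#' connected, canonical alignment path; anything else (no match state, stray
#' or missing indicators) is a structure error.
#'
#' @param z 0/1 array of dimension `(n1+1) x (n2+1) x 5`.
#' @return A valid `protein_alignment`.
#' @export
matrix_to_triples <- function(z) {
  stopifnot(length(dim(z)) == 3L, dim(z)[3] == 5L)
  n1 <- dim(z)[1] - 1L
  n2 <- dim(z)[2] - 1L
  mm <- which(z[, , 1] != 0, arr.ind = TRUE)
  mm <- mm[mm[, 1] > 1L & mm[, 2] > 1L, , drop = FALSE]
  if (nrow(mm) == 0L) stop("matrix encodes no match state")
  a <- alignment_from_pairs(mm - 2L, n1, n2)
  if (!identical(unname(triples_to_matrix(a) != 0), unname(z != 0)))
    stop("indicator set is not a single canonical alignment path")
  a
}

#' Path representation of an alignment
#'
#' The path through the `(n1+1) x (n2+1)` alignment grid: the cumulative
#' number of template and query residues consumed after each triple.
#'
#' @param a a valid `protein_alignment`.
#' @return Integer matrix with columns `i`, `j` (one row per triple).
#' @export
triples_to_path <- function(a) {
  validate_alignment(a)
  s7 <- triple_internal_states(a)
  cbind(i = cumsum(DX7[s7]), j = cumsum(DY7[s7]))
}

#' Alignment from its grid path
#'
#' Inverse of [triples_to_path()].  Each step's consumption pattern plus its
#' position relative to the first/last diagonal step determines the state.
#'
#' @param path integer matrix of cumulative `(i, j)` positions.
#' @param n1,n2 protein lengths.
#' @return A valid `protein_alignment`.
#' @export
path_to_triples <- function(path, n1, n2) {
  path <- rbind(c(0L, 0L), matrix(as.integer(path), ncol = 2))
  d <- diff(path)
  if (any(!d %in% 0:1) || any(rowSums(d) == 0L))
    stop("each path step must consume one or two residues")
  diag_steps <- which(d[, 1] == 1L & d[, 2] == 1L)
  if (length(diag_steps) == 0L) stop("path has no match step")
  first_m <- min(diag_steps); last_m <- max(diag_steps)
  n <- nrow(d)
  state <- character(n); ii <- integer(n); jj <- integer(n)
  for (k in seq_len(n)) {
    if (d[k, 1] == 1L && d[k, 2] == 1L) {
      state[k] <- "M"; ii[k] <- path[k + 1L, 1] - 1L; jj[k] <- path[k + 1L, 2] - 1L
    } else if (d[k, 1] == 1L) {
      state[k] <- if (k < first_m) "Gh" else if (k > last_m) "Gt" else "Ix"
      ii[k] <- path[k + 1L, 1] - 1L; jj[k] <- -1L
    } else {
      state[k] <- if (k < first_m) "Gh" else if (k > last_m) "Gt" else "Iy"
      ii[k] <- -1L; jj[k] <- path[k + 1L, 2] - 1L
    }
  }
  alignment(data.frame(i = ii, j = jj, state = state), n1, n2)
}

#' Collapsed state string of an alignment
#'
#' One letter per triple: `M`, `X` (`Ix`), `Y` (`Iy`), `H` (`Gh`), `T`
#' (`Gt`).  The state string alone does not record which protein a flanking
#' gap consumes; the three-line text format (see [write_alignment()]) is the
#' lossless form.
#'
#' @param a a `protein_alignment`.
#' @return A single string of length `nrow(a$triples)`.
#' @export
as_state_string <- function(a) {
  paste(c(M = "M", Ix = "X", Iy = "Y", Gh = "H", Gt = "T")[a$triples$state],
        collapse = "")
}

#' Reference-dependent alignment accuracy
#'
#' Compares the matched pairs of a predicted alignment against a reference
#' alignment of the same two proteins.  Precision is the fraction of
#' predicted pairs that occur in the reference; recall is the fraction of
#' reference pairs recovered.
#'
#' @param pred,ref `protein_alignment` objects over the same `n1`, `n2`.
#' @return Object of class `align_eval`: list with `precision`, `recall`,
#'   `n_pred_pairs`, `n_ref_pairs`, `n_correct`.
#' @export
evaluate_alignment <- function(pred, ref) {
  if (pred$n1 != ref$n1 || pred$n2 != ref$n2)
    stop("pred and ref must align proteins of the same lengths")
  pp <- aligned_pairs(pred); rp <- aligned_pairs(ref)
  key <- function(p) paste(p[, 1], p[, 2])
  nc <- sum(key(pp) %in% key(rp))
  structure(list(precision = nc / nrow(pp), recall = nc / nrow(rp),
                 n_pred_pairs = nrow(pp), n_ref_pairs = nrow(rp),
                 n_correct = nc),
            class = "align_eval")
}

#' @export
print.align_eval <- function(x, ...) {
  cat(sprintf("alignment accuracy: precision %.4f (%d/%d), recall %.4f (%d/%d)\n",
              x$precision, x$n_correct, x$n_pred_pairs,
              x$recall, x$n_correct, x$n_ref_pairs))
  invisible(x)
}

#' @export
print.protein_alignment <- function(x, ...) {
  np <- sum(x$triples$state == "M")
  cat(sprintf("pairwise alignment: template %d aa, query %d aa, %d steps, %d matched pairs\n",
              x$n1, x$n2, nrow(x$triples), np))
  cat(" states:", as_state_string(x), "\n")
  invisible(x)
}
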