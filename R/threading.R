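## Cross-term map: C(i, j) = sum over matched pairs (k, l) of zmat of the
## pair score theta_ijkl^MM.  With z a valid alignment's indicator matrix,
## sum(C * z) = 2 * S_pairwise (each unordered pair counted twice).
.cross_map <- function(pot, tbins, zmat) {
  out <- matrix(0, nrow(zmat), ncol(zmat))
  if (is.null(pot)) return(out)
  idx <- which(zmat != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    out <- out + .pair_score_matrix(pot, tbins, idx[r, 1], idx[r, 2])
  out
}

.zmat <- function(a) {
  z <- matrix(0, a$n1, a$n2)
  z[aligned_pairs(a) + 1L] <- 1
  z
}

## Viterbi on a score table whose M slice is replaced by `m` and whose other
## slices are scaled by `w2` (the split singleton weight).
.aug_viterbi <- function(theta, m, w2, tm) {
  th <- theta$theta * w2
  th[, , 1] <- m
  viterbi(score_table(th), tm)$alignment
}

#' ADMM improvement of an alignment under the threading objective
#'
#' Maximizes the distance-augmented threading objective
#' `S = w * S_singleton + S_pairwise` (see [threading_objective()]), which is
#' quadratic in the match indicators and NP-hard to optimize exactly, by the
#' alternating direction method of multipliers.  The alignment variables are
#' duplicated into two copies tied by a consensus constraint; each copy's
#' subproblem is a singleton-only alignment exactly solvable by [viterbi()]
#' with augmented match scores (the quadratic term linearized against the
#' other copy, plus scaled dual and proximity terms), and the scaled dual is
#' updated from the consensus residual.  The procedure is a heuristic: it
#' may stop in a local optimum, so with `keep_best` (default) the
#' best-objective valid alignment encountered — including the initial one —
#' is returned, and the returned objective is never below the initial
#' alignment's.
#'
#' @param theta a [score_table()] of singleton scores.
#' @param pot a [dfire_potential()] over query pairs (`NULL` for a pure
#'   singleton problem).
#' @param tbins a [template_distance_bins()] matrix.
#' @param init a valid initial `protein_alignment` (e.g. the Viterbi
#'   alignment of `theta`).
#' @param w singleton weight (default 1; use e.g. 20 for easy targets).
#' @param rho ADMM penalty parameter (> 0, default 0.5).
#' @param max_iter iteration cap (default 20).
#' @param tol unused numerical slack reserved for residual-based stopping;
#'   iteration stops when the two copies agree exactly.
#' @param keep_best return the best-objective alignment seen (default) rather
#'   than the final consensus.
#' @param tm a [transition_model()].
#' @return List with `alignment`, `objective` (a [threading_objective()]),
#'   `trace` (per-iteration objectives and primal residual), `converged`,
#'   `iterations`.
#' @export
admm_align <- function(theta, pot, tbins, init, w = 1, rho = 0.5,
                       max_iter = 20L, tol = 1e-6, keep_best = TRUE,
                       tm = transition_model()) {
  stopifnot(inherits(theta, "score_table"), rho > 0, max_iter >= 1)
  validate_alignment(init, tm)
  obj <- function(a) threading_objective(a, theta, pot, tbins, w)
  best_a <- init
  best <- obj(init)
  y <- .zmat(init)
  lambda <- matrix(0, theta$n1, theta$n2)
  thM <- theta$theta[, , 1]
  trace <- NULL
  converged <- FALSE
  it <- 0L
  consider <- function(a) {
    o <- obj(a)
    if (o$s_total > best$s_total + 1e-12) { best <<- o; best_a <<- a }
    o
  }
  for (it in seq_len(max_iter)) {
    ## z-step: the first iteration omits the proximal terms, so with a zero
    ## potential it reduces to plain Viterbi decoding of theta
    mz <- 0.5 * w * thM + 0.5 * .cross_map(pot, tbins, y)
    if (it > 1L) mz <- mz + lambda + rho * (y - 0.5)
    za <- .aug_viterbi(theta, mz, 0.5 * w, tm)
    z <- .zmat(za)
    oz <- consider(za)
    ## y-step
    my <- 0.5 * w * thM + 0.5 * .cross_map(pot, tbins, z) -
      lambda + rho * (z - 0.5)
    ya <- .aug_viterbi(theta, my, 0.5 * w, tm)
    y <- .zmat(ya)
    oy <- consider(ya)
    primal <- sum(abs(z - y))
    trace <- rbind(trace, data.frame(iter = it, obj_z = oz$s_total,
                                     obj_y = oy$s_total, primal = primal,
                                     best = best$s_total))
    if (primal == 0) { converged <- TRUE; break }
    lambda <- lambda - rho * (z - y)
  }
  out_a <- if (keep_best) best_a else za
  list(alignment = out_a, objective = if (keep_best) best else obj(za),
       trace = trace, converged = converged, iterations = it)
}

#' Multi-start ADMM threading
#'
#' Generates one initial alignment per supplied score table by Viterbi
#' decoding, improves each with [admm_align()] under a designated primary
#' score table, and returns the best final alignment by the threading
#' objective.  Mirrors the recipe of initializing from several differently
#' trained scorers to escape local optima of the ADMM heuristic.
#'
#' @param theta_list list of [score_table()]s (typically 4); element
#'   `primary` supplies the singleton scores of the objective.
#' @param pot,tbins,w,rho,max_iter,keep_best,tm as in [admm_align()].
#' @param primary index of the primary score table (default 1).
#' @return List with `alignment`, `objective`, `start` (winning start index)
#'   and `per_start` objectives.
#' @export
multistart_align <- function(theta_list, pot, tbins, w = 1, rho = 0.5,
                             max_iter = 20L, keep_best = TRUE, primary = 1L,
                             tm = transition_model()) {
  stopifnot(length(theta_list) >= 1L)
  main <- theta_list[[primary]]
  best <- NULL
  per <- numeric(length(theta_list))
  for (s in seq_along(theta_list)) {
    init <- viterbi(theta_list[[s]], tm)$alignment
    r <- admm_align(main, pot, tbins, init, w = w, rho = rho,
                    max_iter = max_iter, keep_best = keep_best, tm = tm)
    per[s] <- r$objective$s_total
    if (is.null(best) || r$objective$s_total > best$objective$s_total)
      best <- c(r[c("alignment", "objective")], list(start = s))
  }
  c(best, list(per_start = per))
}

#' Template selection score
#'
#' Scores an alignment for template ranking:
#' `SelectionScore = w1 * S_singleton + S_pairwise + w2 * S_norm`, where
#' `S_norm` is the pairwise score normalized by the number of aligned
#' positions.  The normalized term emphasizes per-position alignment quality
#' over sheer alignment length.  Defaults `w1 = 1` (raise to e.g. 20 for
#' easy targets) and `w2 = 5`.
#'
#' @param a a valid `protein_alignment`.
#' @param theta a [score_table()].
#' @param pot a [dfire_potential()] or `NULL` (pairwise terms 0).
#' @param tbins a [template_distance_bins()] matrix (with `pot`).
#' @param w1,w2 weights.
#' @return Object of class `selection_result`: list with `score`,
#'   `s_singleton`, `s_pairwise`, `s_norm`, `n_aligned`, `w1`, `w2`.
#' @export
selection_score <- function(a, theta, pot = NULL, tbins = NULL,
                            w1 = 1, w2 = 5) {
  o <- threading_objective(a, theta, pot, tbins, w = 1)
  n_aligned <- nrow(aligned_pairs(a))
  s_norm <- o$s_pairwise / n_aligned
  structure(list(score = w1 * o$s_singleton + o$s_pairwise + w2 * s_norm,
                 s_singleton = o$s_singleton, s_pairwise = o$s_pairwise,
                 s_norm = s_norm, n_aligned = n_aligned, w1 = w1, w2 = w2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection score %.4f (w1 %.3g * singleton %.4f + pairwise %.4f + w2 %.3g * norm %.4f; %d aligned)\n",
              x$score, x$w1, x$s_singleton, x$s_pairwise, x$w2, x$s_norm,
              x$n_aligned))
  invisible(x)
}

#' Rank candidate templates for a query
#'
#' Aligns the query to every template (Viterbi under the fitted scorer; in
#' `"distance"` mode the alignment is further improved by [admm_align()]
#' with the query's distance potential) and sorts the templates by
#' [selection_score()], descending.  Ties are broken by higher singleton
#' score, then template id.
#'
#' @param query a [query_record()].
#' @param templates named list of [template_record()]s.
#' @param scorer a `crf_scorer` from [train_mle()], or a function
#'   `(query, template) -> score_table`.
#' @param mode `"singleton"` (sequence-only) or `"distance"`.
#' @param pot a [dfire_potential()] for the query (required in distance
#'   mode; in singleton mode, if supplied, it still enters the selection
#'   score's pairwise terms).
#' @param w,w1,w2,rho,max_iter tuning parameters (see [admm_align()] and
#'   [selection_score()]).
#' @param top_k truncate the report to the best `k` templates.
#' @param tm a [transition_model()].
#' @return Object of class `template_ranking`: list with `table` (a
#'   data.frame of scores, best first) and `alignments`.
#' @export
rank_templates <- function(query, templates, scorer,
                           mode = c("singleton", "distance"), pot = NULL,
                           w = 1, w1 = 1, w2 = 5, rho = 0.5, max_iter = 20L,
                           top_k = NULL, tm = transition_model()) {
  mode <- match.arg(mode)
  if (length(templates) == 0L) stop("empty template list")
  if (is.null(names(templates)) || any(!nzchar(names(templates))))
    stop("templates must be a named list")
  if (mode == "distance" && is.null(pot))
    stop("distance mode requires a distance potential")
  theta_of <- if (inherits(scorer, "crf_scorer"))
    function(q, t) emission_scores(scorer, q, t) else scorer
  rows <- list(); alns <- list()
  for (id in names(templates)) {
    t <- templates[[id]]
    theta <- theta_of(query, t)
    tbins <- template_distance_bins(t$dist)
    a <- viterbi(theta, tm)$alignment
    if (mode == "distance")
      a <- admm_align(theta, pot, tbins, a, w = w, rho = rho,
                      max_iter = max_iter, tm = tm)$alignment
    sel <- selection_score(a, theta, pot, tbins, w1 = w1, w2 = w2)
    rows[[id]] <- data.frame(template = id, score = sel$score,
                             s_singleton = sel$s_singleton,
                             s_pairwise = sel$s_pairwise, s_norm = sel$s_norm,
                             n_aligned = sel$n_aligned)
    alns[[id]] <- a
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$score, -tab$s_singleton, tab$template)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  if (!is.null(top_k)) tab <- tab[seq_len(min(top_k, nrow(tab))), , drop = FALSE]
  structure(list(table = tab, alignments = alns[tab$template], mode = mode),
            class = "template_ranking")
}

#' @export
print.template_ranking <- function(x, ...) {
  cat("template ranking (", x$mode, " mode):\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
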