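#' Build the input channels of the alignment refiner
#'
#' The refiner consumes three `n1 x n2` maps: the initial alignment as a
#' binary match-indicator matrix, the emission match scores `theta(i, j, M)`,
#' and the distance-potential score map, whose `(i, j)` entry sums the pair
#' scores `theta_ijkl^MM` over all matched pairs `(k, l)` of the initial
#' alignment with template residue `k` within 16 Angstrom of `i` (i.e. not in
#' the last distance bin), excluding the self pair `k == i`.
#'
#' @param init a valid `protein_alignment` (the alignment to refine).
#' @param theta a [score_table()].
#' @param pot a [dfire_potential()] over query pairs.
#' @param tbins a [template_distance_bins()] matrix.
#' @return Object of class `refiner_input`: list with `align`, `theta_m`,
#'   `potential` (each `n1 x n2`).
#' @export
build_refiner_input <- function(init, theta, pot, tbins) {
  validate_alignment(init)
  stopifnot(inherits(theta, "score_table"),
            inherits(pot, "distance_potential"),
            inherits(tbins, "template_distance_bins"))
  n1 <- theta$n1; n2 <- theta$n2
  stopifnot(init$n1 == n1, init$n2 == n2, nrow(tbins) == n1,
            dim(pot$u)[1] == n2)
  z <- matrix(0, n1, n2)
  z[aligned_pairs(init) + 1L] <- 1
  potmap <- matrix(0, n1, n2)
  ap <- aligned_pairs(init) + 1L
  for (r in seq_len(nrow(ap)))
    potmap <- potmap + .pair_score_matrix(pot, tbins, ap[r, 1], ap[r, 2])
  structure(list(align = z, theta_m = theta$theta[, , 1], potential = potmap),
            class = "refiner_input")
}

#' @export
print.refiner_input <- function(x, ...) {
  cat(sprintf("refiner input: %d x %d cells, %d initial matches, potential in [%.3g, %.3g]\n",
              nrow(x$align), ncol(x$align), sum(x$align),
              min(x$potential), max(x$potential)))
  invisible(x)
}

#' Initialize refiner parameters
#'
#' The refiner is a 2D residual network (same block structure as the 2D
#' stage of [drnf_score()]) over the three [build_refiner_input()] channels.
#'
#' @param config a [drnf_config()] (only the 2D fields are used).
#' @param seed integer seed.
#' @return Object of class `refiner_params`.
#' @export
refiner_init <- function(config = drnf_config(), seed = 1L) {
  with_seed(.mix_seed(seed, 47), {
    n_out <- if (config$emit_gap_scores) 3L else 1L
    p <- list(net2d = .build_net2d(config, 3L, n_out),
              gap = c(gap_ix = 0, gap_iy = 0))
    attr(p, "config") <- config
    class(p) <- "refiner_params"
    p
  })
}

#' Re-score an alignment problem from refiner inputs
#'
#' Integrates the initial alignment, the singleton scores and the
#' distance-potential map through the refiner network into a new emission
#' score table, to be decoded by [viterbi()] (or [maxacc_decode()]).
#'
#' @param input a [build_refiner_input()] object.
#' @param params a [refiner_init()] parameter set.
#' @return A [score_table()].
#' @export
refine_alignment <- function(input, params) {
  stopifnot(inherits(input, "refiner_input"), inherits(params, "refiner_params"))
  cfg <- attr(params, "config")
  n1 <- nrow(input$align); n2 <- ncol(input$align)
  a <- array(0, c(3L, n1, n2))
  a[1, , ] <- input$align
  a[2, , ] <- input$theta_m
  a[3, , ] <- input$potential
  z <- net_forward(params$net2d, a)$out
  if (cfg$emit_gap_scores) {
    theta <- score_table(matrix(z[1, , ], n1, n2))
    theta$theta[, , 2] <- z[2, , ]
    theta$theta[, , 3] <- z[3, , ]
    theta
  } else {
    score_table(matrix(z[1, , ], n1, n2),
                gap_ix = params$gap[1], gap_iy = params$gap[2])
  }
}
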