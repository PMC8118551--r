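# Shared helpers: tiny random instances and brute-force oracles that stay
# independent of the dynamic-programming code paths they check.

random_score_table <- function(n1, n2, sd = 1) {
  score_table(array(stats::rnorm(n1 * n2 * 5, sd = sd), c(n1, n2, 5)))
}

# Random DFIRE-style potential and template bins for Eq-style objectives.
random_distance_instance <- function(n1, n2, sd = 1) {
  u <- array(stats::rnorm(n2 * n2 * 14, sd = sd), c(n2, n2, 14))
  for (b in 1:14) u[, , b] <- (u[, , b] + t(u[, , b])) / 2
  pot <- structure(list(u = u, alpha = 1.61, clip = 10,
                        p_ref = rep(1 / 14, 14)),
                   class = "distance_potential")
  d <- matrix(stats::runif(n1 * n1, 3, 20), n1, n1)
  d <- (d + t(d)) / 2; diag(d) <- 0
  list(pot = pot, tbins = template_distance_bins(d))
}

# Brute-force threading objective from first principles (independent of
# pairwise_score / threading_objective).
brute_objective <- function(a, theta, pot, tbins, w = 1) {
  s1 <- score_alignment(a, theta, transition_model())
  ap <- aligned_pairs(a) + 1L
  s2 <- 0
  if (nrow(ap) > 1L)
    for (r in 1:(nrow(ap) - 1L)) for (s in (r + 1L):nrow(ap)) {
      b <- tbins[ap[r, 1], ap[s, 1]]
      if (b < 14L) s2 <- s2 - pot$u[ap[r, 2], ap[s, 2], b]
    }
  w * s1 + s2
}

# Exhaustive optimum of the threading objective over all valid alignments.
brute_best_objective <- function(theta, pot, tbins, w = 1) {
  alns <- enumerate_alignments(theta$n1, theta$n2)
  max(vapply(alns, brute_objective, 0, theta = theta, pot = pot,
             tbins = tbins, w = w))
}

# Naive re-implementation of the layer engine (direct loops), used as an
# independent oracle for the vectorized network forward pass.
naive_net_forward <- function(ops, x) {
  stack <- list()
  for (op in ops) {
    if (op$kind == "conv") {
      W <- op$W
      if (length(dim(W)) == 3L) {
        k <- dim(W)[3]; half <- (k - 1) / 2
        n <- ncol(x)
        out <- matrix(0, dim(W)[1], n)
        for (co in seq_len(dim(W)[1])) for (t in seq_len(n)) {
          acc <- op$b[co]
          for (ci in seq_len(dim(W)[2])) for (o in seq_len(k)) {
            s <- t + o - 1 - half
            if (s >= 1 && s <= n) acc <- acc + W[co, ci, o] * x[ci, s]
          }
          out[co, t] <- acc
        }
        x <- out
      } else {
        k <- dim(W)[3]; half <- (k - 1) / 2
        d <- dim(x)
        out <- array(0, c(dim(W)[1], d[2], d[3]))
        for (co in seq_len(dim(W)[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
          acc <- op$b[co]
          for (ci in seq_len(d[1])) for (ox in seq_len(k)) for (oy in seq_len(k)) {
            si <- i + ox - 1 - half; sj <- j + oy - 1 - half
            if (si >= 1 && si <= d[2] && sj >= 1 && sj <= d[3])
              acc <- acc + W[co, ci, ox, oy] * x[ci, si, sj]
          }
          out[co, i, j] <- acc
        }
        x <- out
      }
    } else if (op$kind == "inorm") {
      d <- dim(x); xm <- matrix(x, d[1])
      for (c in seq_len(d[1])) {
        mu <- mean(xm[c, ]); v <- mean((xm[c, ] - mu)^2)
        xm[c, ] <- op$g[c] * (xm[c, ] - mu) / sqrt(v + 1e-5) + op$be[c]
      }
      x <- array(xm, d)
    } else if (op$kind == "relu") {
      x <- pmax(x, 0)
    } else if (op$kind == "skip+") {
      stack[[length(stack) + 1L]] <- x
    } else if (op$kind == "skip-") {
      x <- x + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    }
  }
  x
}

tiny_drnf_config <- function(...) {
  drnf_config(conv1d_layers = 3L, res2d_blocks = 1L, width1d = 4L,
              width2d = 6L, init_sd = 0.05, ...)
}

# A small training/evaluation corpus of fixtures.
fixture_corpus <- function(n, lengths = 18:30, mutation = 0.2, indel = 0.06,
                           noise = 0.05, seed_base = 0) {
  lapply(seq_len(n), function(k) {
    len <- with_seed(seed_base + 11 * k, sample(lengths, 1))
    make_pair(sample_fold(len, seed = seed_base + 9000 + k),
              mutation_rate = mutation, indel_rate = indel, noise = noise,
              seed = seed_base + 100 + k)
  })
}

cli_script <- function() {
  p <- system.file("cli", "threadcrf.R", package = "threadcrf")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  # the child process must see the same library paths as this session
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(system2(rscript, c(cli_script(), ...),
                                  stdout = TRUE, stderr = TRUE, env = libs))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
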