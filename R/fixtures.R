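#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded generators never perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.mix_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + salt) %% 2147483647)
}

## Ideal helix step geometry: radius 2.3 A, rise 1.5 A, 100 degrees per
## residue gives consecutive Cbeta-like spacing of ~3.83 A.
.helix_points <- function(n, origin, frame, phase = 0) {
  r <- 2.3; rise <- 1.5; step <- 100 * pi / 180
  ang <- phase + step * (seq_len(n) - 1L)
  local <- cbind(r * cos(ang) - r * cos(phase),
                 r * sin(ang) - r * sin(phase),
                 rise * (seq_len(n) - 1L))
  sweep(local %*% t(frame), 2, origin, "+")
}

.random_frame <- function() {
  repeat {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    a <- a / sqrt(sum(a^2))
    b <- b - sum(a * b) * a
    nb <- sqrt(sum(b^2))
    if (nb > 1e-6) break
  }
  b <- b / nb
  cbind(a, b, .cross(a, b)) # columns: local x, y, z axes
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Sample a toy protein fold
#'
#' Generates a self-avoiding chain of Cbeta-like coordinates as a series of
#' short ideal-helix segments joined by 3.8-Angstrom bonds in directions
#' biased toward the current centroid (compactness).  Invariants: every
#' consecutive distance lies in `[3.6, 4.0]` Angstrom and no two
#' non-consecutive residues come closer than 3.5 Angstrom.  Deterministic per
#' seed.
#'
#' @param n chain length (`>= 2`).
#' @param seed integer seed.
#' @return Object of class `toy_fold`: list with `coords` (`n x 3`) and
#'   `seed`.
#' @export
sample_fold <- function(n, seed) {
  if (n < 2L) stop("fold length must be >= 2")
  for (attempt in 0:199) {
    coords <- with_seed(.mix_seed(seed, attempt), .try_fold(n))
    if (!is.null(coords))
      return(structure(list(coords = coords, seed = seed), class = "toy_fold"))
  }
  stop("failed to sample a clash-free fold") # practically unreachable
}

.try_fold <- function(n) {
  coords <- .helix_points(min(n, sample(6:12, 1)), c(0, 0, 0), .random_frame())
  while (nrow(coords) < n) {
    seg_len <- min(n - nrow(coords), sample(6:12, 1))
    placed <- FALSE
    for (k in 1:30) {
      dir <- stats::rnorm(3)
      centroid_pull <- colMeans(coords) - coords[nrow(coords), ]
      ncp <- sqrt(sum(centroid_pull^2))
      if (ncp > 1e-6) dir <- dir + 1.2 * centroid_pull / ncp
      dir <- dir / sqrt(sum(dir^2))
      origin <- coords[nrow(coords), ] + 3.8 * dir
      seg <- .helix_points(seg_len, origin, .random_frame())
      cand <- rbind(coords, seg)
      if (.fold_ok(cand, nrow(coords))) { coords <- cand; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  if (.fold_ok(coords, 0L)) coords else NULL
}

.fold_ok <- function(coords, from) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  consec <- d[cbind(1:(n - 1), 2:n)]
  if (any(consec < 3.6 | consec > 4.0)) return(FALSE)
  d[cbind(1:(n - 1), 2:n)] <- Inf
  d[cbind(2:n, 1:(n - 1))] <- Inf
  diag(d) <- Inf
  min(d) >= 3.5
}

#' @export
print.toy_fold <- function(x, ...) {
  cat(sprintf("toy fold: %d residues (seed %d)\n", nrow(x$coords), x$seed))
  invisible(x)
}

## Geometry-derived labels shared by fixture templates and queries.
.geom_ss3 <- function(coords) {
  n <- nrow(coords)
  lab <- rep("C", n)
  if (n >= 3) {
    d13 <- sqrt(rowSums((coords[3:n, , drop = FALSE] -
                           coords[1:(n - 2), , drop = FALSE])^2))
    mid <- 2:(n - 1)
    lab[mid][d13 < 6.0] <- "H"
    lab[mid][d13 > 6.8] <- "E"
  }
  lab
}

.geom_acc <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  cnt <- vapply(seq_len(n), function(i) {
    sum(d[i, ] < 10 & abs(seq_len(n) - i) >= 2)
  }, 0L)
  pmin(1, pmax(0, 1 - cnt / 12))
}

.blend_onehot <- function(labels, levels, noise) {
  m <- matrix(noise / length(levels), length(labels), length(levels))
  m[cbind(seq_along(labels), match(labels, levels))] <-
    1 - noise + noise / length(levels)
  m
}

.query_pssm <- function(psfm) {
  bg <- 1 / 20
  log2((0.9 * psfm + 0.1 * bg) / bg)
}

#' Synthesize a query-template pair with a known reference alignment
#'
#' The template takes the fold's coordinates and a random sequence.  The
#' query is derived by point mutations (rate `mutation_rate` on matched
#' positions) and insertions/deletions (each at rate `indel_rate / 2`), with
#' the generative correspondence recorded as the reference alignment.
#' Matched query residues inherit the template coordinates (a conserved
#' fold); inserted residues are placed near the chain between their
#' neighbours.  The query's predicted inputs emulate upstream predictors:
#' its profile is the one-hot sequence blended toward background by `noise`,
#' secondary structure and accessibility are geometry-derived labels blended
#' by `noise`, and the predicted distance distribution is the one-hot of the
#' query's true self-distance bins smoothed by `noise` toward uniform (so
#' `noise = 0` gives exact one-hot distributions).
#'
#' @param fold a [sample_fold()] result.
#' @param mutation_rate,indel_rate rates in `[0, 1)`.
#' @param noise predictor-error level in `[0, 1)`.
#' @param seed integer seed.
#' @param ref_style `"A"` keeps every generative matched pair; `"B"` emulates
#'   a more conservative reference aligner by trimming the outermost matched
#'   pair at each end (when more than four matches exist).
#' @return Object of class `pair_fixture`: list with `query`
#'   ([query_record()]), `template` ([template_record()]), `reference`
#'   (`protein_alignment`), `dist_pred` (`n2 x n2 x 14` array), the rates and
#'   the seed.
#' @export
make_pair <- function(fold, mutation_rate = 0.2, indel_rate = 0.05,
                      noise = 0.05, seed = 1L, ref_style = c("A", "B")) {
  stopifnot(inherits(fold, "toy_fold"),
            mutation_rate >= 0, mutation_rate < 1,
            indel_rate >= 0, indel_rate < 1, noise >= 0, noise < 1)
  ref_style <- match.arg(ref_style)
  with_seed(.mix_seed(seed, 577), {
    n1 <- nrow(fold$coords)
    tseq <- sample(AA20, n1, replace = TRUE)
    ## generative correspondence
    qseq <- character(0)
    qpos_coord <- list()
    pairs <- NULL
    push_insert <- function(anchor) {
      qseq <<- c(qseq, sample(AA20, 1))
      qpos_coord[[length(qseq)]] <<- anchor + stats::rnorm(3, sd = 1.2)
    }
    for (i in seq_len(n1)) {
      if (stats::runif(1) < indel_rate / 2) next # deletion: template-only
      res <- tseq[i]
      if (stats::runif(1) < mutation_rate)
        res <- sample(setdiff(AA20, res), 1)
      qseq <- c(qseq, res)
      qpos_coord[[length(qseq)]] <- fold$coords[i, ]
      pairs <- rbind(pairs, c(i - 1L, length(qseq) - 1L))
      if (stats::runif(1) < indel_rate / 2)
        push_insert(fold$coords[i, ])
    }
    if (is.null(pairs)) { # degenerate: force one match
      i <- ceiling(n1 / 2)
      qseq <- tseq[i]
      qpos_coord <- list(fold$coords[i, ])
      pairs <- matrix(c(i - 1L, 0L), 1)
    }
    n2 <- length(qseq)
    qcoords <- do.call(rbind, qpos_coord)
    ref_pairs <- pairs
    if (ref_style == "B" && nrow(ref_pairs) > 4L)
      ref_pairs <- ref_pairs[-c(1L, nrow(ref_pairs)), , drop = FALSE]
    reference <- alignment_from_pairs(ref_pairs, n1, n2)
    ## template record from geometry
    ss3_t <- .geom_ss3(fold$coords)
    ss8_t <- ss3_t # H/E/C are shared letters of the 8-class alphabet
    template <- template_record(paste(tseq, collapse = ""), fold$coords,
                                ss3 = ss3_t, ss8 = ss8_t,
                                acc = .geom_acc(fold$coords))
    ## query predicted inputs
    psfm <- .blend_onehot(qseq, AA20, noise)
    ss3_q <- .geom_ss3(qcoords)
    acc_q <- acc_class(.geom_acc(qcoords))
    query <- query_record(paste(qseq, collapse = ""),
                          psfm = psfm, pssm = .query_pssm(psfm),
                          ss3 = .blend_onehot(ss3_q, SS3_LABELS, noise),
                          ss8 = .blend_onehot(ss3_q, SS8_LABELS, noise),
                          acc = .blend_onehot(acc_q, ACC_LABELS, noise))
    ## predicted distance distribution: smoothed one-hot of true bins
    nb <- distance_bins()$n_bins
    qbins <- discretize_distance(as.matrix(stats::dist(qcoords)))
    dist_pred <- array(noise / nb, dim = c(n2, n2, nb))
    hit <- cbind(rep(seq_len(n2), n2), rep(seq_len(n2), each = n2), as.vector(qbins))
    dist_pred[hit] <- dist_pred[hit] + (1 - noise)
    structure(list(query = query, template = template, reference = reference,
                   dist_pred = dist_pred, mutation_rate = mutation_rate,
                   indel_rate = indel_rate, noise = noise, seed = seed,
                   ref_style = ref_style),
              class = "pair_fixture")
  })
}

#' @export
print.pair_fixture <- function(x, ...) {
  cat(sprintf("pair fixture: template %d aa, query %d aa, %d reference pairs (mutation %.2f, indel %.2f, noise %.2f)\n",
              x$template$length, x$query$length,
              nrow(aligned_pairs(x$reference)),
              x$mutation_rate, x$indel_rate, x$noise))
  invisible(x)
}

## Default difficulty ladder, sampled in the ratio 1:2:2:1.
.DIFFICULTY <- data.frame(level = c("easy", "medium_easy", "medium_hard", "hard"),
                          mutation = c(0.10, 0.30, 0.50, 0.70),
                          indel = c(0.02, 0.06, 0.10, 0.15),
                          weight = c(1, 2, 2, 1))

#' Generate a reproducible corpus of pair fixtures
#'
#' Samples `n_pairs` fixtures over fresh folds, mixing four difficulty levels
#' (mutation/indel rates) in the ratio 1:2:2:1, and assigns a
#' train/validation/test split by fold identity so no fold crosses splits.
#'
#' @param n_pairs number of fixtures.
#' @param length_range template length range (inclusive).
#' @param noise predictor-error level applied to every fixture.
#' @param seed integer seed.
#' @param split_frac train/validation/test fractions (sum to 1).
#' @return Object of class `fixture_dataset`: list with `pairs` (list of
#'   [make_pair()] fixtures), `fold_id`, `difficulty`, `split` (factor).
#' @export
make_dataset <- function(n_pairs, length_range = c(30, 60), noise = 0.05,
                         seed = 1L, split_frac = c(0.7, 0.15, 0.15)) {
  stopifnot(n_pairs >= 1, length(length_range) == 2,
            abs(sum(split_frac) - 1) < 1e-8)
  meta <- with_seed(.mix_seed(seed, 91), {
    lev <- sample(nrow(.DIFFICULTY), n_pairs, replace = TRUE,
                  prob = .DIFFICULTY$weight)
    len <- sample(length_range[1]:length_range[2], n_pairs, replace = TRUE)
    list(lev = lev, len = len)
  })
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    fold <- sample_fold(meta$len[k], seed = .mix_seed(seed, 1000 + k))
    pairs[[k]] <- make_pair(fold,
                            mutation_rate = .DIFFICULTY$mutation[meta$lev[k]],
                            indel_rate = .DIFFICULTY$indel[meta$lev[k]],
                            noise = noise, seed = .mix_seed(seed, 2000 + k))
  }
  cuts <- cumsum(c(0, split_frac)) * n_pairs
  split <- cut(seq_len(n_pairs), breaks = unique(round(cuts)),
               labels = c("train", "validation", "test")[seq_len(length(unique(round(cuts))) - 1)],
               include.lowest = TRUE)
  structure(list(pairs = pairs, fold_id = seq_len(n_pairs),
                 difficulty = .DIFFICULTY$level[meta$lev], split = split),
            class = "fixture_dataset")
}

#' @export
print.fixture_dataset <- function(x, ...) {
  cat(sprintf("fixture dataset: %d pairs (%s)\n", length(x$pairs),
              paste(names(table(x$split)), table(x$split),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Random valid alignment
#'
#' Draws a uniform random non-empty set of strictly increasing matched pairs
#' and returns its canonical alignment.  Useful as a null model when probing
#' whether an objective favours a reference alignment.  Uses the current RNG
#' stream.
#'
#' @param n1,n2 protein lengths.
#' @return A valid `protein_alignment`.
#' @export
random_alignment <- function(n1, n2) {
  m <- sample(min(n1, n2), 1)
  alignment_from_pairs(cbind(sort(sample(n1, m)) - 1L,
                             sort(sample(n2, m)) - 1L), n1, n2)
}
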