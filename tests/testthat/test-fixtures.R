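test_that("sampled folds satisfy the chain-geometry invariants", {
  f2 <- sample_fold(2, seed = 1)
  d2 <- sqrt(sum((f2$coords[1, ] - f2$coords[2, ])^2))
  expect_true(d2 >= 3.6 && d2 <= 4.0)
  for (s in 1:20) {
    f <- sample_fold(50, seed = s)
    d <- as.matrix(dist(f$coords))
    consec <- d[cbind(1:49, 2:50)]
    expect_true(all(consec >= 3.6 & consec <= 4.0))
    d[cbind(1:49, 2:50)] <- Inf; d[cbind(2:50, 1:49)] <- Inf; diag(d) <- Inf
    expect_gte(min(d), 3.5)
  }
  expect_identical(sample_fold(30, seed = 5)$coords,
                   sample_fold(30, seed = 5)$coords)
  expect_error(sample_fold(1, seed = 1), ">= 2")
})

test_that("a noise- and indel-free pair is the identity fixture", {
  f <- sample_fold(20, seed = 3)
  fx <- make_pair(f, mutation_rate = 0, indel_rate = 0, noise = 0, seed = 4)
  expect_equal(fx$query$sequence, fx$template$sequence)
  expect_true(all(fx$reference$triples$state == "M"))
  expect_equal(aligned_pairs(fx$reference)[, 1], 0:19, ignore_attr = TRUE)
  ev <- evaluate_alignment(fx$reference, fx$reference)
  expect_equal(c(ev$precision, ev$recall), c(1, 1))
  # one-hot distance distributions at the true self-distance bins
  qb <- discretize_distance(fx$template$dist) # identical structures
  for (j in c(1, 7)) for (l in c(3, 15)) {
    expect_equal(fx$dist_pred[j, l, qb[j, l]], 1)
    expect_equal(sum(fx$dist_pred[j, l, ]), 1)
  }
  # one-hot profile
  expect_equal(sort(unique(as.vector(fx$query$psfm))), c(0, 1))
})

test_that("indel-free references contain no insertion states", {
  fx <- make_pair(sample_fold(15, seed = 6), mutation_rate = 0.5,
                  indel_rate = 0, noise = 0.2, seed = 5)
  expect_false(any(fx$reference$triples$state %in% c("Ix", "Iy")))
  expect_true(validate_alignment(fx$reference))
})

test_that("smoothing preserves distance-distribution row normalization", {
  fx <- make_pair(sample_fold(12, seed = 7), 0.3, 0.1, 0.37, seed = 6)
  sums <- apply(fx$dist_pred, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(validate_alignment(fx$reference))
})

test_that("the conservative reference style trims the outermost matches", {
  f <- sample_fold(18, seed = 8)
  a <- make_pair(f, 0.2, 0.1, 0, seed = 9, ref_style = "A")
  b <- make_pair(f, 0.2, 0.1, 0, seed = 9, ref_style = "B")
  pa <- aligned_pairs(a$reference); pb <- aligned_pairs(b$reference)
  expect_equal(nrow(pb), nrow(pa) - 2)
  expect_equal(pb, pa[-c(1, nrow(pa)), ], ignore_attr = TRUE)
})

test_that("datasets are reproducible with fold-disjoint splits", {
  d1 <- make_dataset(10, length_range = c(12, 18), seed = 5)
  d2 <- make_dataset(10, length_range = c(12, 18), seed = 5)
  expect_identical(d1$pairs[[3]]$query$psfm, d2$pairs[[3]]$query$psfm)
  expect_identical(d1$difficulty, d2$difficulty)
  expect_equal(length(d1$pairs), 10)
  expect_setequal(levels(d1$split), c("train", "validation", "test"))
  expect_equal(length(intersect(d1$fold_id[d1$split == "train"],
                                d1$fold_id[d1$split == "test"])), 0)
})

test_that("the reference dominates random alignments under the objective", {
  # signal-dominance with noise -> 0
  hits <- 0
  for (s in 1:20) {
    fx <- make_pair(sample_fold(20, seed = 200 + s), 0.3, 0.08, 0, seed = s)
    feats <- pair_features(fx$query, fx$template)
    th <- linear_score(feats, c(2, 0, 0.3, 0, 1, 0.05, 1, 0.5, 0.5),
                       bias = -2, gap_ix = -1, gap_iy = -1)
    pot <- dfire_potential(fx$dist_pred)
    tb <- template_distance_bins(fx$template$dist)
    ref_obj <- threading_objective(fx$reference, th, pot, tb, 1)$s_total
    ref_key <- paste(aligned_pairs(fx$reference), collapse = ",")
    rnd <- with_seed(1000 + s, replicate(100, {
      a <- random_alignment(fx$template$length, fx$query$length)
      # a uniform draw can reproduce the reference itself (e.g. the full
      # diagonal); dominance is over alignments that differ from it
      if (paste(aligned_pairs(a), collapse = ",") == ref_key) -Inf
      else threading_objective(a, th, pot, tb, 1)$s_total
    }))
    if (ref_obj > max(rnd)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("easier pairs yield better held-out precision than harder ones", {
  fit <- train_mle(fixture_corpus(12, lengths = 14:20, mutation = 0.3,
                                  seed_base = 150),
                   scorer = "linear", epochs = 12, seed = 3)
  prec <- function(mut, base) mean(vapply(
    fixture_corpus(8, lengths = 14:20, mutation = mut, seed_base = base),
    function(p) evaluate_alignment(predict(fit, p$query, p$template)$alignment,
                                   p$reference)$precision, 0))
  expect_gt(prec(0.1, 300), prec(0.7, 400))
})
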