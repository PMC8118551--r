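test_that("with a zero potential ADMM reduces to Viterbi and stops early", {
  with_seed(11, {
    th <- random_score_table(5, 5)
    pot <- structure(list(u = array(0, c(5, 5, 14)), alpha = 1.61, clip = 10,
                          p_ref = rep(1 / 14, 14)), class = "distance_potential")
    tb <- random_distance_instance(5, 5)$tbins
    init <- random_alignment(5, 5)
    r <- admm_align(th, pot, tb, init, w = 1)
    v <- viterbi(th)
    expect_equal(r$objective$s_total, v$score, tolerance = 1e-9)
    expect_lte(nrow(r$trace), 2)
    expect_true(r$converged)
  })
})

test_that("an optimal initial alignment is never degraded (keep_best floor)", {
  with_seed(12, for (rep in 1:5) {
    th <- random_score_table(4, 4)
    inst <- random_distance_instance(4, 4)
    alns <- enumerate_alignments(4, 4)
    objs <- vapply(alns, brute_objective, 0, theta = th, pot = inst$pot,
                   tbins = inst$tbins, w = 1)
    best <- alns[[which.max(objs)]]
    r <- admm_align(th, inst$pot, inst$tbins, best, w = 1)
    expect_equal(r$objective$s_total, max(objs), tolerance = 1e-9)
  })
})

test_that("ADMM never returns below the initial objective on random instances", {
  with_seed(13, for (rep in 1:15) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    th <- random_score_table(n1, n2)
    inst <- random_distance_instance(n1, n2)
    init <- random_alignment(n1, n2)
    r <- admm_align(th, inst$pot, inst$tbins, init, w = 1)
    expect_gte(r$objective$s_total + 1e-9,
               threading_objective(init, th, inst$pot, inst$tbins, 1)$s_total)
    expect_true(validate_alignment(r$alignment))
  })
})

test_that("multistart dominates every single start and equals it when tied", {
  with_seed(14, {
    n1 <- 4; n2 <- 4
    th <- random_score_table(n1, n2)
    inst <- random_distance_instance(n1, n2)
    # identical tables reproduce the single-start result
    same <- multistart_align(list(th, th, th, th), inst$pot, inst$tbins)
    single <- admm_align(th, inst$pot, inst$tbins, viterbi(th)$alignment)
    expect_equal(same$objective$s_total, single$objective$s_total)
    # one informative table among zero tables: the winner uses it
    zero <- score_table(matrix(0, n1, n2))
    ms <- multistart_align(list(th, zero, zero), inst$pot, inst$tbins)
    expect_gte(ms$objective$s_total, max(ms$per_start) - 1e-12)
    expect_equal(ms$objective$s_total, max(ms$per_start))
  })
})

test_that("alternating ADMM and the refiner never lowers the best objective", {
  with_seed(15, {
    th <- random_score_table(6, 6)
    inst <- random_distance_instance(6, 6)
    a <- viterbi(th)$alignment
    best <- threading_objective(a, th, inst$pot, inst$tbins, 1)$s_total
    rp <- refiner_init(tiny_drnf_config(), seed = 3)
    for (round in 1:2) {
      r <- admm_align(th, inst$pot, inst$tbins, a, w = 1)
      expect_gte(r$objective$s_total + 1e-9, best)
      best <- max(best, r$objective$s_total)
      a <- r$alignment
      ri <- build_refiner_input(a, th, inst$pot, inst$tbins)
      cand <- viterbi(refine_alignment(ri, rp))$alignment
      co <- threading_objective(cand, th, inst$pot, inst$tbins, 1)$s_total
      if (co > best) { a <- cand; best <- co } # keep-best across stages
    }
    expect_true(is.finite(best))
  })
})

test_that("the selection score combines its components as defined", {
  with_seed(16, {
    th <- random_score_table(6, 5)
    inst <- random_distance_instance(6, 5)
    a <- random_alignment(6, 5)
    sel <- selection_score(a, th, inst$pot, inst$tbins, w1 = 2, w2 = 5)
    o <- threading_objective(a, th, inst$pot, inst$tbins, 1)
    expect_equal(sel$score,
                 2 * o$s_singleton + o$s_pairwise + 5 * o$s_pairwise / sel$n_aligned)
    expect_equal(sel$s_norm, sel$s_pairwise / sel$n_aligned)
    # without a potential the score is w1 * singleton
    sel0 <- selection_score(a, th, NULL, NULL, w1 = 3)
    expect_equal(sel0$score, 3 * o$s_singleton)
    # doubling the alignment length at fixed pairwise halves the norm term
    a2 <- alignment_from_pairs(cbind(0:3, 0:3), 6, 5)
    a1 <- alignment_from_pairs(cbind(0:1, 0:1), 6, 5)
    s1 <- selection_score(a1, th, inst$pot, inst$tbins)
    s2 <- selection_score(a2, th, inst$pot, inst$tbins)
    expect_equal(s1$s_norm, s1$s_pairwise / 2)
    expect_equal(s2$s_norm, s2$s_pairwise / 4)
  })
})

test_that("ranking is stable under template permutation and trivial for one", {
  fit <- train_mle(fixture_corpus(6, lengths = 14:18, seed_base = 20),
                   scorer = "linear", epochs = 10, seed = 2)
  fx <- make_pair(sample_fold(16, seed = 33), 0.3, 0.05, 0.05, seed = 7)
  decoy <- make_pair(sample_fold(16, seed = 44), 0, 0, 0, seed = 8)$template
  third <- make_pair(sample_fold(15, seed = 55), 0, 0, 0, seed = 9)$template
  pot <- dfire_potential(fx$dist_pred)
  one <- rank_templates(fx$query, list(only = fx$template), fit,
                        mode = "singleton")
  expect_equal(one$table$rank, 1L)
  t1 <- list(a = fx$template, b = decoy, c = third)
  t2 <- t1[c(3, 1, 2)]
  r1 <- rank_templates(fx$query, t1, fit, mode = "distance", pot = pot)
  r2 <- rank_templates(fx$query, t2, fit, mode = "distance", pot = pot)
  expect_equal(r1$table$template, r2$table$template)
  expect_equal(r1$table$score, r2$table$score)
  expect_error(rank_templates(fx$query, list(), fit), "empty template list")
})
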