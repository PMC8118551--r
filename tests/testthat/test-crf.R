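test_that("a 1x1 problem has the unique alignment [(0,0,M)]", {
  th <- score_table(matrix(1.7, 1, 1))
  v <- viterbi(th)
  expect_equal(v$alignment$triples,
               data.frame(i = 0L, j = 0L, state = "M"))
  expect_equal(v$score, 1.7)
  fb <- forward_backward(th)
  expect_equal(fb$logZ, 1.7)
  expect_equal(unname(fb$p_match), 1)
  expect_equal(loglik(v$alignment, th), 0)
})

test_that("zero scores give logZ = log(#valid alignments) and equal loglik", {
  for (dims in list(c(2, 2), c(3, 3), c(3, 2))) {
    th <- score_table(matrix(0, dims[1], dims[2]))
    alns <- enumerate_alignments(dims[1], dims[2])
    fb <- forward_backward(th)
    expect_equal(fb$logZ, log(length(alns)), tolerance = 1e-10)
    lls <- vapply(alns, loglik, 0, theta = th)
    expect_equal(lls, rep(-log(length(alns)), length(alns)), tolerance = 1e-10)
    v <- viterbi(th)
    expect_equal(v$score, 0)
    expect_true(validate_alignment(v$alignment))
  }
})

test_that("DP quantities match exhaustive enumeration on random instances", {
  tm <- transition_model()
  with_seed(20, {
    for (trial in 1:12) {
      n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
      th <- random_score_table(n1, n2)
      alns <- enumerate_alignments(n1, n2)
      sc <- vapply(alns, score_alignment, 0, theta = th, tm = tm)
      v <- viterbi(th, tm)
      expect_equal(v$score, max(sc), tolerance = 1e-9)
      expect_equal(score_alignment(v$alignment, th, tm), v$score,
                   tolerance = 1e-9)
      fb <- forward_backward(th, tm)
      lz <- max(sc) + log(sum(exp(sc - max(sc))))
      expect_equal(fb$logZ, lz, tolerance = 1e-8)
      w <- exp(sc - fb$logZ)
      pm <- matrix(0, n1, n2)
      for (k in seq_along(alns))
        pm[aligned_pairs(alns[[k]]) + 1L] <- pm[aligned_pairs(alns[[k]]) + 1L] + w[k]
      expect_equal(matrix(fb$p_match, n1, n2), pm, tolerance = 1e-8)
    }
  })
})

test_that("alignment probabilities are normalized (enumeration check)", {
  with_seed(4, for (k in 1:5) {
    th <- random_score_table(3, 3)
    lls <- vapply(enumerate_alignments(3, 3), loglik, 0, theta = th)
    expect_equal(sum(exp(lls)), 1, tolerance = 1e-8)
  })
})

test_that("MaxAcc maximizes the expected accuracy over valid alignments", {
  tm <- transition_model()
  with_seed(12, for (trial in 1:8) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    th <- random_score_table(n1, n2)
    fb <- forward_backward(th, tm)
    pm <- matrix(fb$p_match, n1, n2)
    ma <- maxacc_decode(fb, tm)
    objs <- vapply(enumerate_alignments(n1, n2),
                   function(a) sum(pm[aligned_pairs(a) + 1L]), 0)
    expect_equal(ma$objective, max(objs), tolerance = 1e-9)
    # the maximizer is never worse than the Viterbi alignment's accuracy
    va <- viterbi(th, tm)$alignment
    expect_gte(ma$objective + 1e-12, sum(pm[aligned_pairs(va) + 1L]))
  })
})

test_that("posterior concentration pins the match and rows sum below one", {
  pm <- matrix(0, 2, 2); pm[1, 1] <- 1
  post <- structure(list(p_match = pm, n1 = 2, n2 = 2),
                    class = "posterior_table")
  ma <- maxacc_decode(post)
  expect_true(any(ma$alignment$triples$i == 0 & ma$alignment$triples$j == 0 &
                    ma$alignment$triples$state == "M"))
  with_seed(9, {
    th <- random_score_table(4, 3)
    fb <- forward_backward(th)
    pmat <- matrix(fb$p_match, 4, 3)
    expect_true(all(pmat >= -1e-12 & pmat <= 1 + 1e-12))
    expect_true(all(rowSums(pmat) <= 1 + 1e-9))
    expect_true(all(colSums(pmat) <= 1 + 1e-9))
  })
})

test_that("raising a match score never lowers its posterior", {
  with_seed(31, {
    th <- random_score_table(3, 3)
    fb0 <- forward_backward(th)
    th2 <- th
    th2$theta[2, 2, 1] <- th2$theta[2, 2, 1] + 0.8
    fb1 <- forward_backward(score_table(th2$theta))
    expect_gte(matrix(fb1$p_match, 3, 3)[2, 2],
               matrix(fb0$p_match, 3, 3)[2, 2] - 1e-12)
  })
})

test_that("decoded alignments always satisfy the validator", {
  with_seed(77, for (k in 1:10) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    th <- random_score_table(n1, n2)
    expect_true(validate_alignment(viterbi(th)$alignment))
    expect_true(validate_alignment(maxacc_decode(forward_backward(th))$alignment))
  })
})
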