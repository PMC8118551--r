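make_line_template <- function(seq, spacing = 3.8) {
  n <- nchar(seq)
  template_record(seq, cbind((seq_len(n) - 1) * spacing, 0, 0),
                  ss3 = rep("C", n), ss8 = rep("C", n), acc = rep(0.5, n))
}

make_uniform_query <- function(seq) {
  n <- nchar(seq)
  query_record(seq,
               psfm = matrix(1 / 20, n, 20),
               pssm = matrix(0, n, 20),
               ss3 = matrix(1 / 3, n, 3),
               ss8 = matrix(1 / 8, n, 8),
               acc = matrix(1 / 3, n, 3))
}

test_that("records validate their invariants", {
  expect_error(query_record("AB", matrix(1 / 20, 2, 20), matrix(0, 2, 20),
                            matrix(1 / 3, 2, 3), matrix(1 / 8, 2, 8),
                            matrix(1 / 3, 2, 3)),
               "unknown residue code 'B' at position 2")
  bad_psfm <- matrix(1 / 20, 2, 20); bad_psfm[1, 1] <- 0.5
  expect_error(query_record("AC", bad_psfm, matrix(0, 2, 20),
                            matrix(1 / 3, 2, 3), matrix(1 / 8, 2, 8),
                            matrix(1 / 3, 2, 3)),
               "sum to 1")
  expect_error(template_record("AC", cbind(0:1, 0, 0), c("H", "Z"),
                               c("H", "H"), c(0.5, 0.5)),
               "ss3")
})

test_that("a straight 4-residue template has the hand-computed distances", {
  t <- make_line_template("ACDE")
  expect_equal(t$dist[1, 4], 11.4, tolerance = 1e-9)
  expect_equal(t$dist, t(t$dist))
  expect_equal(unname(diag(t$dist)), rep(0, 4))
  tb <- template_distance_bins(t$dist)
  expect_equal(tb[1, 2], 1L)   # 3.8 A -> first bin
  expect_equal(tb[1, 4], 9L)   # 11.4 A -> [11, 12)
})

test_that("identity and substitution channels follow the canonical matrices", {
  t <- make_line_template("AVXA")
  q <- make_uniform_query("AAX")
  f <- pair_features(q, t)
  expect_equal(as.numeric(f[1, 1, "identity"]), 1) # A vs A
  expect_equal(as.numeric(f[2, 1, "identity"]), 0) # V vs A
  expect_equal(as.numeric(f[1, 1, "blosum62"]), 4) # BLOSUM62 Ala diagonal
  expect_equal(as.numeric(f[2, 1, "blosum62"]), 0) # A vs V = 0 in BLOSUM62
  expect_equal(as.numeric(f[1, 1, "blosum45"]), 5) # NCBI BLOSUM45 Ala diagonal
  expect_equal(as.numeric(f[1, 1, "blosum80"]), 5) # NCBI BLOSUM80 Ala diagonal
  # X rows/columns score 0 on identity and substitution channels
  expect_equal(unname(f[3, , "blosum62"]), rep(0, 3))
  expect_equal(unname(f[, 3, "identity"]), rep(0, 4))
})

test_that("profile channels are the two-directional inner products", {
  t <- make_line_template("AC")
  q <- make_uniform_query("AD")
  f <- pair_features(q, t)
  # query psfm uniform: <psfm_q, pssm_t> is the mean BLOSUM62 row
  b62 <- threadcrf:::.blosum("BLOSUM62")
  expect_equal(as.numeric(f[1, 1, "prof_q2t"]), mean(b62["A", ]),
               tolerance = 1e-12)
  expect_equal(as.numeric(f[2, 2, "prof_q2t"]), mean(b62["C", ]),
               tolerance = 1e-12)
  # query pssm all-zero: the reverse channel vanishes
  expect_equal(unname(f[, , "prof_t2q"]), matrix(0, 2, 2))
})

test_that("ss/acc channels read the query probability of the template class", {
  n <- 2
  ss3 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  q <- query_record("AC", matrix(1 / 20, n, 20), matrix(0, n, 20), ss3,
                    matrix(1 / 8, n, 8),
                    rbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6)))
  t <- template_record("AC", cbind(c(0, 3.8), 0, 0), c("H", "E"),
                       c("H", "E"), c(0.05, 0.9))
  f <- pair_features(q, t)
  expect_equal(unname(f[, , "ss3"]), rbind(c(0.7, 0.1), c(0.2, 0.8)))
  # template acc 0.05 -> buried, 0.9 -> exposed
  expect_equal(unname(f[, , "acc"]), rbind(c(0.6, 0.2), c(0.1, 0.6)))
})

test_that("permuting template positions permutes feature rows equivariantly", {
  with_seed(8, {
    fx <- make_pair(sample_fold(8, seed = 2), 0.3, 0, 0.1, seed = 5)
    f <- pair_features(fx$query, fx$template)
    perm <- sample(8)
    tp <- fx$template
    tp2 <- template_record(paste(tp$chars[perm], collapse = ""),
                           tp$coords_cb[perm, ], tp$ss3[perm], tp$ss8[perm],
                           tp$acc[perm])
    f2 <- pair_features(fx$query, tp2)
    expect_equal(f2, f[perm, , , drop = FALSE], ignore_attr = TRUE)
    expect_true(all(is.finite(f)))
  })
})

test_that("sequential features are a 54-channel shared encoding", {
  fx <- make_pair(sample_fold(6, seed = 4), 0.2, 0, 0.05, seed = 1)
  xq <- seq_features(fx$query)
  xt <- seq_features(fx$template)
  expect_equal(nrow(xq), 54)
  expect_equal(nrow(xt), 54)
  expect_equal(ncol(xt), fx$template$length)
  # template one-hot PSFM block sums to one per position
  expect_equal(unname(colSums(xt[1:20, ])), rep(1, fx$template$length))
})
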