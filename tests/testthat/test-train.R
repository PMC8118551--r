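test_that("analytic likelihood gradients match central finite differences", {
  fx <- with_seed(2, make_pair(sample_fold(5, seed = 11), 0.3, 0.2, 0.1,
                               seed = 2))
  feats <- pair_features(fx$query, fx$template)
  tm <- transition_model()
  par <- with_seed(5, rnorm(12, sd = 0.3))
  r <- threadcrf:::.linear_grad(par, feats, fx$reference, tm)
  fd <- vapply(seq_along(par), function(k) {
    h <- 1e-5; e <- numeric(length(par)); e[k] <- h
    (threadcrf:::.linear_grad(par + e, feats, fx$reference, tm)$loglik -
       threadcrf:::.linear_grad(par - e, feats, fx$reference, tm)$loglik) / (2 * h)
  }, 0)
  expect_lt(max(abs(r$grad - fd) / pmax(abs(fd), 1e-6)), 1e-4)
  expect_lte(r$loglik, 0)
})

test_that("transition-score gradients match finite differences when trained", {
  fx <- with_seed(3, make_pair(sample_fold(5, seed = 4), 0.3, 0.2, 0.1,
                               seed = 4))
  feats <- pair_features(fx$query, fx$template)
  par <- with_seed(7, rnorm(12, sd = 0.3))
  trainable <- with(transition_model(),
                    which(feasible & !((row(score) * 10 + col(score)) %in%
                                         c(15, 41, 44, 55))))
  sc <- matrix(0, 5, 5)
  sc[trainable] <- with_seed(8, rnorm(length(trainable), sd = 0.2))
  tm <- transition_model(score = sc)
  r <- threadcrf:::.linear_grad(par, feats, fx$reference, tm, want_edges = TRUE)
  fd <- vapply(trainable, function(ix) {
    h <- 1e-5
    s1 <- sc; s1[ix] <- s1[ix] + h
    s2 <- sc; s2[ix] <- s2[ix] - h
    (threadcrf:::.linear_grad(par, feats, fx$reference,
                              transition_model(score = s1))$loglik -
       threadcrf:::.linear_grad(par, feats, fx$reference,
                                transition_model(score = s2))$loglik) / (2 * h)
  }, 0)
  expect_lt(max(abs(r$edge_grad[trainable] - fd)), 1e-6)
})

test_that("network likelihood gradients backpropagate correctly", {
  fx <- with_seed(4, make_pair(sample_fold(5, seed = 6), 0.3, 0.2, 0.1,
                               seed = 5))
  feats <- pair_features(fx$query, fx$template)
  tm <- transition_model()
  p0 <- drnf_init(tiny_drnf_config(), seed = 9)
  v0 <- threadcrf:::drnf_flatten(p0)
  eval_at <- function(v) {
    pk <- threadcrf:::drnf_unflatten(p0, v)
    fw <- threadcrf:::.drnf_forward(fx$query, fx$template, pk, feats,
                                    keep_cache = TRUE)
    fb <- forward_backward(fw$theta, tm)
    d <- threadcrf:::.obs_cells(fx$reference, fw$theta$n1, fw$theta$n2) - fb$post
    list(ll = score_alignment(fx$reference, fw$theta, tm) - fb$logZ,
         g = threadcrf:::drnf_flatten_grads(pk, threadcrf:::.drnf_backward(pk, fw, d)))
  }
  r0 <- eval_at(v0)
  idx <- with_seed(10, sort(sample(length(v0), 25)))
  fd <- vapply(idx, function(k) {
    h <- 1e-5; e <- numeric(length(v0)); e[k] <- h
    (eval_at(v0 + e)$ll - eval_at(v0 - e)$ll) / (2 * h)
  }, 0)
  expect_lt(max(abs(r0$g[idx] - fd) / pmax(abs(fd), 1e-4)), 1e-4)
})

test_that("zero training epochs leave the parameters unchanged", {
  pairs <- fixture_corpus(2, lengths = 10:12, seed_base = 60)
  init <- with_seed(3, rnorm(12, sd = 0.1))
  fit <- train_mle(pairs, scorer = "linear", epochs = 0, init = init)
  expect_equal(unname(coef(fit)), init)
  p0 <- drnf_init(tiny_drnf_config(), seed = 4)
  fitd <- train_mle(pairs, scorer = "drnf", config = tiny_drnf_config(),
                    epochs = 0, init = p0)
  expect_equal(coef(fitd), threadcrf:::drnf_flatten(p0))
})

test_that("small-step full-batch ascent never decreases the likelihood", {
  pairs <- fixture_corpus(4, lengths = 10:14, seed_base = 70)
  fit <- train_mle(pairs, scorer = "linear", optimizer = "sgd", lr = 5e-4,
                   epochs = 12, batch_budget = 1e9, seed = 2)
  expect_gte(min(diff(fit$loglik_trace)), -1e-9)
})

test_that("training recovers alignments generated by a feature-linear rule", {
  # references decoded from known linear weights; training from zero must
  # recover them on held-out pairs
  true_par <- c(2, 0, 0.3, 0, 1, 0.05, 0.8, 0.4, 0.4, -2, -1, -1)
  gen <- function(n, seed_base) lapply(seq_len(n), function(k) {
    fx <- make_pair(sample_fold(with_seed(seed_base + k, sample(14:20, 1)),
                                seed = seed_base + 500 + k),
                    0.4, 0.08, 0.05, seed = seed_base + k)
    th <- threadcrf:::.linear_theta(true_par, pair_features(fx$query, fx$template))
    list(query = fx$query, template = fx$template,
         reference = viterbi(th)$alignment)
  })
  train <- gen(25, 3000)
  test <- gen(8, 4000)
  fit <- train_mle(train, scorer = "linear", epochs = 25, seed = 5)
  prec <- vapply(test, function(p) {
    evaluate_alignment(predict(fit, p$query, p$template)$alignment,
                       p$reference)$precision
  }, 0)
  expect_gt(mean(prec), 0.8)
})

test_that("minibatches respect the length-product budget", {
  pairs <- fixture_corpus(6, lengths = 12:20, seed_base = 80)
  # budget below the largest pair still trains (one pair per batch)
  fit <- train_mle(pairs, scorer = "linear", epochs = 2, batch_budget = 150,
                   seed = 1)
  expect_length(fit$loglik_trace, 2)
  expect_true(all(is.finite(fit$loglik_trace)))
})

test_that("the network scorer also improves its reference likelihood", {
  pairs <- fixture_corpus(4, lengths = 9:12, mutation = 0.2, seed_base = 90)
  fit <- train_mle(pairs, scorer = "drnf", config = tiny_drnf_config(),
                   epochs = 6, lr = 0.02, seed = 3)
  expect_gt(fit$loglik_trace[6], fit$loglik_trace[1])
  pr <- predict(fit, pairs[[1]]$query, pairs[[1]]$template, decoder = "maxacc")
  expect_true(validate_alignment(pr$alignment))
})

test_that("training transitions moves only the eight free entries", {
  pairs <- fixture_corpus(3, lengths = 10:12, seed_base = 95)
  fit <- train_mle(pairs, scorer = "linear", epochs = 4, seed = 2,
                   train_transitions = TRUE)
  sc <- fit$tm$score
  expect_equal(sc["M", "Gt"], 0)
  expect_equal(sc["Gh", "M"], 0)
  expect_equal(sc["Gh", "Gh"], 0)
  expect_equal(sc["Gt", "Gt"], 0)
  expect_true(any(sc[fit$tm$feasible] != 0))
})
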