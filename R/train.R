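#' Maximum-likelihood training of an emission scorer
#'
#' Fits the parameters of an emission scorer by maximizing the conditional
#' log-likelihood of reference alignments under the five-state alignment
#' CRF.  Two scorers are supported: `"linear"` (exact analytic gradients via
#' forward-backward expected counts; see [linear_score()]) and `"drnf"` (the
#' residual convolutional scorer of [drnf_score()], trained by
#' backpropagating the same expected-count gradient through the network).
#' The transition matrix is held fixed by default (training it adds the
#' expected-transition-count gradient for the eight non-fixed feasible
#' entries).  Training pairs are grouped into minibatches by the product of
#' their protein lengths, so one batch holds several small pairs or a single
#' large one.
#'
#' @param pairs list of training pairs: [make_pair()] fixtures or lists with
#'   elements `query`, `template`, `reference`.
#' @param scorer `"linear"` or `"drnf"`.
#' @param config a [drnf_config()] for the drnf scorer (ignored otherwise).
#' @param seed integer seed (initialization and batch shuffling).
#' @param epochs full passes over the data; `0` returns the initial
#'   parameters unchanged.
#' @param lr learning rate (default 0.05 for adam, 1e-3 for sgd).
#' @param optimizer `"adam"` or plain `"sgd"` gradient ascent.
#' @param batch_budget maximum summed length product `n1 * n2` per minibatch.
#' @param tm starting [transition_model()].
#' @param train_transitions also learn the non-fixed transition scores
#'   (default `FALSE`: fixed transition matrix).
#' @param init optional initial parameters (numeric vector for linear,
#'   `drnf_params` for drnf); defaults to zeros / seeded Gaussian.
#' @param verbose print the per-epoch mean log-likelihood.
#' @return Object of class `crf_scorer` with methods [print()], [coef()],
#'   [logLik()], [predict()] and [plot()].
#' @export
train_mle <- function(pairs, scorer = c("linear", "drnf"), config = NULL,
                      seed = 1L, epochs = 30L, lr = NULL,
                      optimizer = c("adam", "sgd"), batch_budget = 4000,
                      tm = transition_model(), train_transitions = FALSE,
                      init = NULL, verbose = FALSE) {
  scorer <- match.arg(scorer)
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 0.05 else 1e-3
  stopifnot(length(pairs) >= 1, epochs >= 0)
  prep <- lapply(pairs, function(p) {
    stopifnot(!is.null(p$query), !is.null(p$template), !is.null(p$reference))
    validate_alignment(p$reference, tm)
    list(q = p$query, t = p$template, ref = p$reference,
         feats = pair_features(p$query, p$template),
         size = p$template$length * p$query$length)
  })
  nc <- dim(prep[[1]]$feats)[3]
  if (scorer == "linear") {
    par <- if (is.null(init)) numeric(nc + 3) else init
    stopifnot(length(par) == nc + 3)
  } else {
    if (is.null(config)) config <- drnf_config()
    params <- if (is.null(init)) drnf_init(config, seed = seed) else init
    stopifnot(inherits(params, "drnf_params"))
    par <- drnf_flatten(params)
  }
  trainable_trans <- which(tm$feasible &
                             !(row(tm$score) * 10 + col(tm$score)) %in%
                             (.ZERO_SCORED[, 1] * 10 + .ZERO_SCORED[, 2]))
  tvec <- if (train_transitions) tm$score[trainable_trans] else numeric(0)
  np <- length(par)
  theta_vec <- c(par, tvec)
  mom1 <- mom2 <- numeric(length(theta_vec))
  step <- 0L
  trace <- numeric(0)
  current_tm <- function(v) {
    if (!train_transitions) return(tm)
    sc <- tm$score
    sc[trainable_trans] <- v[np + seq_along(trainable_trans)]
    transition_model(score = sc, feasible = tm$feasible)
  }
  pair_grad <- function(v, p, tmx) {
    if (scorer == "linear") {
      r <- .linear_grad(v[seq_len(np)], p$feats, p$ref, tmx,
                        want_edges = train_transitions)
      g <- r$grad
    } else {
      params_k <- drnf_unflatten(params, v[seq_len(np)])
      fw <- .drnf_forward(p$q, p$t, params_k, p$feats, keep_cache = TRUE)
      fb <- forward_backward(fw$theta, tmx, edges = train_transitions)
      d <- .obs_cells(p$ref, fw$theta$n1, fw$theta$n2) - fb$post
      g <- drnf_flatten_grads(params_k, .drnf_backward(params_k, fw, d))
      r <- list(loglik = score_alignment(p$ref, fw$theta, tmx) - fb$logZ,
                edge_grad = if (train_transitions) .obs_transitions(p$ref) - fb$edges)
    }
    if (train_transitions) g <- c(g, r$edge_grad[trainable_trans])
    list(grad = g, loglik = r$loglik)
  }
  for (ep in seq_len(epochs)) {
    ord <- with_seed(.mix_seed(seed, 5000 + ep), sample(length(prep)))
    batches <- list(); cur <- integer(0); tot <- 0
    for (k in ord) {
      if (length(cur) > 0L && tot + prep[[k]]$size > batch_budget) {
        batches[[length(batches) + 1L]] <- cur; cur <- integer(0); tot <- 0
      }
      cur <- c(cur, k); tot <- tot + prep[[k]]$size
    }
    batches[[length(batches) + 1L]] <- cur
    ep_ll <- 0
    for (b in batches) {
      tmx <- current_tm(theta_vec)
      g <- numeric(length(theta_vec)); ll <- 0
      for (k in b) {
        r <- pair_grad(theta_vec, prep[[k]], tmx)
        g <- g + r$grad; ll <- ll + r$loglik
      }
      if (!all(is.finite(g)) || !is.finite(ll))
        stop("training diverged: non-finite log-likelihood/gradient at epoch ",
             ep, " (try a smaller learning rate)")
      g <- g / length(b)
      step <- step + 1L
      if (optimizer == "adam") {
        mom1 <- 0.9 * mom1 + 0.1 * g
        mom2 <- 0.999 * mom2 + 0.001 * g^2
        m_hat <- mom1 / (1 - 0.9^step)
        v_hat <- mom2 / (1 - 0.999^step)
        theta_vec <- theta_vec + lr * m_hat / (sqrt(v_hat) + 1e-8)
      } else {
        theta_vec <- theta_vec + lr * g
      }
      ep_ll <- ep_ll + ll
    }
    trace <- c(trace, ep_ll / length(prep))
    if (verbose)
      message(sprintf("epoch %d: mean reference loglik %.4f", ep, ep_ll / length(prep)))
  }
  fit <- structure(list(
    scorer = scorer,
    par = if (scorer == "linear") stats::setNames(
      theta_vec[seq_len(np)],
      c(dimnames(prep[[1]]$feats)[[3]], "bias", "gap_ix", "gap_iy")) else NULL,
    params = if (scorer == "drnf") drnf_unflatten(params, theta_vec[seq_len(np)]),
    tm = current_tm(theta_vec),
    config = if (scorer == "drnf") config,
    loglik_trace = trace, epochs = epochs, seed = seed,
    n_pairs = length(prep), n_par = length(theta_vec),
    call = match.call()), class = "crf_scorer")
  fit
}

#' Emission scores of a fitted scorer for one pair
#'
#' @param object a `crf_scorer` from [train_mle()].
#' @param query a [query_record()].
#' @param template a [template_record()].
#' @return A [score_table()].
#' @export
emission_scores <- function(object, query, template) {
  stopifnot(inherits(object, "crf_scorer"))
  if (object$scorer == "linear")
    .linear_theta(unname(object$par), pair_features(query, template))
  else
    drnf_score(query, template, object$params)
}

#' Decode an alignment with a fitted scorer
#'
#' @param object a `crf_scorer`.
#' @param query,template the pair to align.
#' @param decoder `"viterbi"` (highest-probability alignment) or `"maxacc"`
#'   (maximum expected accuracy).
#' @param ... unused.
#' @return List with `alignment`, `score` (Viterbi total score or MaxAcc
#'   objective), `theta` and `logZ`.
#' @export
predict.crf_scorer <- function(object, query, template,
                               decoder = c("viterbi", "maxacc"), ...) {
  decoder <- match.arg(decoder)
  theta <- emission_scores(object, query, template)
  if (decoder == "viterbi") {
    v <- viterbi(theta, object$tm)
    list(alignment = v$alignment, score = v$score, theta = theta,
         logZ = forward_backward(theta, object$tm)$logZ)
  } else {
    fb <- forward_backward(theta, object$tm)
    m <- maxacc_decode(fb, object$tm)
    list(alignment = m$alignment, score = m$objective, theta = theta,
         logZ = fb$logZ)
  }
}

#' @export
print.crf_scorer <- function(x, ...) {
  cat(sprintf("CRF alignment scorer (%s), %d parameters, trained %d epochs on %d pairs\n",
              x$scorer, x$n_par, x$epochs, x$n_pairs))
  if (length(x$loglik_trace))
    cat(sprintf("  mean reference loglik: %.4f -> %.4f\n",
                x$loglik_trace[1], x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @export
summary.crf_scorer <- function(object, ...) {
  print(object)
  if (object$scorer == "linear") {
    cat("coefficients:\n")
    print(round(object$par, 4))
  }
  invisible(object)
}

#' @export
coef.crf_scorer <- function(object, ...) {
  if (object$scorer == "linear") object$par else drnf_flatten(object$params)
}

#' @export
logLik.crf_scorer <- function(object, ...) {
  ll <- if (length(object$loglik_trace))
    object$loglik_trace[length(object$loglik_trace)] else NA_real_
  structure(ll, df = object$n_par, nobs = object$n_pairs, class = "logLik")
}

#' @export
plot.crf_scorer <- function(x, ...) {
  if (!length(x$loglik_trace)) stop("no training trace to plot")
  graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                 xlab = "epoch", ylab = "mean reference log-likelihood", ...)
  invisible(x)
}

#' Save / load a fitted scorer
#'
#' The checkpoint is an RDS container; a human-readable JSON sidecar
#' (`<file>.json`) records the scorer type and configuration.
#'
#' @param object a `crf_scorer`.
#' @param file path.
#' @export
write_scorer <- function(object, file) {
  stopifnot(inherits(object, "crf_scorer"))
  saveRDS(object, file)
  side <- list(scorer = object$scorer, n_par = object$n_par,
               epochs = object$epochs, seed = object$seed)
  if (!is.null(object$config)) side$config <- unclass(object$config)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(file) {
  object <- readRDS(file)
  stopifnot(inherits(object, "crf_scorer"))
  object
}
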