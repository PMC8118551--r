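## Alphabets and class labels.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SS3_LABELS <- c("H", "E", "C")
SS8_LABELS <- c("H", "G", "I", "E", "B", "T", "S", "C")
ACC_LABELS <- c("B", "M", "E") # buried, intermediate, exposed

## Relative-accessibility class thresholds (buried < 0.10, exposed >= 0.40).
acc_class <- function(racc) {
  ACC_LABELS[findInterval(racc, c(0.10, 0.40)) + 1L]
}

.blosum_env <- new.env(parent = emptyenv())
.blosum <- function(name) {
  if (is.null(.blosum_env[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .blosum_env[[name]] <- e[[name]][AA20, AA20]
  }
  .blosum_env[[name]]
}

.check_rows <- function(x, n, k, what, sums = TRUE) {
  if (!is.matrix(x) || nrow(x) != n || ncol(x) != k)
    stop(what, " must be a ", n, " x ", k, " matrix")
  if (any(!is.finite(x))) stop(what, " contains non-finite values")
  if (sums && any(abs(rowSums(x) - 1) > 1e-6))
    stop(what, " rows must sum to 1")
  invisible(TRUE)
}

.check_seq <- function(sequence, what) {
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% c(AA20, "X"))
  if (length(bad))
    stop(what, ": unknown residue code '", ch[bad[1]], "' at position ", bad[1])
  ch
}

#' Query protein record
#'
#' Bundles the sequence-derived inputs of a query protein: its sequence, the
#' position-specific frequency and scoring matrices of its profile, predicted
#' 3- and 8-class secondary-structure probabilities and predicted 3-class
#' solvent-accessibility probabilities (buried/intermediate/exposed).
#'
#' @param sequence amino-acid string (20-letter alphabet plus `X`).
#' @param psfm `N x 20` frequency matrix (rows sum to 1), columns in the
#'   standard `ARNDCQEGHILKMFPSTWYV` residue order.
#' @param pssm `N x 20` log-odds score matrix.
#' @param ss3,ss8 `N x 3` / `N x 8` class-probability matrices.
#' @param acc `N x 3` accessibility class probabilities.
#' @return Object of class `query_record`.
#' @export
query_record <- function(sequence, psfm, pssm, ss3, ss8, acc) {
  ch <- .check_seq(sequence, "query")
  n <- length(ch)
  .check_rows(psfm, n, 20, "psfm")
  .check_rows(pssm, n, 20, "pssm", sums = FALSE)
  .check_rows(ss3, n, 3, "ss3")
  .check_rows(ss8, n, 8, "ss8")
  .check_rows(acc, n, 3, "acc")
  structure(list(sequence = sequence, chars = ch, psfm = psfm, pssm = pssm,
                 ss3 = ss3, ss8 = ss8, acc = acc, length = n),
            class = "query_record")
}

#' Template protein record
#'
#' Bundles the structure-derived inputs of a template: sequence, Cbeta
#' coordinates (Calpha substituted for glycine), observed secondary-structure
#' labels, observed relative solvent accessibility, and the Cbeta-Cbeta
#' distance matrix, which is always recomputed from the coordinates.
#' An optional profile (`psfm`/`pssm`) may be supplied; by default the PSFM
#' is the one-hot encoding of the sequence and the PSSM row of a residue is
#' its BLOSUM62 row (the single-sequence profile).
#'
#' @param sequence amino-acid string.
#' @param coords_cb `N x 3` coordinate matrix in Angstrom.
#' @param ss3,ss8 character label vectors (`H/E/C` and the 8-class DSSP-style
#'   alphabet `H G I E B T S C`).
#' @param acc numeric relative accessibility in `[0, 1]`.
#' @param psfm,pssm optional `N x 20` template profile matrices.
#' @return Object of class `template_record` (with element `dist`).
#' @export
template_record <- function(sequence, coords_cb, ss3, ss8, acc,
                            psfm = NULL, pssm = NULL) {
  ch <- .check_seq(sequence, "template")
  n <- length(ch)
  coords_cb <- as.matrix(coords_cb)
  stopifnot(nrow(coords_cb) == n, ncol(coords_cb) == 3,
            all(is.finite(coords_cb)))
  if (length(ss3) != n || !all(ss3 %in% SS3_LABELS))
    stop("ss3 must be length-", n, " labels among ", paste(SS3_LABELS, collapse = ""))
  if (length(ss8) != n || !all(ss8 %in% SS8_LABELS))
    stop("ss8 must be length-", n, " labels among ", paste(SS8_LABELS, collapse = ""))
  stopifnot(length(acc) == n, all(is.finite(acc)), all(acc >= 0), all(acc <= 1))
  if (is.null(psfm)) {
    psfm <- matrix(0, n, 20, dimnames = list(NULL, AA20))
    known <- ch %in% AA20
    psfm[cbind(which(known), match(ch[known], AA20))] <- 1
    psfm[!known, ] <- 1 / 20 # 'X': uninformative
  } else .check_rows(psfm, n, 20, "psfm")
  if (is.null(pssm)) {
    b62 <- .blosum("BLOSUM62")
    pssm <- matrix(0, n, 20)
    known <- ch %in% AA20
    pssm[known, ] <- b62[ch[known], , drop = FALSE]
  } else .check_rows(pssm, n, 20, "pssm", sums = FALSE)
  d <- as.matrix(stats::dist(coords_cb))
  dimnames(d) <- NULL
  structure(list(sequence = sequence, chars = ch, coords_cb = coords_cb,
                 ss3 = ss3, ss8 = ss8, acc = acc, psfm = psfm, pssm = pssm,
                 dist = d, length = n),
            class = "template_record")
}

#' @export
print.query_record <- function(x, ...) {
  cat(sprintf("query record: %d residues\n", x$length)); invisible(x)
}

#' @export
print.template_record <- function(x, ...) {
  cat(sprintf("template record: %d residues, distance matrix %d x %d\n",
              x$length, x$length, x$length))
  invisible(x)
}

#' Pairwise sequential feature tensor
#'
#' Builds the nine per-cell feature channels consumed by the emission
#' scorers: residue identity, BLOSUM80/62/45 substitution scores,
#' profile similarity in both directions (`<q.psfm[j], t.pssm[i]>` and
#' `<t.psfm[i], q.pssm[j]>`), and agreement scores for secondary structure
#' (the probability the query's predicted class distribution assigns to the
#' template's observed class, for 3- and 8-class separately) and solvent
#' accessibility (likewise over the 3 burial classes).  Residue `X` scores 0
#' for identity and substitution channels.
#'
#' @param q a [query_record()].
#' @param t a [template_record()].
#' @return Numeric array `n1 x n2 x 9` (template x query x channel), class
#'   `pair_features`, with channel dimnames.
#' @export
pair_features <- function(q, t) {
  stopifnot(inherits(q, "query_record"), inherits(t, "template_record"))
  n1 <- t$length; n2 <- q$length
  channels <- c("identity", "blosum80", "blosum62", "blosum45",
                "prof_q2t", "prof_t2q", "ss3", "ss8", "acc")
  f <- array(0, dim = c(n1, n2, 9L), dimnames = list(NULL, NULL, channels))
  known_t <- t$chars %in% AA20
  known_q <- q$chars %in% AA20
  f[, , "identity"] <- outer(t$chars, q$chars, "==") * outer(known_t, known_q, "&")
  for (bl in c("blosum80", "blosum62", "blosum45")) {
    b <- .blosum(toupper(bl))
    m <- matrix(0, n1, n2)
    m[known_t, known_q] <- b[t$chars[known_t], q$chars[known_q], drop = FALSE]
    f[, , bl] <- m
  }
  f[, , "prof_q2t"] <- t$pssm %*% t(q$psfm)
  f[, , "prof_t2q"] <- t$psfm %*% t(q$pssm)
  f[, , "ss3"] <- t(q$ss3[, match(t$ss3, SS3_LABELS), drop = FALSE])
  f[, , "ss8"] <- t(q$ss8[, match(t$ss8, SS8_LABELS), drop = FALSE])
  f[, , "acc"] <- t(q$acc[, match(acc_class(t$acc), ACC_LABELS), drop = FALSE])
  structure(f, class = "pair_features")
}

#' Per-residue sequential feature matrix
#'
#' The 1D input of the residual scorer: 54 rows per residue position
#' (20 PSFM + 20 PSSM + 3 ss3 + 8 ss8 + 3 accessibility-class
#' probabilities).  Template records use one-hot/observed encodings so query
#' and template share the same feature space.
#'
#' @param rec a [query_record()] or [template_record()].
#' @return Numeric matrix `54 x N`.
#' @export
seq_features <- function(rec) {
  onehot <- function(labels, levels) {
    m <- matrix(0, length(labels), length(levels))
    m[cbind(seq_along(labels), match(labels, levels))] <- 1
    m
  }
  if (inherits(rec, "template_record")) {
    ss3 <- onehot(rec$ss3, SS3_LABELS)
    ss8 <- onehot(rec$ss8, SS8_LABELS)
    acc <- onehot(acc_class(rec$acc), ACC_LABELS)
  } else {
    stopifnot(inherits(rec, "query_record"))
    ss3 <- rec$ss3; ss8 <- rec$ss8; acc <- rec$acc
  }
  t(cbind(rec$psfm, rec$pssm, ss3, ss8, acc))
}
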