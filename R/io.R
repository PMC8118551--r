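## On-disk formats.
##
## Query profile: whitespace-delimited text, comment/header lines starting
## with '#', then one row per position:
##   pos aa  psfm[1..20] pssm[1..20] ss3[1..3] ss8[1..8] acc[1..3]
## Template: a PDB file (CB atoms, CA substituted for glycine; first model,
## single chain) plus a meta file:  pos aa ss3 ss8 acc
## Distance tensors and model checkpoints: RDS containers (with a JSON
## sidecar for checkpoints, see train_mle).

#' Write / read a query record
#'
#' @param q a [query_record()].
#' @param file path.
#' @return `read_query` returns a [query_record()]; `write_query` the file
#'   path, invisibly.
#' @export
write_query <- function(q, file) {
  stopifnot(inherits(q, "query_record"))
  num <- cbind(q$psfm, q$pssm, q$ss3, q$ss8, q$acc)
  lines <- c("# threadcrf query profile v1",
             paste0("# length ", q$length),
             "# columns: pos aa psfm*20 pssm*20 ss3*3 ss8*8 acc*3",
             paste(seq_len(q$length), q$chars,
                   apply(num, 1, function(r)
                     paste(formatC(r, format = "g", digits = 10), collapse = " "))))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_query
#' @export
read_query <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ncol_expected <- 2 + 20 + 20 + 3 + 8 + 3
  for (k in seq_along(parts))
    if (length(parts[[k]]) != ncol_expected)
      stop("query profile parse error at row ", k, ": expected ",
           ncol_expected, " fields, got ", length(parts[[k]]))
  aa <- vapply(parts, `[`, "", 2)
  num <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]),
                  numeric(ncol_expected - 2)))
  if (any(!is.finite(num))) stop("query profile contains non-finite values")
  query_record(paste(aa, collapse = ""),
               psfm = num[, 1:20, drop = FALSE],
               pssm = num[, 21:40, drop = FALSE],
               ss3 = num[, 41:43, drop = FALSE],
               ss8 = num[, 44:51, drop = FALSE],
               acc = num[, 52:54, drop = FALSE])
}

#' Write / read a template record
#'
#' The coordinates go to a PDB file (one CB pseudo-atom per residue, written
#' as CA for glycine) and the labels to a small text meta file; reading
#' recomputes the distance matrix from the coordinates.
#'
#' @param t a [template_record()].
#' @param pdb_file,meta_file paths.
#' @return `read_template` returns a [template_record()].
#' @export
write_template <- function(t, pdb_file, meta_file) {
  stopifnot(inherits(t, "template_record"))
  n <- t$length
  elety <- ifelse(t$chars == "G", "CA", "CB")
  resid <- bio3d::aa123(ifelse(t$chars %in% AA20, t$chars, "A"))
  resid[!t$chars %in% AA20] <- "UNK"
  bio3d::write.pdb(file = pdb_file, xyz = as.numeric(t(t$coords_cb)),
                   resno = seq_len(n), resid = resid, eleno = seq_len(n),
                   elety = elety, chain = rep("A", n))
  writeLines(c("# threadcrf template meta v1",
               "# columns: pos aa ss3 ss8 acc",
               paste(seq_len(n), t$chars, t$ss3, t$ss8,
                     formatC(t$acc, format = "g", digits = 10))),
             meta_file)
  invisible(c(pdb_file, meta_file))
}

#' @rdname write_template
#' @export
read_template <- function(pdb_file, meta_file) {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  ## CB per residue; CA where no CB exists (glycine)
  coords <- NULL
  for (rn in unique(at$resno)) {
    rows <- at[at$resno == rn, ]
    hit <- rows[rows$elety == "CB", ]
    if (nrow(hit) == 0L) hit <- rows[rows$elety == "CA", ]
    if (nrow(hit) == 0L) stop("residue ", rn, " has neither CB nor CA atom")
    coords <- rbind(coords, as.numeric(hit[1, c("x", "y", "z")]))
  }
  lines <- readLines(meta_file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  for (k in seq_along(parts))
    if (length(parts[[k]]) != 5L)
      stop("template meta parse error at row ", k)
  if (length(parts) != nrow(coords))
    stop("template meta has ", length(parts), " rows but PDB has ",
         nrow(coords), " residues")
  aa <- vapply(parts, `[`, "", 2)
  template_record(paste(aa, collapse = ""), coords,
                  ss3 = vapply(parts, `[`, "", 3),
                  ss8 = vapply(parts, `[`, "", 4),
                  acc = as.numeric(vapply(parts, `[`, "", 5)))
}

#' Write / read a distance distribution or potential tensor
#'
#' Stored as an RDS container (binary, portable across platforms).
#'
#' @param x array or `distance_potential`.
#' @param file path.
#' @export
write_dist_tensor <- function(x, file) { saveRDS(x, file); invisible(file) }

#' @rdname write_dist_tensor
#' @export
read_dist_tensor <- function(file) readRDS(file)

#' Write / read an alignment in the three-line text format
#'
#' The record is: optional `#`-comment header lines (carrying `n1`, `n2` and,
#' when available, the decoder score and log partition function), then the
#' gapped template row, the gapped query row, and the state string over
#' `{M, X, Y, H, T}`.  The two gapped rows make the record lossless (the
#' state string alone does not say which protein a flank-gap step consumes).
#'
#' @param a a valid `protein_alignment`.
#' @param file path (or connection).
#' @param template_seq,query_seq sequences; `X` placeholders when omitted.
#' @param score,logZ optional numbers recorded in the header.
#' @return `read_alignment` returns the alignment with attributes
#'   `template_row`, `query_row` and any header numbers.
#' @export
write_alignment <- function(a, file, template_seq = NULL, query_seq = NULL,
                            score = NULL, logZ = NULL) {
  validate_alignment(a)
  tch <- if (is.null(template_seq)) rep("X", a$n1) else .check_seq(template_seq, "template")
  qch <- if (is.null(query_seq)) rep("X", a$n2) else .check_seq(query_seq, "query")
  stopifnot(length(tch) == a$n1, length(qch) == a$n2)
  trow <- ifelse(a$triples$i >= 0L, tch[a$triples$i + 1L], "-")
  qrow <- ifelse(a$triples$j >= 0L, qch[a$triples$j + 1L], "-")
  hdr <- sprintf("# threadcrf alignment n1=%d n2=%d", a$n1, a$n2)
  if (!is.null(score)) hdr <- paste0(hdr, sprintf(" score=%.10g", score))
  if (!is.null(logZ)) hdr <- paste0(hdr, sprintf(" logZ=%.10g", logZ))
  writeLines(c(hdr, paste(trow, collapse = ""), paste(qrow, collapse = ""),
               as_state_string(a)), file)
  invisible(file)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(file) {
  lines <- readLines(file)
  hdr <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) != 3L) stop("alignment record must have exactly 3 body lines")
  trow <- strsplit(body[1], "")[[1]]
  qrow <- strsplit(body[2], "")[[1]]
  st <- strsplit(body[3], "")[[1]]
  if (length(trow) != length(st) || length(qrow) != length(st))
    stop("alignment rows and state string differ in length")
  n1 <- sum(trow != "-"); n2 <- sum(qrow != "-")
  smap <- c(M = "M", X = "Ix", Y = "Iy", H = "Gh", T = "Gt")
  if (any(!st %in% names(smap))) stop("unknown state letter in state string")
  ic <- cumsum(trow != "-"); jc <- cumsum(qrow != "-")
  a <- alignment(data.frame(i = ifelse(trow != "-", ic - 1L, -1L),
                            j = ifelse(qrow != "-", jc - 1L, -1L),
                            state = unname(smap[st])), n1, n2)
  attr(a, "template_row") <- body[1]
  attr(a, "query_row") <- body[2]
  for (key in c("score", "logZ")) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    m <- unlist(m)
    if (length(m)) attr(a, key) <- as.numeric(sub(paste0(key, "="), "", m[1]))
  }
  a
}

#' Export a pairwise alignment as A3M-style FASTA
#'
#' Two records with the template as master: the template sequence is written
#' ungapped in upper case; the query carries an upper-case residue or `-` in
#' every template column and lower-case residues for insertions relative to
#' the template.
#'
#' @param a a valid `protein_alignment`.
#' @param file path.
#' @param template_seq,query_seq residue strings.
#' @param ids record identifiers.
#' @export
write_pair_fasta <- function(a, file, template_seq, query_seq,
                             ids = c("template", "query")) {
  validate_alignment(a)
  tch <- .check_seq(template_seq, "template")
  qch <- .check_seq(query_seq, "query")
  stopifnot(length(tch) == a$n1, length(qch) == a$n2)
  qa3m <- character(0)
  for (k in seq_len(nrow(a$triples))) {
    tri <- a$triples[k, ]
    if (tri$state == "M") {
      qa3m <- c(qa3m, toupper(qch[tri$j + 1L]))
    } else if (tri$i >= 0L) {
      qa3m <- c(qa3m, "-")                     # template column, query gapped
    } else {
      qa3m <- c(qa3m, tolower(qch[tri$j + 1L])) # query insertion
    }
  }
  writeLines(c(paste0(">", ids[1]), paste(tch, collapse = ""),
               paste0(">", ids[2]), paste(qa3m, collapse = "")), file)
  invisible(file)
}
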