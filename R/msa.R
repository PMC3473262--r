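# Multiple alignment of protease domains.
#
# The module aligns the eligible protease-domain sequences with its own
# progressive aligner (guide tree from pairwise alignment distances,
# profile-profile merges by affine-gap dynamic programming), runs it under
# two or more scoring parameterisations, and keeps only the alignment
# columns on which every run agrees (an automated, conservative surrogate
# for manual consensus curation).  Gapped columns are then stripped before
# tree inference.

GAP_CHAR <- "-"

#' Multiple alignment container
#'
#' A character matrix over the amino-acid alphabet plus `-`, one row per
#' sequence; all rows have equal length and de-gapping a row reproduces the
#' input sequence.
#'
#' @param x character matrix with row names, or a named character vector of
#'   equal-length gapped sequences.
#' @return object of class `deg_msa`.
#' @export
deg_msa <- function(x) {
  if (is.character(x) && is.null(dim(x)))
    return(msa_from_strings(x))
  if (is.null(rownames(x))) stop("alignment rows must be named")
  structure(x, class = "deg_msa")
}

msa_from_strings <- function(strings) {
  stopifnot(!is.null(names(strings)), length(unique(nchar(strings))) == 1L)
  m <- do.call(rbind, strsplit(unname(strings), ""))
  rownames(m) <- names(strings)
  structure(m, class = "deg_msa")
}

#' @export
print.deg_msa <- function(x, ...) {
  cat("Multiple alignment:", nrow(x), "sequences x", ncol(x), "columns\n")
  show <- unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE]
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %-12s %s%s\n", rownames(show)[i],
                paste(show[i, seq_len(min(50L, ncol(show)))], collapse = ""),
                if (ncol(show) > 50L) "..." else ""))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' De-gap one alignment row back to its input sequence
#'
#' @param msa a `deg_msa`.
#' @param id row name.
#' @export
degap <- function(msa, id) {
  r <- unclass(msa)[id, ]
  paste(r[r != GAP_CHAR], collapse = "")
}

msa_strings <- function(msa)
  apply(unclass(msa), 1L, paste, collapse = "")

#' Mask low-complexity single-residue repeats
#'
#' Long single amino-acid repeats (10-20 aa runs occur in some green-alga
#' gene models) degrade alignment quality; maximal runs of one identical
#' residue at least `min_run` long are replaced by X and marginalised
#' downstream.
#'
#' @param sequence amino-acid string.
#' @param min_run minimum run length to mask (default 10, `>= 2`).
#' @export
mask_low_complexity <- function(sequence, min_run = 10L) {
  stopifnot(min_run >= 2L)
  chars <- strsplit(sequence, "")[[1L]]
  r <- rle(chars)
  mask <- r$lengths >= min_run
  r$values[mask] <- "X"
  paste(inverse.rle(r), collapse = "")
}

#' BLOSUM62 substitution scores over the 20-residue alphabet plus X
#'
#' Taken from the Biostrings substitution-matrix data; the X row/column is
#' overridden to score 0 against everything (masked residues are neutral).
#'
#' @return symmetric 21x21 integer matrix.
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA20, AA20]
  m <- cbind(m, X = 0L)
  m <- rbind(m, X = 0L)
  m
}

#' Affine gap penalties
#'
#' A gap run of length k costs `open + k * extend`.
#'
#' @param open,extend non-negative; `open >= extend`.
#' @export
gap_penalties <- function(open = 10, extend = 1) {
  stopifnot(open >= 0, extend >= 0, open >= extend)
  structure(list(open = open, extend = extend), class = "deg_gap_penalties")
}

#' Optimal global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch with affine gaps; the score is the sum of substitution
#' scores minus the total gap-run costs.  Ties are broken deterministically
#' (match preferred over a gap in `b`, preferred over a gap in `a`).
#'
#' @param a,b amino-acid strings (may contain X; X scores 0).
#' @param m substitution matrix (default [blosum62_matrix()]).
#' @param g a [gap_penalties()].
#' @return list with `a`, `b` (gapped aligned strings) and `score`.
#' @export
global_affine_align <- function(a, b, m = blosum62_matrix(),
                                g = gap_penalties()) {
  ca <- seq_to_codes(a)
  cb <- seq_to_codes(b)
  if (length(ca) == 0L && length(cb) == 0L)
    return(list(a = "", b = "", score = 0))
  if (length(ca) == 0L)
    return(list(a = strrep(GAP_CHAR, length(cb)), b = b,
                score = -(g$open + length(cb) * g$extend)))
  if (length(cb) == 0L)
    return(list(a = a, b = strrep(GAP_CHAR, length(ca)),
                score = -(g$open + length(ca) * g$extend)))
  S <- m[AA_ALPHABET21[ca], AA_ALPHABET21[cb], drop = FALSE]
  r <- affine_dp_cpp(matrix(S, length(ca), length(cb)), g$open, g$extend)
  av <- ifelse(r$a == 0L, GAP_CHAR, AA_ALPHABET21[ca][pmax(r$a, 1L)])
  bv <- ifelse(r$b == 0L, GAP_CHAR, AA_ALPHABET21[cb][pmax(r$b, 1L)])
  list(a = paste(av, collapse = ""), b = paste(bv, collapse = ""),
       score = r$score)
}

#' Guide tree for progressive alignment
#'
#' Neighbor-joining tree on normalised pairwise alignment distances
#' d = 1 - identity, where identity is computed over aligned non-gap pairs
#' of the optimal global alignment.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @inheritParams global_affine_align
#' @return a `phylo` guide tree whose tips are the sequence names.
#' @export
build_guide_tree <- function(seqs, m = blosum62_matrix(),
                             g = gap_penalties()) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences for a guide tree")
  ids <- names(seqs)
  if (n == 2L) {
    aln <- global_affine_align(seqs[[1L]], seqs[[2L]], m, g)
    d <- 1 - alignment_identity(aln$a, aln$b)
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", ids[1L], d / 2,
                                         ids[2L], d / 2)))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- global_affine_align(seqs[[i]], seqs[[j]], m, g)
    D[i, j] <- D[j, i] <- 1 - alignment_identity(aln$a, aln$b)
  }
  neighbor_joining(D)
}

alignment_identity <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  ok <- av != GAP_CHAR & bv != GAP_CHAR
  if (!any(ok)) return(0)
  mean(av[ok] == bv[ok])
}

#' Progressive multiple alignment
#'
#' Merges sequence profiles in post-order over the guide tree; the score of
#' aligning two profile columns is the mean pairwise substitution score over
#' their residues (gaps contribute 0), and merges use the same affine-gap
#' dynamic programme as the pairwise aligner.  De-gapping any output row
#' reproduces its input sequence.
#'
#' @param seqs named character vector.
#' @param guide a `phylo` guide tree with `names(seqs)` as tips; defaults to
#'   [build_guide_tree()].
#' @inheritParams global_affine_align
#' @return a `deg_msa`.
#' @export
progressive_align <- function(seqs, guide = NULL, m = blosum62_matrix(),
                              g = gap_penalties()) {
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) == 1L) return(msa_from_strings(seqs))
  if (is.null(guide)) guide <- build_guide_tree(seqs, m, g)
  if (!setequal(guide$tip.label, names(seqs)))
    stop("guide tree tips do not match sequence ids")
  # traverse merges in post-order over the (possibly multifurcating) guide
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    if (!length(kids)) {
      id <- guide$tip.label[node]
      return(matrix(strsplit(seqs[[id]], "")[[1L]], nrow = 1L,
                    dimnames = list(id, NULL)))
    }
    profs <- lapply(kids, merge_node)
    acc <- profs[[1L]]
    for (k in seq_along(profs)[-1L])
      acc <- merge_profiles(acc, profs[[k]], m, g)
    acc
  }
  root <- setdiff(guide$edge[, 1L], guide$edge[, 2L])[1L]
  out <- merge_node(root)
  out <- out[names(seqs)[names(seqs) %in% rownames(out)], , drop = FALSE]
  structure(out, class = "deg_msa")
}

merge_profiles <- function(A, B, m, g) {
  S <- profile_score_matrix(A, B, m)
  r <- affine_dp_cpp(S, g$open, g$extend)
  L <- length(r$a)
  out <- matrix(GAP_CHAR, nrow(A) + nrow(B), L,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  out[seq_len(nrow(A)), r$a != 0L] <- A[, r$a[r$a != 0L], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), r$b != 0L] <- B[, r$b[r$b != 0L],
                                                  drop = FALSE]
  out
}

# Mean pairwise column score via residue-count matrices: gaps contribute 0,
# so S = (Ca %*% M %*% t(Cb)) / (nA * nB) with residue counts Ca, Cb.
profile_score_matrix <- function(A, B, m) {
  M <- m[AA_ALPHABET21, AA_ALPHABET21]
  count_cols <- function(P) {
    C <- matrix(0, ncol(P), 21L)
    for (k in seq_len(21L))
      C[, k] <- colSums(P == AA_ALPHABET21[k])
    C
  }
  (count_cols(A) %*% M %*% t(count_cols(B))) / (nrow(A) * nrow(B))
}

#' Consensus of several alignments of the same sequences
#'
#' Automated surrogate for manual discrepancy resolution: a column is
#' retained only when every input alignment contains a column inducing the
#' identical residue-residue homology (the same residues, by serial index
#' within each sequence, aligned together).  Retained columns keep their
#' input order.
#'
#' @param alignments list of `deg_msa` over the same row ids and underlying
#'   sequences.
#' @return a `deg_msa` of the agreed columns.
#' @export
consensus_merge <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  ids <- rownames(alignments[[1L]])
  for (a in alignments) {
    if (!identical(sort(rownames(a)), sort(ids)))
      stop("alignments have differing row sets")
  }
  for (a in alignments[-1L]) {
    s1 <- vapply(ids, function(i) degap(alignments[[1L]], i), "")
    s2 <- vapply(ids, function(i) degap(a, i), "")
    if (!identical(s1, s2))
      stop("alignments are not over the same underlying sequences")
  }
  sigs <- lapply(alignments, function(a) column_signatures(a, ids))
  keep <- sigs[[1L]] %in% Reduce(intersect, sigs)
  if (!any(keep))
    stop("no alignment column is shared by all runs; relax the scoring ",
         "parameterisations or use fewer runs")
  out <- unclass(alignments[[1L]])[ids, keep, drop = FALSE]
  structure(out, class = "deg_msa")
}

# Signature of a column: which rows hold a residue there, and the serial
# index of that residue within its (de-gapped) sequence.
column_signatures <- function(a, ids) {
  M <- unclass(a)[ids, , drop = FALSE]
  idx <- t(apply(M != GAP_CHAR, 1L, cumsum))
  vapply(seq_len(ncol(M)), function(j) {
    r <- which(M[, j] != GAP_CHAR)
    paste(ids[r], idx[r, j], sep = ":", collapse = "|")
  }, "")
}

#' Remove gapped alignment columns
#'
#' Drops columns whose gap fraction exceeds `max_gap_frac`; the default 0
#' removes every column containing any gap.  The map of kept columns is
#' attached as attribute `kept_columns`.
#'
#' @param msa a `deg_msa`.
#' @param max_gap_frac tolerated gap fraction per column, in `[0, 1]`.
#' @return a `deg_msa` with attribute `kept_columns` (original indices).
#' @export
strip_gap_columns <- function(msa, max_gap_frac = 0) {
  stopifnot(max_gap_frac >= 0, max_gap_frac <= 1)
  M <- unclass(msa)
  frac <- colMeans(M == GAP_CHAR)
  keep <- which(frac <= max_gap_frac)
  out <- structure(M[, keep, drop = FALSE], class = "deg_msa")
  attr(out, "kept_columns") <- keep
  out
}

#' Read / write alignments (gapped FASTA or relaxed PHYLIP)
#'
#' @param msa a `deg_msa`.
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed: name, whitespace,
#'   sequence on one line).
#' @export
write_alignment <- function(msa, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  s <- msa_strings(msa)
  if (format == "fasta") {
    write_alignment_fasta(s, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(s), nchar(s[[1L]])), con)
    writeLines(sprintf("%-12s %s", names(s), s), con)
  }
  invisible(path)
}

write_alignment_fasta <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(s)[i]), con)
    writeLines(s[[i]], con)
  }
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    s <- toupper(as.character(set))
    names(s) <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  } else {
    lines <- readLines(path)
    body <- strsplit(trimws(lines[-1L]), "[ \t]+")
    s <- setNames(vapply(body, `[`, "", 2L), vapply(body, `[`, "", 1L))
  }
  msa_from_strings(s)
}
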