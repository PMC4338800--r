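#' BLOSUM62 substitution matrix
#'
#' Fetches the BLOSUM62 matrix shipped with Biostrings (cached after first
#' use).
#'
#' @return integer substitution matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.tmr_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tmr_cache$BLOSUM62 <- e$BLOSUM62
  }
  .tmr_cache$BLOSUM62
}

#' Optimal global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment of two residue strings. A gap of
#' length L costs `|gap_open| + L * |gap_extend|`. Traceback ties are
#' broken deterministically: match/mismatch over gap-in-`a` over
#' gap-in-`b`.
#'
#' @param a,b non-empty residue strings.
#' @param matrix substitution score matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap scores (negative; defaults -10 / -1).
#' @return a list with `score` and `alignment` (character vector of the two
#'   gapped rows).
#' @export
pairwise_global <- function(a, b, matrix = blosum62(),
                            gap_open = -10, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) .stopf("pairwise_global requires non-empty sequences")
  ca <- .chars(a); cb <- .chars(b)
  known <- rownames(matrix)
  bad <- setdiff(unique(c(ca, cb)), known)
  if (length(bad)) .stopf("unknown residue symbol '%s'", bad[[1L]])
  S <- matrix[ca, cb, drop = FALSE]
  res <- .gotoh_path(S, abs(gap_open), abs(gap_extend),
                     rep(1, length(ca)), rep(1, length(cb)))
  path <- res$path
  out_a <- rep("-", length(path)); out_b <- rep("-", length(path))
  out_a[path != 2L] <- ca
  out_b[path != 3L] <- cb
  list(score = res$score,
       alignment = c(paste(out_a, collapse = ""), paste(out_b, collapse = "")))
}

# --- built-in progressive aligner ------------------------------------------

# shared-3-mer guide distances (the standard fast proxy used by large-scale
# aligners); deterministic.
.kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  all_k <- unique(unlist(km))
  idx <- lapply(km, function(x) match(x, all_k))
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(idx)),
    j = unlist(idx), x = 1,
    dims = c(n, length(all_k)))
  common <- as.matrix(Matrix::tcrossprod(inc))
  sizes <- lengths(km)
  denom <- outer(sizes, sizes, pmin)
  d <- 1 - common / denom
  diag(d) <- 0
  d
}

# column frequency profile over the 20 amino acids (gaps and ambiguity
# codes contribute zero weight), as a 20 x width matrix
.profile_freq <- function(mat) {
  w <- ncol(mat); n <- nrow(mat)
  f <- matrix(0, length(.AA20), w, dimnames = list(.AA20, NULL))
  for (aa in .AA20) f[aa, ] <- colSums(mat == aa)
  f / n
}

.merge_profiles <- function(matA, matB, S20, gap_open, gap_extend) {
  fA <- .profile_freq(matA)
  fB <- .profile_freq(matB)
  # column scores use gap-normalized residue frequencies (profile-SP
  # scoring), so a sparsely occupied column scores like the residues it
  # actually holds; gap penalties are weighted by column occupancy, so gaps
  # stay cheap in regions that are already gap-rich (variable loops) and
  # expensive inside conserved blocks. Together these keep the helices in
  # register across merges.
  occA <- pmax(colSums(fA), 1e-12)
  occB <- pmax(colSums(fB), 1e-12)
  CS <- crossprod(fA, S20 %*% fB)
  res <- .gotoh_path(CS, abs(gap_open), abs(gap_extend), occA, occB)
  path <- res$path
  out <- matrix("-", nrow(matA) + nrow(matB), length(path))
  out[seq_len(nrow(matA)), path != 2L] <- matA
  out[nrow(matA) + seq_len(nrow(matB)), path != 3L] <- matB
  rownames(out) <- c(rownames(matA), rownames(matB))
  out
}

.align_builtin <- function(records, submat = blosum62(),
                           gap_open = -10, gap_extend = -1) {
  S20 <- submat[.AA20, .AA20]
  ids <- records$id
  seqs <- records$residues
  # ambiguity codes carry no profile weight; replace for charwise work is
  # unnecessary -- they simply score zero in profiles
  rowmats <- lapply(seq_along(ids), function(i) {
    m <- matrix(.chars(seqs[[i]]), nrow = 1L)
    rownames(m) <- ids[[i]]
    m
  })
  if (length(rowmats) == 1L) return(new_msa(rowmats[[1L]]))
  if (length(rowmats) == 2L) {
    merged <- .merge_profiles(rowmats[[1L]], rowmats[[2L]], S20,
                              gap_open, gap_extend)
    return(new_msa(merged[ids, , drop = FALSE]))
  }
  d <- .kmer_distance(seqs)
  dimnames(d) <- list(ids, ids)
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) rowmats[[-x]] else nodes[[x]]
    nodes[[i]] <- .merge_profiles(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L]),
                                  S20, gap_open, gap_extend)
  }
  final <- nodes[[length(nodes)]]
  new_msa(final[ids, , drop = FALSE])
}

# --- external adapter -------------------------------------------------------

.align_external <- function(records, command) {
  tool <- strsplit(trimws(command), "\\s+")[[1L]][[1L]]
  if (!nzchar(Sys.which(tool))) {
    .stopf("external alignment adapter '%s' not found on PATH", tool)
  }
  tmp <- tempfile("tmrefine_aln_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  infile <- file.path(tmp, "input.fasta")
  outfile <- file.path(tmp, "output.fasta")
  write_fasta(records, infile)
  status <- system(paste(command, shQuote(infile), ">", shQuote(outfile),
                         "2>", shQuote(file.path(tmp, "stderr.log"))))
  if (status != 0L) .stopf("external aligner '%s' exited with status %d", tool, status)
  aligned <- Biostrings::readBStringSet(outfile)
  ids <- sub("\\s.*$", "", names(aligned))
  rows <- toupper(as.character(aligned))
  names(rows) <- ids
  if (!setequal(ids, records$id)) .stopf("external aligner dropped or renamed sequences")
  msa <- .msa_from_rows(records$id, unname(rows[records$id]))
  got <- degap(msa)
  if (!identical(unname(got), unname(toupper(records$residues)))) {
    .stopf("external aligner corrupted sequence content (degap invariant violated)")
  }
  msa
}

#' Align sequence records into a multiple sequence alignment
#'
#' The built-in backend is a deterministic progressive aligner: a UPGMA
#' guide tree over shared-3-mer distances, with profile-profile extension
#' of the affine-gap pairwise aligner ([pairwise_global()]) and BLOSUM62
#' scores. The external backend (`"external:<command>"`) shells out to any
#' tool that accepts an input FASTA path as final argument and writes
#' aligned FASTA to stdout (e.g. `"external:mafft --auto --quiet"`); its
#' output is verified against the degap invariant on every call and the
#' temporary directory is discarded on failure.
#'
#' @param records sequence-record data.frame with at least 1 row (a single
#'   record yields an identity alignment with a warning).
#' @param backend `"builtin"` or `"external:<command>"`.
#' @param submat,gap_open,gap_extend scoring parameters for the built-in
#'   backend.
#' @return a `tm_msa`; row order equals input order.
#' @export
align <- function(records, backend = "builtin", submat = blosum62(),
                  gap_open = -10, gap_extend = -0.15) {
  .check_records(records)
  if (nrow(records) == 0L) .stopf("no sequences to align")
  if (anyDuplicated(records$id)) .stopf("duplicate id %s", records$id[duplicated(records$id)][[1L]])
  if (nrow(records) == 1L) {
    .warnf("single sequence: returning identity alignment")
    m <- matrix(.chars(records$residues[[1L]]), nrow = 1L)
    rownames(m) <- records$id
    return(new_msa(m))
  }
  if (identical(backend, "builtin")) {
    msa <- .align_builtin(records, submat, gap_open, gap_extend)
  } else if (startsWith(backend, "external:")) {
    msa <- .align_external(records, sub("^external:", "", backend))
  } else {
    .stopf("unknown alignment backend '%s'", backend)
  }
  got <- degap(msa)
  want <- setNames(toupper(records$residues), records$id)
  if (!identical(got[records$id], want)) {
    .stopf("internal error: degap invariant violated by backend '%s'", backend)
  }
  msa
}
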