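#' Project per-residue domain labels through alignment gaps
#'
#' @param msa a `tm_msa`.
#' @param labels named list of per-residue label vectors (E/M/I/U), one per
#'   alignment row, each as long as the row's ungapped sequence.
#' @return character matrix of the alignment's shape with labels at residue
#'   positions and `"-"` at gaps.
#' @export
project_labels <- function(msa, labels) {
  m <- msa$matrix
  out <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    id <- rownames(m)[[i]]
    lab <- labels[[id]]
    if (is.null(lab)) .stopf("no labels for sequence %s", id)
    resid <- m[i, ] != "-"
    if (sum(resid) != length(lab)) {
      .stopf("label track length mismatch for %s (%d labels, %d residues)",
             id, length(lab), sum(resid))
    }
    out[i, resid] <- lab
  }
  out
}

#' Consensus structural domain of one alignment column
#'
#' Gaps and U (unassigned) labels are treated as missing; the consensus is
#' the unique argmax of the E/M/I counts, and U when all counts are zero or
#' the maximum is tied.
#'
#' @param column_labels character vector of labels (`E`/`M`/`I`/`U`/`-`)
#'   for one column, one entry per alignment row.
#' @return single label, one of `"E"`, `"M"`, `"I"`, `"U"`.
#' @export
column_consensus <- function(column_labels) {
  counts <- c(E = sum(column_labels == "E"),
              M = sum(column_labels == "M"),
              I = sum(column_labels == "I"))
  mx <- max(counts)
  if (mx == 0L || sum(counts == mx) > 1L) return("U")
  names(counts)[which.max(counts)]
}

#' Per-column consensus profile of a labeled alignment
#'
#' @param label_mat aligned label matrix from [project_labels()].
#' @return an object of class `tm_consensus_profile`: a data.frame with
#'   columns `column`, `consensus`, `n_E`, `n_M`, `n_I`. The number of
#'   U-consensus columns is reported by `print()`.
#' @export
consensus_profile <- function(label_mat) {
  nE <- colSums(label_mat == "E")
  nM <- colSums(label_mat == "M")
  nI <- colSums(label_mat == "I")
  mx <- pmax(nE, nM, nI)
  ties <- (nE == mx) + (nM == mx) + (nI == mx)
  cons <- c("E", "M", "I")[max.col(cbind(nE, nM, nI), ties.method = "first")]
  cons[mx == 0L | ties > 1L] <- "U"
  structure(data.frame(column = seq_along(cons), consensus = cons,
                       n_E = nE, n_M = nM, n_I = nI, row.names = NULL),
            class = c("tm_consensus_profile", "data.frame"))
}

#' @export
print.tm_consensus_profile <- function(x, ...) {
  cat(sprintf("<tm_consensus_profile> %d columns (M: %d, E: %d, I: %d, U/unassigned: %d)\n",
              nrow(x), sum(x$consensus == "M"), sum(x$consensus == "E"),
              sum(x$consensus == "I"), sum(x$consensus == "U")))
  invisible(x)
}

#' Structural discordance of one aligned sequence against the consensus
#'
#' Evaluable residues are non-gap positions with an assigned (non-U) label
#' sitting in columns whose consensus is itself assigned; a residue is
#' discordant when its label differs from its column's consensus. The
#' default denominator is the evaluable residue count; `"columns"` divides
#' the same discordant count by the alignment width instead.
#'
#' @param row_labels aligned label vector for one row (with `"-"` at gaps).
#' @param consensus consensus label vector (same length) or a
#'   `tm_consensus_profile`.
#' @param denominator `"residues"` (default) or `"columns"`.
#' @return list with `fraction`, `discordant`, `evaluable`. Zero evaluable
#'   residues yield fraction 0 with a warning.
#' @export
sequence_discordance <- function(row_labels, consensus,
                                 denominator = c("residues", "columns")) {
  denominator <- match.arg(denominator)
  if (inherits(consensus, "tm_consensus_profile")) consensus <- consensus$consensus
  if (length(row_labels) != length(consensus)) {
    .stopf("label row length %d != profile length %d",
           length(row_labels), length(consensus))
  }
  ev <- row_labels %in% c("E", "M", "I") & consensus != "U"
  disc <- sum(ev & row_labels != consensus)
  n_ev <- sum(ev)
  if (denominator == "residues") {
    if (n_ev == 0L) {
      .warnf("sequence has no evaluable residues; discordance set to 0")
      return(list(fraction = 0, discordant = 0L, evaluable = 0L))
    }
    frac <- disc / n_ev
  } else {
    frac <- disc / length(consensus)
  }
  list(fraction = frac, discordant = disc, evaluable = n_ev)
}

# vectorized discordance report over all rows
.discordance_report <- function(label_mat, consensus, denominator = "residues") {
  cons <- if (inherits(consensus, "tm_consensus_profile")) consensus$consensus else consensus
  cons_mat <- matrix(cons, nrow(label_mat), ncol(label_mat), byrow = TRUE)
  ev <- (label_mat == "E" | label_mat == "M" | label_mat == "I") & cons_mat != "U"
  disc <- rowSums(ev & label_mat != cons_mat)
  n_ev <- rowSums(ev)
  frac <- if (denominator == "residues") {
    ifelse(n_ev == 0L, 0, disc / pmax(n_ev, 1L))
  } else {
    disc / ncol(label_mat)
  }
  data.frame(id = rownames(label_mat), discordant = disc, evaluable = n_ev,
             fraction = frac, row.names = NULL, stringsAsFactors = FALSE)
}

#' One culling pass: remove sequences at or above the discordance threshold
#'
#' @param msa a `tm_msa`.
#' @param label_mat aligned label matrix ([project_labels()]).
#' @param threshold discordance threshold in (0, 1]; removal uses `>=`.
#' @param denominator see [sequence_discordance()].
#' @return list with `removed` (data.frame `id`, `fraction`), `retained`
#'   (degapped sequence records ready for re-alignment) and `report` (the
#'   full per-sequence discordance data.frame). Removing every sequence is
#'   an error.
#' @export
cull_pass <- function(msa, label_mat, threshold = 0.05,
                      denominator = c("residues", "columns")) {
  denominator <- match.arg(denominator)
  if (!(threshold > 0 && threshold <= 1)) .stopf("threshold must lie in (0, 1]")
  prof <- consensus_profile(label_mat)
  rep <- .discordance_report(label_mat, prof, denominator)
  out <- rep$fraction >= threshold
  if (all(out)) .stopf("no sequences survive culling")
  seqs <- degap(msa)
  retained <- sequence_records(rep$id[!out], unname(seqs[rep$id[!out]]))
  list(removed = rep[out, c("id", "fraction")],
       retained = retained,
       report = rep)
}

#' Iteratively refine an alignment by consensus-domain culling
#'
#' Implements the align / project-labels / consensus / cull loop: sequences
#' whose discordance against the per-column consensus domain reaches the
#' threshold are removed in a batch, the survivors are re-aligned from
#' scratch, and the process repeats until a pass removes nothing. The
#' sequence count strictly decreases between passes, so convergence is
#' guaranteed; a guard errors beyond `max_iter` iterations.
#'
#' @param records sequence-record data.frame (at least 2 rows).
#' @param annotation a `tm_domain_annotation` covering the record ids, or a
#'   pre-computed named list of per-residue label vectors.
#' @param threshold discordance removal threshold (default 0.05, `>=`
#'   semantics).
#' @param cutoff posterior cutoff for label assignment (default 0.5).
#' @param backend alignment backend passed to [align()].
#' @param denominator see [sequence_discordance()].
#' @param max_iter iteration guard (default: number of records + 1).
#' @param verbose print per-iteration progress.
#' @return an object of class `tm_refinement`: list with `alignment`
#'   (final `tm_msa`), `labels` (final aligned label matrix), `profile`
#'   (final `tm_consensus_profile`), `report` (final per-sequence
#'   discordance) and `audit` (per-iteration bookkeeping with removed ids
#'   and fractions, plus `iterations` and `converged`).
#' @export
iterative_refine <- function(records, annotation, threshold = 0.05,
                             cutoff = 0.5, backend = "builtin",
                             denominator = c("residues", "columns"),
                             max_iter = nrow(records) + 1L, verbose = FALSE) {
  denominator <- match.arg(denominator)
  .check_records(records)
  if (nrow(records) < 2L) .stopf("iterative refinement needs at least 2 sequences")
  if (inherits(annotation, "tm_domain_annotation")) {
    labels <- lapply(records$id, function(id) {
      p <- annotation$posteriors[[id]]
      if (is.null(p)) .stopf("no posterior track for %s", id)
      assign_domains(p, cutoff)
    })
    names(labels) <- records$id
  } else {
    labels <- annotation
  }
  current <- records
  iterations <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) .stopf("internal error: refinement exceeded %d iterations", max_iter)
    msa <- align(current, backend = backend)
    label_mat <- project_labels(msa, labels)
    prof <- consensus_profile(label_mat)
    rep <- .discordance_report(label_mat, prof, denominator)
    out <- rep$fraction >= threshold
    if (all(out)) .stopf("no sequences survive culling")
    iterations[[iter]] <- list(
      n_input = nrow(current),
      removed = rep[out, c("id", "fraction")],
      n_output = sum(!out))
    if (verbose) {
      message(sprintf("iteration %d: %d in, %d removed", iter,
                      nrow(current), sum(out)))
    }
    if (!any(out)) break
    current <- current[match(rep$id[!out], current$id), , drop = FALSE]
  }
  structure(list(alignment = msa, labels = label_mat, profile = prof,
                 report = rep,
                 audit = list(iterations = iterations,
                              total_iterations = iter,
                              converged = TRUE,
                              threshold = threshold,
                              denominator = denominator)),
            class = "tm_refinement")
}

#' @export
print.tm_refinement <- function(x, ...) {
  n_rm <- sum(vapply(x$audit$iterations, function(it) nrow(it$removed), 1L))
  cat(sprintf("<tm_refinement> %d sequences retained (%d culled) in %d iteration(s)\n",
              nrow(x$alignment$matrix), n_rm, x$audit$total_iterations))
  invisible(x)
}

#' Mask residues discordant with their column's consensus domain
#'
#' A residue is replaced by `'?'` exactly when it carries an assigned
#' label, its column's consensus is assigned, and the two differ. Gaps,
#' U-labeled residues, and residues in U-consensus columns are untouched.
#' The original residues are retained inside the returned object so that
#' [unmask()] / [degap()] recover the aligner's inputs.
#'
#' @param msa a `tm_msa`.
#' @param label_mat aligned label matrix ([project_labels()]).
#' @param profile a `tm_consensus_profile` (recomputed from `label_mat`
#'   when omitted).
#' @return an object of class `tm_masked_msa`.
#' @export
mask_discordant <- function(msa, label_mat, profile = NULL) {
  m <- msa$matrix
  stopifnot(identical(dim(m), dim(label_mat)))
  if (is.null(profile)) profile <- consensus_profile(label_mat)
  cons_mat <- matrix(profile$consensus, nrow(m), ncol(m), byrow = TRUE)
  mask <- (label_mat == "E" | label_mat == "M" | label_mat == "I") &
    cons_mat != "U" & label_mat != cons_mat
  out <- m
  out[mask] <- "?"
  structure(list(matrix = out, mask = mask, original = m,
                 consensus = profile$consensus),
            class = "tm_masked_msa")
}

#' Extract the TM/EM column partition scheme from a consensus profile
#'
#' TM collects the columns whose consensus domain is transmembrane (M); EM
#' (extramembrane) collects everything else — extracellular, intracellular,
#' and unassigned consensus columns. Unassigned columns are counted in the
#' `"n_unassigned"` attribute and assigned to EM (the weaker-constraint
#' class) so the scheme covers every column; a warning reports an all-U
#' profile.
#'
#' @param profile a `tm_consensus_profile`.
#' @return a `tm_partition_scheme` with partitions `TM` and `EM`.
#' @export
extract_partitions <- function(profile) {
  stopifnot(inherits(profile, "tm_consensus_profile"), nrow(profile) > 0L)
  cons <- profile$consensus
  tm_cols <- which(cons == "M")
  em_cols <- which(cons != "M")
  if (length(tm_cols) == 0L) {
    .warnf("no TM-consensus columns; all %d columns assigned to EM", length(cons))
  }
  scheme <- partition_scheme(TM = tm_cols, EM = em_cols)
  attr(scheme, "n_unassigned") <- sum(cons == "U")
  scheme
}

# parse a residue-class pattern ([DE]RY, NP..Y, ...) into a fixed-width
# anchored regular expression; '.' matches any amino acid but never '?'
.parse_motif_pattern <- function(pattern) {
  chars <- .chars(pattern)
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[[j]] != "]") j <- j + 1L
      if (j > length(chars)) .stopf("malformed pattern '%s': unclosed '['", pattern)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(inner) || grepl("[^A-Z]", inner)) {
        .stopf("malformed pattern '%s': bad class '[%s]'", pattern, inner)
      }
      tokens <- c(tokens, sprintf("[%s]", inner))
      i <- j + 1L
    } else if (ch == ".") {
      tokens <- c(tokens, "[A-Z]")
      i <- i + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      .stopf("malformed pattern '%s': unexpected character '%s'", pattern, ch)
    }
  }
  if (length(tokens) == 0L) .stopf("empty motif pattern")
  list(regex = paste0("^", paste(tokens, collapse = ""), "$"),
       width = length(tokens))
}

#' Locate a conserved sequence motif in alignment columns
#'
#' Scans every window of consecutive columns whose width matches the
#' pattern and reports the windows in which at least `min_fraction` of the
#' gap-free rows match. Patterns are residue-class patterns: literal amino
#' acids, `[..]` classes and `.` wildcards (e.g. `"[DE]RY"`, `"NP..Y"`).
#' Masked (`'?'`) residues never match, and rows with a gap inside the
#' window are excluded from the denominator.
#'
#' @param msa a `tm_msa` or `tm_masked_msa`.
#' @param pattern residue-class pattern string.
#' @param min_fraction minimum fraction of gap-free rows that must match
#'   (default 0.5).
#' @return data.frame with 1-based inclusive `start`, `end` columns,
#'   `fraction`, `n_match`, `n_evaluable`; zero rows when the motif is
#'   absent.
#' @export
locate_motif <- function(msa, pattern, min_fraction = 0.5) {
  pat <- .parse_motif_pattern(pattern)
  m <- msa$matrix
  k <- pat$width
  W <- ncol(m)
  hits <- list()
  if (W >= k) {
    for (s in seq_len(W - k + 1L)) {
      win <- m[, s:(s + k - 1L), drop = FALSE]
      gapfree <- rowSums(win == "-") == 0L
      n_ev <- sum(gapfree)
      if (n_ev == 0L) next
      strs <- do.call(paste0, as.data.frame(win[gapfree, , drop = FALSE],
                                            stringsAsFactors = FALSE))
      n_match <- sum(grepl(pat$regex, strs))
      frac <- n_match / n_ev
      if (frac >= min_fraction) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s, end = s + k - 1L, fraction = frac,
          n_match = n_match, n_evaluable = n_ev)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      fraction = numeric(0), n_match = integer(0),
                      n_evaluable = integer(0)))
  }
  do.call(rbind, hits)
}
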