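#' Read protein sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of the header (RefSeq
#' style); the remainder of the header line becomes the description.
#' Residues are uppercased and validated against the amino-acid alphabet
#' (20 residues plus B/X/Z).
#'
#' @param path FASTA file path.
#' @return a sequence-record `data.frame` (see [sequence_records()]), in
#'   file order. An empty file yields an empty data.frame with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (file.info(path)$size == 0L) {
    .warnf("empty FASTA file: %s", path)
    return(sequence_records(character(0), character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate id %s", dup[[1L]])
  sequence_records(ids, as.character(set), desc)
}

#' Write sequence records (or an alignment) to FASTA
#'
#' @param x a sequence-record data.frame, a `tm_msa`, or a
#'   `tm_masked_msa`.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "tm_msa") || inherits(x, "tm_masked_msa")) {
    seqs <- apply(x$matrix, 1L, paste, collapse = "")
    headers <- rownames(x$matrix)
  } else {
    .check_records(x)
    seqs <- x$residues
    headers <- ifelse(nzchar(x$description),
                      paste(x$id, x$description), x$id)
    names(seqs) <- NULL
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a per-residue domain-annotation table
#'
#' The table emulates the per-residue output of a membrane-topology
#' annotator: for every sequence, one row per residue carrying the
#' posterior probabilities of the extracellular (`p_ext`), transmembrane
#' (`p_mem`) and intracellular (`p_int`) states, plus a companion table of
#' per-sequence global and local classifier scores.
#'
#' The main file is a TSV with header
#' `seq_id pos residue p_ext p_mem p_int`; the companion scores file is a
#' TSV with header `seq_id global_score local_score`. Positions must be
#' 1-based, contiguous and ascending, and each posterior triple must sum to
#' 1 within `1e-6`.
#'
#' @param path path of the per-residue TSV.
#' @param scores_path path of the companion scores TSV. Defaults to
#'   `<path minus extension>_scores.tsv`.
#' @return an object of class `tm_domain_annotation`: a list with
#'   `posteriors` (named list of n x 3 matrices with columns
#'   `p_ext`, `p_mem`, `p_int`), `residues` (named list of per-residue
#'   character vectors) and `scores` (data.frame `seq_id`, `global_score`,
#'   `local_score`).
#' @export
read_domain_table <- function(path,
                              scores_path = sub("\\.[^.]+$", "_scores.tsv", path)) {
  main <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "pos", "residue", "p_ext", "p_mem", "p_int")
  if (!all(need %in% names(main))) {
    .stopf("domain table must have columns: %s", paste(need, collapse = " "))
  }
  scores <- read.delim(scores_path, stringsAsFactors = FALSE)
  if (!all(c("seq_id", "global_score", "local_score") %in% names(scores))) {
    .stopf("scores table must have columns: seq_id global_score local_score")
  }
  split_rows <- split(main, main$seq_id)
  posteriors <- list(); residues <- list()
  for (id in names(split_rows)) {
    rows <- split_rows[[id]]
    rows <- rows[order(rows$pos), , drop = FALSE]
    if (!identical(as.integer(rows$pos), seq_len(nrow(rows)))) {
      .stopf("non-contiguous positions for %s", id)
    }
    p <- as.matrix(rows[, c("p_ext", "p_mem", "p_int")])
    if (any(abs(rowSums(p) - 1) > 1e-6)) {
      .stopf("posteriors do not sum to 1 for %s", id)
    }
    if (any(p < -1e-12 | p > 1 + 1e-12)) {
      .stopf("posterior outside [0,1] for %s", id)
    }
    dimnames(p) <- list(NULL, c("p_ext", "p_mem", "p_int"))
    posteriors[[id]] <- p
    residues[[id]] <- toupper(rows$residue)
  }
  domain_annotation(posteriors, scores, residues)
}

#' Construct a domain-annotation object in memory
#'
#' @param posteriors named list of n x 3 posterior matrices (columns
#'   ext/mem/int order).
#' @param scores data.frame with columns `seq_id`, `global_score`,
#'   `local_score`.
#' @param residues optional named list of per-residue character vectors.
#' @return a `tm_domain_annotation` object; see [read_domain_table()].
#' @export
domain_annotation <- function(posteriors, scores, residues = NULL) {
  stopifnot(is.list(posteriors), is.data.frame(scores))
  for (id in names(posteriors)) {
    p <- posteriors[[id]]
    stopifnot(is.matrix(p), ncol(p) == 3L)
    if (any(abs(rowSums(p) - 1) > 1e-6)) .stopf("posteriors do not sum to 1 for %s", id)
  }
  structure(list(posteriors = posteriors, scores = scores, residues = residues),
            class = "tm_domain_annotation")
}

#' @export
print.tm_domain_annotation <- function(x, ...) {
  cat(sprintf("<tm_domain_annotation> %d sequences, %d residues total\n",
              length(x$posteriors), sum(vapply(x$posteriors, nrow, 1L))))
  invisible(x)
}

#' Write a domain-annotation object to its TSV dialect
#'
#' Posteriors are written with enough digits to round-trip to `1e-9`.
#'
#' @param annotation a `tm_domain_annotation`.
#' @param path main TSV path; the scores companion goes to
#'   `<path minus extension>_scores.tsv` unless overridden.
#' @param scores_path companion scores TSV path.
#' @param records optional sequence records supplying residue letters when
#'   the annotation has none.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(annotation, path,
                               scores_path = sub("\\.[^.]+$", "_scores.tsv", path),
                               records = NULL) {
  stopifnot(inherits(annotation, "tm_domain_annotation"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("seq_id\tpos\tresidue\tp_ext\tp_mem\tp_int", con)
  for (id in names(annotation$posteriors)) {
    p <- annotation$posteriors[[id]]
    res <- annotation$residues[[id]]
    if (is.null(res) && !is.null(records)) {
      res <- .chars(records$residues[match(id, records$id)])
    }
    if (is.null(res)) res <- rep("X", nrow(p))
    writeLines(sprintf("%s\t%d\t%s\t%.10g\t%.10g\t%.10g",
                       id, seq_len(nrow(p)), res, p[, 1L], p[, 2L], p[, 3L]), con)
  }
  sc <- annotation$scores
  con2 <- file(scores_path, "w")
  on.exit(close(con2), add = TRUE)
  writeLines("seq_id\tglobal_score\tlocal_score", con2)
  writeLines(sprintf("%s\t%.10g\t%.10g", sc$seq_id, sc$global_score,
                     sc$local_score), con2)
  invisible(path)
}

#' Write a partition scheme as a RAxML-style partition file
#'
#' One line per partition, format
#' `"<model_tag>, <name> = <a>-<b>[, <a>-<b>...]"` with ascending,
#' maximally-merged 1-based inclusive ranges; single columns render as
#' `a-a`. Empty partitions are omitted.
#'
#' @param scheme a `tm_partition_scheme`.
#' @param model_tag substitution-model tag written before each partition
#'   name (e.g. `"LG"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(scheme, model_tag, path) {
  stopifnot(inherits(scheme, "tm_partition_scheme"))
  if (length(scheme) == 0L) .stopf("empty partition scheme")
  lines <- character(0)
  for (nm in names(scheme)) {
    r <- scheme[[nm]]
    if (nrow(r) == 0L) next
    lines <- c(lines, sprintf("%s, %s = %s", model_tag, nm,
                              paste(sprintf("%d-%d", r[, 1L], r[, 2L]),
                                    collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a partition file written by [write_partition_file()]
#'
#' @param path partition file path.
#' @return a `tm_partition_scheme`; the model tag is attached as attribute
#'   `"model_tag"`.
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- list()
  tag <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^,]+),\\s*(\\S+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 4L) .stopf("malformed partition line: %s", ln)
    tag <- trimws(m[[2L]])
    nm <- m[[3L]]
    pieces <- strsplit(m[[4L]], ",")[[1L]]
    rr <- lapply(trimws(pieces), function(p) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab)) .stopf("malformed range '%s'", p)
      seq.int(ab[[1L]], ab[[2L]])
    })
    parts[[nm]] <- unlist(rr)
  }
  out <- partition_scheme(parts)
  attr(out, "model_tag") <- tag
  out
}

#' Read a Newick tree and attach leaf annotations
#'
#' Internal node support values, when present in the Newick string, are
#' preserved (as `phylo$node.label`). Leaves absent from the label map are
#' annotated `"unlabeled"` with a warning.
#'
#' @param path Newick file path.
#' @param label_map named character vector mapping leaf id to annotation.
#' @param vocabulary optional reference vocabulary of valid classes.
#' @return a `tm_labeled_tree`.
#' @export
read_newick_labeled <- function(path, label_map, vocabulary = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) .stopf("unmatched ')' at character offset %d", i)
    }
  }
  if (depth != 0L) .stopf("unmatched '(' in Newick string (%d unclosed)", depth)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) .stopf("failed to parse Newick file %s", path)
  labeled_tree(tree, label_map, vocabulary = vocabulary)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' Relaxed PHYLIP: a header line `"<n> <width>"` followed by one
#' `"<id>  <row>"` line per sequence (ids of any length, no column
#' truncation). The alphabet is amino acids plus `'-'` and `'?'`, which is
#' what partitioned phylogenetics engines consume for masked alignments.
#'
#' @param x a `tm_msa` or `tm_masked_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_relaxed <- function(x, path) {
  m <- x$matrix
  rows <- apply(m, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(sprintf("%s  %s", rownames(m), rows), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment written by [write_phylip_relaxed()]
#'
#' @param path file path.
#' @return a character matrix (rows = sequences, possibly containing `'?'`),
#'   with rownames set to the ids. Returned as a plain matrix rather than a
#'   `tm_msa` because masked rows no longer degap to their input sequences.
#' @export
read_phylip_relaxed <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) .stopf("malformed PHYLIP header")
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != hdr[[1L]]) {
    .stopf("PHYLIP header promises %d sequences, found %d", hdr[[1L]], length(body))
  }
  fields <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  ids <- vapply(fields, `[[`, character(1L), 2L)
  rows <- vapply(fields, `[[`, character(1L), 3L)
  if (any(nchar(rows) != hdr[[2L]])) .stopf("PHYLIP row width mismatch")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  mat
}
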