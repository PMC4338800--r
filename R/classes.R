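#' Construct a set of sequence records
#'
#' Sequence records are the raw (unaligned) unit of the pipeline: a unique
#' id, a free-text description, and a residue string over the 20 amino acids
#' plus the ambiguity codes B, X, Z. Gap characters are not allowed.
#'
#' @param id character vector of unique, non-empty ids.
#' @param residues character vector of residue strings (uppercased).
#' @param description free-text descriptions (recycled if length 1).
#' @return a `data.frame` with columns `id`, `description`, `residues`.
#' @export
sequence_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(description) == 1L) description <- rep(description, length(id))
  if (any(!nzchar(id))) .stopf("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) .stopf("duplicate id %s", dup[[1L]])
  if (any(!nzchar(residues))) {
    .stopf("empty residue string for id %s", id[!nzchar(residues)][[1L]])
  }
  bad <- grepl(sprintf("[^%s]", paste(c(.AA20, .AMBIG), collapse = "")), residues)
  if (any(bad)) {
    .stopf("id %s contains characters outside the amino-acid alphabet (20 residues + B/X/Z)",
           id[bad][[1L]])
  }
  data.frame(id = id, description = as.character(description),
             residues = residues, stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "description", "residues") %in% names(records)))
  invisible(records)
}

#' Construct a multiple sequence alignment object
#'
#' An alignment is stored as a character matrix of single characters
#' (residues plus `'-'`), with row names holding the sequence ids. At
#' creation time every row must degap to a non-empty sequence and no column
#' may consist entirely of gaps.
#'
#' @param mat character matrix; rows are sequences, columns are alignment
#'   columns, rownames are the (unique) sequence ids.
#' @return an object of class `tm_msa`.
#' @export
new_msa <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat))
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids))) .stopf("alignment rows must be named by sequence id")
  if (anyDuplicated(ids)) .stopf("duplicate id %s in alignment", ids[duplicated(ids)][[1L]])
  if (ncol(mat) > 0L && any(colSums(mat != "-") == 0L)) {
    .stopf("alignment contains an all-gap column")
  }
  structure(list(matrix = mat), class = "tm_msa")
}

#' @export
print.tm_msa <- function(x, ...) {
  cat(sprintf("<tm_msa> %d sequences x %d columns\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
as.matrix.tm_msa <- function(x, ...) x$matrix

#' Alignment dimensions and ids
#' @param x a `tm_msa` (or `tm_masked_msa`).
#' @return `msa_width()`: the number of columns; `msa_ids()`: sequence ids.
#' @export
msa_width <- function(x) ncol(x$matrix)

#' @rdname msa_width
#' @export
msa_ids <- function(x) rownames(x$matrix)

#' Remove gaps (and masking) from alignment rows
#'
#' @param x a `tm_msa` or `tm_masked_msa`.
#' @return named character vector of ungapped sequences. For a masked
#'   alignment the stored original residues are restored first, so
#'   `degap(masked)` always reproduces the aligner's input sequences.
#' @export
degap <- function(x) UseMethod("degap")

#' @export
degap.tm_msa <- function(x) {
  m <- x$matrix
  out <- vapply(seq_len(nrow(m)), function(i) {
    paste(m[i, m[i, ] != "-"], collapse = "")
  }, character(1L))
  names(out) <- rownames(m)
  out
}

#' @export
degap.tm_masked_msa <- function(x) degap(unmask(x))

# build an msa from id + aligned-row strings
.msa_from_rows <- function(ids, rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  new_msa(mat)
}

#' Restore the residues hidden by discordance masking
#'
#' @param x a `tm_masked_msa` as produced by [mask_discordant()].
#' @return the unmasked `tm_msa`.
#' @export
unmask <- function(x) {
  stopifnot(inherits(x, "tm_masked_msa"))
  m <- x$matrix
  m[x$mask] <- x$original[x$mask]
  new_msa(m)
}

#' @export
print.tm_masked_msa <- function(x, ...) {
  cat(sprintf("<tm_masked_msa> %d sequences x %d columns, %d residues masked\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$mask)))
  invisible(x)
}

#' Construct a partition scheme
#'
#' A partition scheme maps partition names (here TM and EM) to disjoint sets
#' of 1-based inclusive column ranges. Used to drive partitioned
#' phylogenetic inference, where transmembrane and extramembrane columns
#' receive independent substitution models.
#'
#' @param ... named range matrices (two columns `start`, `end`) or integer
#'   vectors of column indices.
#' @return an object of class `tm_partition_scheme` (named list of merged,
#'   ascending range matrices).
#' @export
partition_scheme <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.matrix(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  if (is.null(names(parts)) || any(!nzchar(names(parts)))) {
    .stopf("all partitions must be named")
  }
  parts <- lapply(parts, function(p) {
    if (is.matrix(p)) merge_ranges(.expand_ranges(p)) else merge_ranges(p)
  })
  cols <- lapply(parts, .expand_ranges)
  all_cols <- unlist(cols, use.names = FALSE)
  if (anyDuplicated(all_cols)) {
    .stopf("partitions overlap at column %d", all_cols[duplicated(all_cols)][[1L]])
  }
  structure(parts, class = "tm_partition_scheme")
}

#' @export
print.tm_partition_scheme <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("%s: %s\n", nm,
                if (nrow(r) == 0L) "(empty)" else
                  paste(sprintf("%d-%d", r[, 1L], r[, 2L]), collapse = ", ")))
  }
  invisible(x)
}

#' Construct a labeled tree
#'
#' A phylogenetic tree together with per-leaf annotation strings (receptor
#' class names), the optional reference vocabulary of valid classes, and
#' optional ground truth (for simulated trees).
#'
#' @param tree an [ape::read.tree()] `phylo` object.
#' @param annotations named character vector, one annotation per leaf id.
#'   Leaves absent from the vector are annotated `"unlabeled"`.
#' @param vocabulary optional character vector of valid class names.
#' @param truth optional data.frame of simulation ground truth.
#' @return an object of class `tm_labeled_tree`.
#' @export
labeled_tree <- function(tree, annotations, vocabulary = NULL, truth = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) .stopf("duplicate leaf id %s", tips[duplicated(tips)][[1L]])
  ann <- rep("unlabeled", length(tips))
  names(ann) <- tips
  hit <- intersect(tips, names(annotations))
  ann[hit] <- annotations[hit]
  missing <- setdiff(tips, names(annotations))
  if (length(missing)) {
    .warnf("%d leaves missing from the label map, annotated 'unlabeled' (first: %s)",
           length(missing), missing[[1L]])
  }
  structure(list(tree = tree, annotations = ann, vocabulary = vocabulary,
                 truth = truth),
            class = "tm_labeled_tree")
}

#' @export
print.tm_labeled_tree <- function(x, ...) {
  cat(sprintf("<tm_labeled_tree> %d leaves, %d annotation classes\n",
              length(x$tree$tip.label), length(unique(x$annotations))))
  invisible(x)
}
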