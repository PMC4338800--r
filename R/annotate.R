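#' Filtering policy for sequence retention
#'
#' Bundles the thresholds of the sequence-retention filters. Defaults
#' follow the conservative screening used for receptor datasets: a 0.5
#' posterior cutoff for per-residue domain assignment, classifier scores of
#' at least 10 (both local and global), at most 1% ambiguous residues, and
#' rejection of descriptions flagged as partial/low-quality/pseudogene.
#'
#' Boundary semantics are literal: a posterior exactly at the cutoff is
#' assigned; a score exactly at `min_score` is kept (only "less than"
#' discards); an ambiguous fraction exactly at `max_ambiguous_fraction` is
#' kept (only "more than" discards).
#'
#' @param posterior_cutoff posterior-probability cutoff in (1/3, 1].
#' @param min_score minimum local and global classifier score.
#' @param max_ambiguous_fraction maximum tolerated fraction of B/X/Z
#'   residues, in \[0, 1\].
#' @param banned_keywords lowercase substrings that disqualify a
#'   description.
#' @param taxon_allowlist optional character vector; when non-NULL a record
#'   is kept only if its description contains one of these strings
#'   (case-insensitive). Stands in for taxonomy-service filtering.
#' @return an object of class `tm_filter_policy`.
#' @export
filter_policy <- function(posterior_cutoff = 0.5,
                          min_score = 10,
                          max_ambiguous_fraction = 0.01,
                          banned_keywords = c("partial", "low quality", "pseudogene"),
                          taxon_allowlist = NULL) {
  if (!(posterior_cutoff > 1 / 3 && posterior_cutoff <= 1)) {
    .stopf("posterior_cutoff must lie in (1/3, 1]")
  }
  if (max_ambiguous_fraction < 0 || max_ambiguous_fraction > 1) {
    .stopf("max_ambiguous_fraction must lie in [0, 1]")
  }
  structure(list(posterior_cutoff = posterior_cutoff,
                 min_score = min_score,
                 max_ambiguous_fraction = max_ambiguous_fraction,
                 banned_keywords = tolower(banned_keywords),
                 taxon_allowlist = taxon_allowlist),
            class = "tm_filter_policy")
}

#' Assign per-residue structural-domain labels from posterior tracks
#'
#' Each residue is labeled with the domain of maximum posterior
#' probability — E (extracellular), M (transmembrane) or I (intracellular) —
#' provided that maximum reaches the cutoff; residues below the cutoff, or
#' with a tie at the maximum, are labeled U (unassigned) and treated as
#' missing downstream.
#'
#' @param posteriors n x 3 matrix of (p_ext, p_mem, p_int) triples on the
#'   probability simplex.
#' @param cutoff posterior cutoff (default 0.5); a maximum exactly equal to
#'   the cutoff is assigned.
#' @return character vector of labels in `c("E", "M", "I", "U")`.
#' @export
assign_domains <- function(posteriors, cutoff = 0.5) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, ncol = 3L)
  if (nrow(posteriors) == 0L) return(character(0))
  stopifnot(ncol(posteriors) == 3L)
  if (any(abs(rowSums(posteriors) - 1) > 1e-6)) {
    .stopf("posterior triples must sum to 1")
  }
  classes <- c("E", "M", "I")
  mx <- pmax(posteriors[, 1L], posteriors[, 2L], posteriors[, 3L])
  n_at_max <- (posteriors[, 1L] == mx) + (posteriors[, 2L] == mx) +
    (posteriors[, 3L] == mx)
  lab <- classes[max.col(posteriors, ties.method = "first")]
  lab[mx < cutoff | n_at_max > 1L] <- "U"
  lab
}

#' Validate a sequence as a genuine receptor by classifier scores
#'
#' A sequence is discarded when either its local or its global score falls
#' strictly below `min_score`; equality keeps the sequence.
#'
#' @param global_score,local_score per-sequence classifier scores.
#' @param min_score score threshold (default 10).
#' @return a list with `keep` (logical) and `reasons` (character vector,
#'   empty when kept).
#' @export
validate_gpcr <- function(global_score, local_score, min_score = 10) {
  reasons <- character(0)
  if (global_score < min_score) {
    reasons <- c(reasons, sprintf("global score %.4g below %.4g", global_score, min_score))
  }
  if (local_score < min_score) {
    reasons <- c(reasons, sprintf("local score %.4g below %.4g", local_score, min_score))
  }
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Apply sequence-quality filters to a single record
#'
#' Discards a record when its fraction of ambiguous residues (B, X or Z)
#' strictly exceeds the policy maximum, when its description contains a
#' banned keyword (case-insensitive substring), or when a taxon allow-list
#' is configured and no allowed taxon string occurs in the description. All
#' triggered reasons are reported.
#'
#' @param record one-row sequence-record data.frame.
#' @param policy a [filter_policy()].
#' @return a list with `keep` (logical) and `reasons`.
#' @export
filter_quality <- function(record, policy = filter_policy()) {
  reasons <- character(0)
  res <- record$residues[[1L]]
  n <- nchar(res)
  n_ambig <- n - nchar(gsub("[BXZ]", "", res))
  frac <- n_ambig / n
  if (frac > policy$max_ambiguous_fraction) {
    reasons <- c(reasons, sprintf("ambiguous fraction %.4g > %.4g",
                                  frac, policy$max_ambiguous_fraction))
  }
  desc <- tolower(record$description[[1L]])
  for (kw in policy$banned_keywords) {
    if (grepl(kw, desc, fixed = TRUE)) {
      reasons <- c(reasons, sprintf("keyword: %s", kw))
    }
  }
  if (!is.null(policy$taxon_allowlist)) {
    hit <- any(vapply(tolower(policy$taxon_allowlist),
                      function(t) grepl(t, desc, fixed = TRUE), logical(1L)))
    if (!hit) reasons <- c(reasons, "taxon not in allow-list")
  }
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Filter a dataset and annotate retained sequences
#'
#' Applies [filter_quality()] and [validate_gpcr()] to every record, then
#' assigns per-residue domain labels to the survivors.
#'
#' @param records sequence-record data.frame.
#' @param annotation a `tm_domain_annotation` covering (at least) the
#'   record ids.
#' @param policy a [filter_policy()].
#' @return a list with `records` (retained), `labels` (named list of
#'   per-residue label vectors), `discarded` (data.frame `id`, `reason`).
#' @export
annotate_sequences <- function(records, annotation, policy = filter_policy()) {
  .check_records(records)
  keep <- logical(nrow(records))
  discarded <- list()
  scores <- annotation$scores
  for (i in seq_len(nrow(records))) {
    id <- records$id[[i]]
    q <- filter_quality(records[i, , drop = FALSE], policy)
    reasons <- q$reasons
    si <- match(id, scores$seq_id)
    if (is.na(si)) {
      reasons <- c(reasons, "no classifier scores")
    } else {
      v <- validate_gpcr(scores$global_score[[si]], scores$local_score[[si]],
                         policy$min_score)
      reasons <- c(reasons, v$reasons)
    }
    if (!id %in% names(annotation$posteriors)) {
      reasons <- c(reasons, "no posterior track")
    } else if (nrow(annotation$posteriors[[id]]) != nchar(records$residues[[i]])) {
      reasons <- c(reasons, "posterior track length mismatch")
    }
    keep[[i]] <- length(reasons) == 0L
    if (!keep[[i]]) {
      discarded[[id]] <- data.frame(id = id, reason = paste(reasons, collapse = "; "),
                                    stringsAsFactors = FALSE)
    }
  }
  kept <- records[keep, , drop = FALSE]
  labels <- lapply(kept$id, function(id) {
    assign_domains(annotation$posteriors[[id]], policy$posterior_cutoff)
  })
  names(labels) <- kept$id
  list(records = kept,
       labels = labels,
       discarded = if (length(discarded)) do.call(rbind, discarded) else
         data.frame(id = character(0), reason = character(0)))
}
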