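#' Describe a fitted phylogenetic model
#'
#' @param log_likelihood model log-likelihood.
#' @param free_parameters non-negative integer count of free parameters.
#' @param description free text (e.g. "unpartitioned LG+CAT").
#' @return an object of class `tm_model_fit`.
#' @export
model_fit <- function(log_likelihood, free_parameters, description = "") {
  stopifnot(is.numeric(log_likelihood), length(log_likelihood) == 1L)
  free_parameters <- as.integer(free_parameters)
  if (is.na(free_parameters) || free_parameters < 0L) {
    .stopf("free_parameters must be a non-negative integer")
  }
  structure(list(log_likelihood = log_likelihood,
                 free_parameters = free_parameters,
                 description = description),
            class = "tm_model_fit")
}

#' Likelihood ratio test between nested phylogenetic models
#'
#' Compares a richer (alternative) model against a nested null model:
#' statistic `2 * (lnL_alt - lnL_null)`, degrees of freedom equal to the
#' difference in free-parameter counts, and an upper-tail chi-square
#' p-value. This is the standard comparison of a structurally partitioned
#' against an unpartitioned inference, where the extra partition
#' contributes its own equilibrium frequencies and rate parameters.
#'
#' @param fit_null,fit_alt [model_fit()] objects; `fit_alt` must have more
#'   free parameters, and its log-likelihood may not fall below the null's
#'   by more than `1e-6`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "tm_model_fit"), inherits(fit_alt, "tm_model_fit"))
  if (fit_alt$free_parameters <= fit_null$free_parameters ||
      fit_alt$log_likelihood < fit_null$log_likelihood - 1e-6) {
    .stopf("models not nested or misordered")
  }
  stat <- max(0, 2 * (fit_alt$log_likelihood - fit_null$log_likelihood))
  df <- fit_alt$free_parameters - fit_null$free_parameters
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

# children / descendant-tip bookkeeping for a phylo object
.tree_maps <- function(tree) {
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  parent <- integer(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
    parent[[ch]] <- p
  }
  root <- n + 1L
  list(desc = desc, parent = parent, root = root, n_tip = n, tree = tree)
}

# candidate enclosing groups for tip `tip`, smallest first:
# rooted tree  -> descendant sets of its ancestors;
# unrooted     -> both sides of every bipartition containing the tip.
.candidate_groups <- function(maps, tip, rooted) {
  if (rooted) {
    out <- list()
    node <- maps$parent[[tip]]
    while (node != 0L) {
      out[[length(out) + 1L]] <- maps$desc[[node]]
      if (node == maps$root) break
      node <- maps$parent[[node]]
    }
    out
  } else {
    all_tips <- seq_len(maps$n_tip)
    sides <- list()
    for (node in (maps$n_tip + 1L):length(maps$desc)) {
      if (node == maps$root) next
      d <- maps$desc[[node]]
      sides[[length(sides) + 1L]] <- if (tip %in% d) d else setdiff(all_tips, d)
    }
    sides <- sides[vapply(sides, length, 1L) < maps$n_tip]
    sides[order(vapply(sides, length, 1L))]
  }
}

#' Scan a labeled tree for annotation-placement discordance
#'
#' Formalizes reclassification-by-placement: for each leaf, the smallest
#' enclosing clade with at least `min_clade` leaves whose non-self,
#' in-vocabulary annotation purity reaches `min_purity` is located; when
#' that clade's majority annotation differs from the leaf's own, a
#' reclassification proposal is emitted. Leaves annotated
#' `"uncharacterized"` (or `"unlabeled"`) always receive the majority
#' annotation of their qualifying clade. Maximal clades of at least
#' `min_clade` leaves whose annotations all fall outside the reference
#' vocabulary are reported as a single group with proposed class
#' `"Unknown"`.
#'
#' Proposals are iterated to a fixpoint: leaves proposed in one pass are
#' excluded from the purity and majority counts of the next, so that a
#' handful of misannotated leaves cannot veto each other's detection by
#' contaminating their shared clades (the same batch-and-iterate logic the
#' alignment culling uses). Clean leaves only gain purity from the
#' exclusion, so the iteration cannot manufacture proposals.
#'
#' For unrooted trees both sides of every bipartition are scanned
#' (covering the clades of all rootings) and a message notes the
#' ambiguity.
#'
#' @param tree a `tm_labeled_tree` (see [labeled_tree()],
#'   [read_newick_labeled()], [simulate_labeled_tree()]).
#' @param min_clade minimum clade size (leaves), default 5.
#' @param min_purity minimum annotation purity in (0.5, 1], default 0.9.
#' @param vocabulary reference class vocabulary; defaults to the tree's
#'   own, else to all observed annotations except
#'   `"unlabeled"`/`"uncharacterized"`.
#' @return data.frame with columns `id`, `current`, `proposed`,
#'   `clade_size`, `purity`, `type` (`"reclassify"` or `"unknown_clade"`)
#'   and `group` (clade index for unknown-clade rows, `NA` otherwise).
#' @export
concordance_scan <- function(tree, min_clade = 5L, min_purity = 0.9,
                             vocabulary = NULL) {
  stopifnot(inherits(tree, "tm_labeled_tree"))
  if (!(min_purity > 0.5)) .stopf("min_purity must exceed 0.5")
  phy <- tree$tree
  ann <- tree$annotations
  vocabulary <- vocabulary %||% tree$vocabulary %||%
    setdiff(unique(ann), c("unlabeled", "uncharacterized"))
  rooted <- ape::is.rooted(phy)
  if (!rooted) {
    message("unrooted tree: scanning both sides of every bipartition")
  }
  maps <- .tree_maps(phy)
  tips <- maps$tree$tip.label
  tip_ann <- unname(ann[tips])
  in_vocab <- tip_ann %in% vocabulary
  special <- tip_ann %in% c("unlabeled", "uncharacterized")
  oov <- !in_vocab & !special

  # maximal all-out-of-vocabulary clades -> "Unknown" group proposals
  proposals <- list()
  oov_member <- rep(NA_integer_, maps$n_tip)
  if (any(oov)) {
    internal <- (maps$n_tip + 1L):length(maps$desc)
    all_oov_node <- vapply(internal, function(nd) all(oov[maps$desc[[nd]]]), logical(1L))
    names(all_oov_node) <- internal
    group_idx <- 0L
    for (nd in internal[all_oov_node]) {
      par <- maps$parent[[nd]]
      parent_all_oov <- par != 0L && par > maps$n_tip &&
        isTRUE(all_oov_node[[as.character(par)]])
      if (parent_all_oov) next  # not maximal
      d <- maps$desc[[nd]]
      if (length(d) < min_clade) next
      group_idx <- group_idx + 1L
      oov_member[d] <- group_idx
      proposals[[length(proposals) + 1L]] <- data.frame(
        id = tips[d], current = tip_ann[d], proposed = "Unknown",
        clade_size = length(d), purity = 1,
        type = "unknown_clade", group = group_idx,
        stringsAsFactors = FALSE)
    }
  }

  scan_pass <- function(excluded) {
    out <- list()
    for (tip in seq_len(maps$n_tip)) {
      if (!is.na(oov_member[[tip]])) next  # already in an Unknown clade
      groups <- .candidate_groups(maps, tip, rooted)
      for (g in groups) {
        if (length(g) < min_clade) next
        others <- setdiff(g, tip)
        inv <- others[in_vocab[others] & !(others %in% excluded)]
        if (length(inv) == 0L) next
        tab <- sort(table(tip_ann[inv]), decreasing = TRUE)
        if (length(tab) > 1L && tab[[1L]] == tab[[2L]]) next  # ambiguous majority
        purity <- tab[[1L]] / length(inv)
        if (purity < min_purity) next
        maj <- names(tab)[[1L]]
        cur <- tip_ann[[tip]]
        if (cur != maj) {
          out[[length(out) + 1L]] <- data.frame(
            id = tips[[tip]], current = cur, proposed = maj,
            clade_size = length(g), purity = purity,
            type = "reclassify", group = NA_integer_,
            stringsAsFactors = FALSE)
        }
        break  # smallest qualifying clade found
      }
    }
    out
  }

  excluded <- integer(0)
  relab <- list()
  for (pass in seq_len(maps$n_tip)) {
    relab <- scan_pass(excluded)
    flagged <- match(vapply(relab, `[[`, "", "id"), tips)
    if (setequal(flagged, excluded)) break
    excluded <- flagged
  }
  proposals <- c(proposals, relab)

  if (length(proposals) == 0L) {
    return(data.frame(id = character(0), current = character(0),
                      proposed = character(0), clade_size = integer(0),
                      purity = numeric(0), type = character(0),
                      group = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, proposals)
  rownames(out) <- NULL
  out
}

#' Default settings manifest for the external tree-inference engine
#'
#' @return named list of engine defaults: LG exchangeabilities, empirical
#'   frequencies, CAT site heterogeneity with 25 rate categories, final
#'   GAMMA optimization, 100 independent searches and 200 bootstrap
#'   replicates.
#' @export
engine_defaults <- function() {
  list(model = "LG",
       frequencies = "empirical",
       site_heterogeneity = "CAT",
       rate_categories = 25L,
       final_optimization = "GAMMA",
       searches = 100L,
       bootstraps = 200L)
}

#' Write the input bundle for an external partitioned tree engine
#'
#' Emits the masked alignment (relaxed PHYLIP), the partition file and a
#' JSON settings manifest with one model block per partition. Columns
#' consisting entirely of `'?'` are engine-hostile and raise an error.
#'
#' @param masked a `tm_masked_msa` (a plain `tm_msa` is accepted).
#' @param scheme a `tm_partition_scheme` covering the alignment columns.
#' @param out_dir output directory (created if needed).
#' @param settings overrides merged over [engine_defaults()].
#' @return named list of written file paths, invisibly.
#' @export
prepare_engine_inputs <- function(masked, scheme, out_dir,
                                  settings = list()) {
  stopifnot(inherits(masked, "tm_masked_msa") || inherits(masked, "tm_msa"))
  m <- masked$matrix
  covered <- sort(unlist(lapply(unclass(scheme), .expand_ranges),
                         use.names = FALSE))
  if (!identical(covered, seq_len(ncol(m)))) {
    .stopf("partition scheme does not exactly cover the %d alignment columns", ncol(m))
  }
  all_q <- colSums(m != "?") == 0L
  if (any(all_q)) {
    .stopf("column %d consists entirely of '?' (engine-hostile input)", which(all_q)[[1L]])
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- modifyList(engine_defaults(), settings)
  aln_path <- file.path(out_dir, "masked_alignment.phy")
  part_path <- file.path(out_dir, "partitions.txt")
  manifest_path <- file.path(out_dir, "engine_settings.json")
  write_phylip_relaxed(masked, aln_path)
  write_partition_file(scheme, cfg$model, part_path)
  manifest <- c(cfg, list(
    partitions = lapply(names(scheme), function(nm) {
      r <- scheme[[nm]]
      list(name = nm, model = cfg$model,
           n_columns = length(.expand_ranges(r)),
           ranges = apply(r, 1L, function(ab) sprintf("%d-%d", ab[[1L]], ab[[2L]])))
    }),
    n_sequences = nrow(m), n_columns = ncol(m)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(alignment = aln_path, partitions = part_path,
                 manifest = manifest_path))
}
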