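# amino-acid emission tables: transmembrane helices are hydrophobic-biased,
# loops follow a generic globular background
.TM_FREQ <- c(A = 0.11, C = 0.02, D = 0.005, E = 0.005, F = 0.09, G = 0.07,
              H = 0.01, I = 0.12, K = 0.005, L = 0.16, M = 0.04, N = 0.01,
              P = 0.02, Q = 0.01, R = 0.005, S = 0.05, T = 0.05, V = 0.12,
              W = 0.03, Y = 0.04)
.BG_FREQ <- c(A = 0.078, C = 0.019, D = 0.053, E = 0.063, F = 0.039,
              G = 0.072, H = 0.023, I = 0.053, K = 0.059, L = 0.091,
              M = 0.022, N = 0.043, P = 0.052, Q = 0.042, R = 0.051,
              S = 0.068, T = 0.059, V = 0.066, W = 0.014, Y = 0.032)

# segment order of the seven-transmembrane architecture: extracellular
# N-terminus, 7 TM helices alternating with intracellular/extracellular
# loops, intracellular C-terminus
.SEGMENTS <- c("nterm", "tm1", "icl1", "tm2", "ecl1", "tm3", "icl2",
               "tm4", "ecl2", "tm5", "icl3", "tm6", "ecl3", "tm7", "cterm")
.SEG_LABEL <- c(nterm = "E", tm1 = "M", icl1 = "I", tm2 = "M", ecl1 = "E",
                tm3 = "M", icl2 = "I", tm4 = "M", ecl2 = "E", tm5 = "M",
                icl3 = "I", tm6 = "M", ecl3 = "E", tm7 = "M", cterm = "I")

#' Specification of a synthetic seven-transmembrane receptor family set
#'
#' Defines the study conditions the generator emulates: several receptor
#' families sharing one ancestral TM architecture (TM helices are strongly
#' conserved across the whole receptor superfamily) while loop lengths vary
#' widely and family-specifically, as real receptor families do (ECL3/ICL3
#' lengths differ by an order of magnitude between families).
#'
#' @param n_families number of families (default 5).
#' @param members_per_family sequences per family (default 40).
#' @param tm_length_range TM helix length range in residues (default
#'   18-28), drawn once for the shared ancestral architecture.
#' @param loop_length_ranges named list of per-loop residue-count ranges;
#'   lengths are drawn per family. Defaults keep short inner loops and
#'   wide, family-specific ICL3/ECL3 (14-120 and 10-120).
#' @param substitution_rate expected substitutions per site per unit branch
#'   length within a family (default 0.1).
#' @param family_divergence per-site substitution probability between the
#'   shared ancestor and each family ancestor's TM helices (default 0.15).
#' @param loop_redraw_prob probability, per member and loop, that the loop
#'   length is redrawn from the family range (loop indels; default 0.1).
#' @param annotator_confidence expected posterior mass on the true domain
#'   in the emulated annotator output (default 0.95).
#' @param motif_plants list of motifs planted in the ancestor and shielded
#'   from substitution; each entry has `pattern` (residue-class pattern
#'   whose literal positions are planted) and `anchor` (`"tm3_end"` or
#'   `"tm7_end"`). Defaults plant the E/DRY motif at the TM3/ICL2 boundary
#'   and NPxxY at the TM7/C-terminus boundary.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return an object of class `tm_family_spec`.
#' @export
family_spec <- function(n_families = 5L,
                        members_per_family = 40L,
                        tm_length_range = c(18L, 28L),
                        loop_length_ranges = list(
                          nterm = c(10L, 40L), icl1 = c(5L, 12L),
                          ecl1 = c(4L, 10L), icl2 = c(8L, 16L),
                          ecl2 = c(10L, 25L), icl3 = c(14L, 120L),
                          ecl3 = c(10L, 120L), cterm = c(10L, 40L)),
                        substitution_rate = 0.1,
                        family_divergence = 0.15,
                        loop_redraw_prob = 0.1,
                        annotator_confidence = 0.95,
                        motif_plants = list(
                          list(pattern = "[DE]RY", anchor = "tm3_end"),
                          list(pattern = "NP..Y", anchor = "tm7_end")),
                        seed = 1L) {
  loops <- setdiff(names(.SEG_LABEL), paste0("tm", 1:7))
  if (!all(loops %in% names(loop_length_ranges))) {
    .stopf("loop_length_ranges must name all of: %s", paste(loops, collapse = ", "))
  }
  ranges <- c(list(tm = tm_length_range), loop_length_ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[[1L]] > r[[2L]] || r[[1L]] < 1L) {
      .stopf("impossible length range for %s", nm)
    }
  }
  if (substitution_rate < 0) .stopf("substitution_rate must be >= 0")
  if (!(annotator_confidence > 1 / 3 && annotator_confidence <= 1)) {
    .stopf("annotator_confidence must lie in (1/3, 1]")
  }
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 tm_length_range = as.integer(tm_length_range),
                 loop_length_ranges = loop_length_ranges,
                 substitution_rate = substitution_rate,
                 family_divergence = family_divergence,
                 loop_redraw_prob = loop_redraw_prob,
                 annotator_confidence = annotator_confidence,
                 motif_plants = motif_plants,
                 seed = as.integer(seed)),
            class = "tm_family_spec")
}

.draw_seq <- function(n, freq) sample(names(freq), n, replace = TRUE, prob = freq)

# point substitutions, domain-preserving emission, protected sites skipped
.mutate_segment <- function(chars, p, freq, protect = integer(0)) {
  hit <- which(runif(length(chars)) < p)
  hit <- setdiff(hit, protect)
  if (length(hit)) chars[hit] <- .draw_seq(length(hit), freq)
  chars
}

# literal positions (and their letters) of a motif pattern; class positions
# take the first letter of the class, '.' positions are unconstrained
.motif_letters <- function(pattern) {
  chars <- .chars(pattern)
  letters_out <- character(0)
  fixed <- logical(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (chars[[j]] != "]") j <- j + 1L
      letters_out <- c(letters_out, chars[[i + 1L]])
      fixed <- c(fixed, TRUE)
      i <- j + 1L
    } else if (ch == ".") {
      letters_out <- c(letters_out, NA_character_)
      fixed <- c(fixed, FALSE)
      i <- i + 1L
    } else {
      letters_out <- c(letters_out, ch)
      fixed <- c(fixed, TRUE)
      i <- i + 1L
    }
  }
  list(letters = letters_out, fixed = fixed)
}

# random rooted bifurcating topology as a Newick string over given leaf
# newick fragments (labels or subtree strings); uses the session RNG
.random_join_newick <- function(items) {
  while (length(items) > 1L) {
    pick <- sample.int(length(items), 2L)
    joined <- sprintf("(%s:%.4f,%s:%.4f)", items[[pick[[1L]]]], runif(1, 0.1, 1),
                      items[[pick[[2L]]]], runif(1, 0.1, 1))
    items <- c(items[-pick], joined)
  }
  items[[1L]]
}

#' Blur one-hot domain tracks into noisy annotator posteriors
#'
#' Emulates the posterior uncertainty of a topology annotator: the true
#' domain receives `confidence` posterior mass in expectation and the
#' remainder is split between the other two domains, with Dirichlet jitter
#' (concentration 60) around that mean. Rows always renormalize to the
#' simplex; `confidence = 1` returns exact one-hot triples.
#'
#' @param tracks character vector of true labels (`E`/`M`/`I`), or a list
#'   of such vectors (a list is returned in kind).
#' @param confidence expected true-class posterior mass, in (1/3, 1].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return n x 3 matrix with columns `p_ext`, `p_mem`, `p_int` (or a named
#'   list of such matrices).
#' @export
emulate_annotator_noise <- function(tracks, confidence = 0.95, seed = NULL) {
  if (!(confidence > 1 / 3 && confidence <= 1)) {
    .stopf("confidence must lie in (1/3, 1]")
  }
  run <- function() {
    if (is.list(tracks)) {
      return(lapply(tracks, function(t) .blur_track(t, confidence)))
    }
    .blur_track(tracks, confidence)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.blur_track <- function(track, confidence) {
  n <- length(track)
  classes <- c(E = 1L, M = 2L, I = 3L)
  ti <- classes[track]
  out <- matrix(0, n, 3L, dimnames = list(NULL, c("p_ext", "p_mem", "p_int")))
  if (n == 0L) return(out)
  if (confidence == 1) {
    out[cbind(seq_len(n), ti)] <- 1
    return(out)
  }
  conc <- 60
  off <- (1 - confidence) / 2
  alpha <- matrix(conc * off, n, 3L)
  alpha[cbind(seq_len(n), ti)] <- conc * confidence
  g <- matrix(rgamma(n * 3L, shape = as.vector(alpha)), n, 3L)
  out[, ] <- g / rowSums(g)
  out
}

#' Generate a synthetic receptor family set with ground truth
#'
#' Draws a shared ancestral architecture (7 TM helices of fixed lengths
#' with hydrophobic-biased composition), derives one ancestor per family
#' (TM point substitutions at the family divergence; family-specific loop
#' lengths and contents), then evolves members along a simulated
#' bifurcating tree with domain-preserving point substitutions.
#' Loop lengths are occasionally redrawn per member (loop indels); TM
#' helices never gain or lose residues. Planted motifs are shielded from
#' substitution. Posterior tracks are the true labels blurred by
#' [emulate_annotator_noise()]; per-sequence classifier scores are drawn
#' N(50, 10) truncated at 15 (comfortably above the retention threshold).
#'
#' @param spec a [family_spec()].
#' @return an object of class `tm_synth_dataset`: list with `records`,
#'   `annotation` (a `tm_domain_annotation`), and `truth` (per-sequence
#'   true `tracks`, `family`, `flag` — all `"clean"` here — plus the true
#'   `tree` as a `tm_labeled_tree` and the originating `spec`).
#' @export
sample_family_set <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "tm_family_spec"))
  withr::with_seed(spec$seed, .sample_family_set_impl(spec))
}

.sample_family_set_impl <- function(spec) {
  fam_names <- sprintf("FAM%02d", seq_len(spec$n_families))
  tm_names <- paste0("tm", 1:7)
  tm_lengths <- setNames(
    .resample(seq.int(spec$tm_length_range[[1L]], spec$tm_length_range[[2L]]),
              7L, replace = TRUE), tm_names)
  anc_tm <- lapply(tm_lengths, function(L) .draw_seq(L, .TM_FREQ))

  # plant motifs in the shared ancestor and record protected positions
  protect <- lapply(tm_names, function(x) integer(0))
  names(protect) <- tm_names
  for (mp in spec$motif_plants) {
    ml <- .motif_letters(mp$pattern)
    seg <- switch(mp$anchor,
                  tm3_end = "tm3", tm7_end = "tm7",
                  .stopf("unknown motif anchor '%s'", mp$anchor))
    L <- length(anc_tm[[seg]])
    k <- length(ml$letters)
    if (k > L) .stopf("motif '%s' longer than segment %s", mp$pattern, seg)
    pos <- (L - k + 1L):L
    fix <- ml$fixed
    anc_tm[[seg]][pos[fix]] <- ml$letters[fix]
    protect[[seg]] <- c(protect[[seg]], pos[fix])
  }

  records_id <- character(0); records_res <- character(0)
  records_desc <- character(0)
  tracks <- list(); families <- character(0)
  fam_newicks <- character(spec$n_families)

  for (f in seq_len(spec$n_families)) {
    fam <- fam_names[[f]]
    # family ancestor: diverged TMs, fresh family-specific loops
    fam_tm <- lapply(tm_names, function(tn) {
      .mutate_segment(anc_tm[[tn]], spec$family_divergence, .TM_FREQ,
                      protect[[tn]])
    })
    names(fam_tm) <- tm_names
    loop_names <- setdiff(.SEGMENTS, tm_names)
    fam_loop_len <- vapply(loop_names, function(ln) {
      r <- spec$loop_length_ranges[[ln]]
      .resample(seq.int(r[[1L]], r[[2L]]))
    }, integer(1L))
    fam_loops <- lapply(loop_names, function(ln) {
      .draw_seq(fam_loop_len[[ln]], .BG_FREQ)
    })
    names(fam_loops) <- loop_names
    fam_anc <- c(fam_tm, fam_loops)[.SEGMENTS]

    # member evolution along a random bifurcating tree
    tr <- ape::rtree(spec$members_per_family,
                     tip.label = sprintf("%s_%03d", fam,
                                         seq_len(spec$members_per_family)))
    tr <- ape::reorder.phylo(tr, "cladewise")
    n_tip <- length(tr$tip.label)
    node_seq <- vector("list", n_tip + tr$Nnode)
    node_seq[[n_tip + 1L]] <- fam_anc
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      p_sub <- 1 - exp(-spec$substitution_rate * tr$edge.length[[e]])
      seqs <- node_seq[[par]]
      seqs <- lapply(names(seqs), function(seg) {
        freq <- if (.SEG_LABEL[[seg]] == "M") .TM_FREQ else .BG_FREQ
        prot <- if (seg %in% tm_names) protect[[seg]] else integer(0)
        .mutate_segment(seqs[[seg]], p_sub, freq, prot)
      })
      names(seqs) <- .SEGMENTS
      node_seq[[ch]] <- seqs
    }
    for (t in seq_len(n_tip)) {
      seqs <- node_seq[[t]]
      # occasional loop-length redraws (indels confined to loops)
      for (ln in loop_names) {
        if (runif(1) < spec$loop_redraw_prob) {
          r <- spec$loop_length_ranges[[ln]]
          newL <- .resample(seq.int(r[[1L]], r[[2L]]))
          old <- seqs[[ln]]
          seqs[[ln]] <- if (newL <= length(old)) old[seq_len(newL)] else
            c(old, .draw_seq(newL - length(old), .BG_FREQ))
        }
      }
      id <- tr$tip.label[[t]]
      residues <- paste(unlist(seqs), collapse = "")
      track <- rep(unname(.SEG_LABEL[.SEGMENTS]), lengths(seqs[.SEGMENTS]))
      records_id <- c(records_id, id)
      records_res <- c(records_res, residues)
      records_desc <- c(records_desc,
                        sprintf("%s receptor, synthetic member %03d", fam, t))
      tracks[[id]] <- track
      families <- c(families, fam)
    }
    fam_newicks[[f]] <- sub(";$", "", ape::write.tree(tr))
  }

  true_newick <- paste0(.random_join_newick(fam_newicks), ";")
  true_tree <- ape::read.tree(text = true_newick)

  records <- sequence_records(records_id, records_res, records_desc)
  posteriors <- lapply(tracks, function(t) {
    .blur_track(t, spec$annotator_confidence)
  })
  scores <- data.frame(
    seq_id = records_id,
    global_score = pmax(15, rnorm(length(records_id), 50, 10)),
    local_score = pmax(15, rnorm(length(records_id), 50, 10)),
    stringsAsFactors = FALSE)
  annotation <- domain_annotation(posteriors, scores,
                                  residues = lapply(records_res, .chars))
  names(annotation$residues) <- records_id

  flags <- setNames(rep("clean", length(records_id)), records_id)
  fam_map <- setNames(families, records_id)
  structure(list(
    records = records,
    annotation = annotation,
    truth = list(tracks = tracks, family = fam_map, flag = flags,
                 tree = labeled_tree(true_tree, fam_map,
                                     vocabulary = fam_names),
                 spec = spec)),
    class = "tm_synth_dataset")
}

#' @export
print.tm_synth_dataset <- function(x, ...) {
  cat(sprintf("<tm_synth_dataset> %d sequences (%s)\n", nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$truth$flag)),
                            table(x$truth$flag)), collapse = ", ")))
  invisible(x)
}

#' Plant alignment artifacts and decoys into a synthetic dataset
#'
#' Frame-shifted sequences keep their residues but have their domain track
#' rotated by `shift` positions, emulating an annotator that locked onto
#' the wrong structural register; their posteriors are regenerated from the
#' rotated track at the dataset's confidence. Decoys are non-receptor
#' sequences drawn from the background composition with uniform
#' low-confidence posterior tracks and classifier scores below any sensible
#' retention threshold (U(0, 8)).
#'
#' @param dataset a `tm_synth_dataset` from [sample_family_set()].
#' @param n_shifted number of existing sequences to shift (default 20).
#' @param shift rotation in residues (default 10); must be smaller than
#'   every shifted sequence.
#' @param n_decoys number of appended decoy records (default 5).
#' @param seed integer seed.
#' @return the corrupted `tm_synth_dataset` with updated truth flags.
#' @export
corrupt_dataset <- function(dataset, n_shifted = 20L, shift = 10L,
                            n_decoys = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "tm_synth_dataset"))
  if (n_shifted + n_decoys < 0L) .stopf("negative artifact counts")
  if (n_shifted > nrow(dataset$records)) {
    .stopf("n_shifted exceeds the dataset size")
  }
  withr::with_seed(seed, {
    conf <- dataset$truth$spec$annotator_confidence
    ids <- dataset$records$id
    shifted_ids <- if (n_shifted > 0L) sort(sample(ids, n_shifted)) else character(0)
    for (id in shifted_ids) {
      track <- dataset$truth$tracks[[id]]
      L <- length(track)
      if (shift >= L) .stopf("shift %d >= length of sequence %s (%d)", shift, id, L)
      if (shift > 0L) {
        track <- c(track[(L - shift + 1L):L], track[seq_len(L - shift)])
        dataset$truth$tracks[[id]] <- track
        dataset$annotation$posteriors[[id]] <- .blur_track(track, conf)
      }
      dataset$truth$flag[[id]] <- "shifted"
    }
    if (n_decoys > 0L) {
      lens <- nchar(dataset$records$residues)
      decoy_ids <- sprintf("DECOY_%03d", seq_len(n_decoys))
      decoy_res <- vapply(seq_len(n_decoys), function(i) {
        paste(.draw_seq(.resample(lens), .BG_FREQ), collapse = "")
      }, character(1L))
      decoys <- sequence_records(decoy_ids, decoy_res,
                                 "synthetic non-receptor decoy")
      dataset$records <- rbind(dataset$records, decoys)
      for (i in seq_len(n_decoys)) {
        id <- decoy_ids[[i]]
        n <- nchar(decoy_res[[i]])
        g <- matrix(rgamma(n * 3L, shape = 3), n, 3L)
        p <- g / rowSums(g)
        dimnames(p) <- list(NULL, c("p_ext", "p_mem", "p_int"))
        dataset$annotation$posteriors[[id]] <- p
        dataset$annotation$residues[[id]] <- .chars(decoy_res[[i]])
        dataset$truth$tracks[[id]] <- NA
        dataset$truth$flag[[id]] <- "decoy"
        dataset$truth$family[[id]] <- "decoy"
      }
      dataset$annotation$scores <- rbind(
        dataset$annotation$scores,
        data.frame(seq_id = decoy_ids,
                   global_score = runif(n_decoys, 0, 8),
                   local_score = runif(n_decoys, 0, 8),
                   stringsAsFactors = FALSE))
    }
  })
  dataset
}

#' Simulate a labeled tree with planted mislabeled leaves
#'
#' Builds a random rooted bifurcating tree in which each annotation class
#' occupies one monophyletic block, then relabels `n_mislabel` random
#' leaves with a uniformly-chosen different class. The ground truth records
#' every planted swap.
#'
#' @param n_leaves total leaves (default 200).
#' @param n_classes number of annotation classes (default 6); must not
#'   exceed `n_leaves`.
#' @param n_mislabel number of planted label swaps (default 10); must be
#'   smaller than `n_leaves`.
#' @param seed integer seed.
#' @return a `tm_labeled_tree` whose `truth` is a data.frame with columns
#'   `id`, `true_class`, `annotation`, `mislabeled`.
#' @export
simulate_labeled_tree <- function(n_leaves = 200L, n_classes = 6L,
                                  n_mislabel = 10L, seed = 1L) {
  if (n_classes > n_leaves) .stopf("n_classes > n_leaves")
  if (n_mislabel >= n_leaves) .stopf("n_mislabel must be < n_leaves")
  withr::with_seed(seed, {
    base <- n_leaves %/% n_classes
    sizes <- rep(base, n_classes)
    extra <- n_leaves - base * n_classes
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    classes <- sprintf("class%02d", seq_len(n_classes))
    offset <- 0L
    block_newicks <- character(n_classes)
    ids <- character(0); true_class <- character(0)
    for (ci in seq_len(n_classes)) {
      leaf_ids <- sprintf("t%04d", offset + seq_len(sizes[[ci]]))
      offset <- offset + sizes[[ci]]
      block_newicks[[ci]] <- .random_join_newick(leaf_ids)
      ids <- c(ids, leaf_ids)
      true_class <- c(true_class, rep(classes[[ci]], sizes[[ci]]))
    }
    tree <- ape::read.tree(text = paste0(.random_join_newick(block_newicks), ";"))
    ann <- setNames(true_class, ids)
    mis <- if (n_mislabel > 0L) sort(sample(ids, n_mislabel)) else character(0)
    for (id in mis) {
      ann[[id]] <- sample(setdiff(classes, ann[[id]]), 1L)
    }
    truth <- data.frame(id = ids, true_class = true_class,
                        annotation = unname(ann[ids]),
                        mislabeled = ids %in% mis,
                        stringsAsFactors = FALSE)
    labeled_tree(tree, ann, vocabulary = classes, truth = truth)
  })
}
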