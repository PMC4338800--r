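test_that("the generator is a pure function of its spec and seed", {
  spec <- family_spec(n_families = 2, members_per_family = 6, seed = 42)
  a <- sample_family_set(spec)
  b <- sample_family_set(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$annotation$posteriors, b$annotation$posteriors)
  expect_identical(ape::write.tree(a$truth$tree$tree),
                   ape::write.tree(b$truth$tree$tree))
})

test_that("zero substitution rate yields identical family members", {
  spec <- family_spec(n_families = 1, members_per_family = 2,
                      substitution_rate = 0, loop_redraw_prob = 0,
                      annotator_confidence = 1, seed = 7)
  ds <- sample_family_set(spec)
  expect_equal(nrow(ds$records), 2L)
  expect_identical(ds$records$residues[[1]], ds$records$residues[[2]])
  expect_identical(ds$truth$tracks[[1]], ds$truth$tracks[[2]])
})

test_that("clean tracks always parse under the seven-TM grammar", {
  ds <- sample_family_set(family_spec(n_families = 3, members_per_family = 8,
                                      seed = 13))
  grammar <- "^E+(M+I+M+E+){3}M+I+$"
  for (id in names(ds$truth$tracks)) {
    expect_match(paste(ds$truth$tracks[[id]], collapse = ""), grammar)
  }
})

test_that("TM residues are hydrophobicity-enriched relative to loops", {
  ds <- sample_family_set(family_spec(n_families = 4, members_per_family = 25,
                                      seed = 14))
  hydrophobic <- c("A", "I", "L", "M", "F", "V", "W")
  frac <- c(M = 0, EI = 0); n <- c(M = 0, EI = 0)
  for (id in ds$records$id) {
    chars <- strsplit(ds$records$residues[[match(id, ds$records$id)]], "")[[1]]
    track <- ds$truth$tracks[[id]]
    is_m <- track == "M"
    frac[["M"]] <- frac[["M"]] + sum(chars[is_m] %in% hydrophobic)
    n[["M"]] <- n[["M"]] + sum(is_m)
    frac[["EI"]] <- frac[["EI"]] + sum(chars[!is_m] %in% hydrophobic)
    n[["EI"]] <- n[["EI"]] + sum(!is_m)
  }
  expect_gt(frac[["M"]] / n[["M"]], frac[["EI"]] / n[["EI"]])
})

test_that("annotator noise keeps rows on the simplex and is recoverable", {
  track <- rep(c("E", "M", "I"), length.out = 10000)
  # noiseless limit: exact one-hot
  p1 <- emulate_annotator_noise(track[1:100], confidence = 1)
  expect_true(all(p1 %in% c(0, 1)))
  expect_equal(rowSums(p1), rep(1, 100))

  p <- emulate_annotator_noise(track, confidence = 0.9, seed = 99)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  recovered <- assign_domains(p, cutoff = 0.5)
  expect_gte(mean(recovered == track), 0.99)
  expect_error(emulate_annotator_noise(track, confidence = 0.2), "confidence")
})

test_that("corruption rotates tracks, flags artifacts and appends decoys", {
  ds <- sample_family_set(family_spec(n_families = 2, members_per_family = 8,
                                      seed = 15))
  n0 <- nrow(ds$records)

  # shift 0: everything identical except the flags
  c0 <- corrupt_dataset(ds, n_shifted = 3, shift = 0, n_decoys = 0, seed = 16)
  expect_identical(c0$records, ds$records)
  expect_identical(c0$annotation$posteriors, ds$annotation$posteriors)
  expect_equal(sum(c0$truth$flag == "shifted"), 3L)

  cd <- corrupt_dataset(ds, n_shifted = 4, shift = 10, n_decoys = 5, seed = 17)
  expect_equal(sum(cd$truth$flag == "decoy"), 5L)
  expect_equal(sum(cd$truth$flag == "shifted"), 4L)
  expect_equal(nrow(cd$records), n0 + 5L)
  # residues of shifted sequences are unchanged; only the track moved
  shifted <- names(cd$truth$flag)[cd$truth$flag == "shifted"]
  for (id in shifted) {
    expect_identical(cd$records$residues[[match(id, cd$records$id)]],
                     ds$records$residues[[match(id, ds$records$id)]])
    expect_false(identical(cd$truth$tracks[[id]], ds$truth$tracks[[id]]))
    expect_identical(sort(table(cd$truth$tracks[[id]])),
                     sort(table(ds$truth$tracks[[id]])))
  }
  # decoy scores sit below any sensible retention threshold
  sc <- cd$annotation$scores
  decoy_sc <- sc[grepl("^DECOY", sc$seq_id), ]
  expect_true(all(decoy_sc$global_score < 10 & decoy_sc$local_score < 10))

  expect_error(corrupt_dataset(ds, n_shifted = 1, shift = 10000, seed = 1),
               "shift")
})

test_that("a shifted sequence lands its TM residues over non-TM consensus", {
  # a 10-residue shift across 20-residue helices throws half of each
  # helix's labels out of structural register, provided every loop is
  # longer than the shift (otherwise the displaced window reaches the next
  # helix); noiseless tracks keep the arithmetic exact
  ds <- sample_family_set(family_spec(
    n_families = 1, members_per_family = 12,
    tm_length_range = c(20L, 20L),
    loop_length_ranges = list(
      nterm = c(15L, 30L), icl1 = c(12L, 16L), ecl1 = c(12L, 16L),
      icl2 = c(12L, 18L), ecl2 = c(12L, 25L), icl3 = c(14L, 60L),
      ecl3 = c(12L, 60L), cterm = c(15L, 30L)),
    annotator_confidence = 1,
    seed = 18))
  cd <- corrupt_dataset(ds, n_shifted = 1, shift = 10, n_decoys = 0, seed = 19)
  shifted_id <- names(cd$truth$flag)[cd$truth$flag == "shifted"]
  ref_labels <- lapply(cd$annotation$posteriors, assign_domains)
  aln <- align(cd$records)
  lm <- project_labels(aln, ref_labels)
  prof <- consensus_profile(lm)
  row <- lm[shifted_id, ]
  cons <- prof$consensus
  m_pos <- row == "M" & cons != "U"
  # at least half of its TM-labeled residues disagree with the consensus
  expect_gte(mean(cons[m_pos] != "M"), 0.5)
})

test_that("simulated labeled trees plant classes monophyletically", {
  lt0 <- simulate_labeled_tree(n_leaves = 40, n_classes = 4, n_mislabel = 0,
                               seed = 20)
  expect_equal(nrow(concordance_scan(lt0)), 0L)

  lt <- simulate_labeled_tree(n_leaves = 200, n_classes = 6, n_mislabel = 10,
                              seed = 21)
  expect_equal(sum(lt$truth$mislabeled), 10L)
  expect_equal(nrow(lt$truth), 200L)
  expect_equal(as.vector(table(lt$truth$true_class)),
               rep(c(34, 33), c(2, 4)))
  # mislabeled annotations differ from truth; the rest agree
  mis <- lt$truth$mislabeled
  expect_true(all(lt$truth$annotation[mis] != lt$truth$true_class[mis]))
  expect_true(all(lt$truth$annotation[!mis] == lt$truth$true_class[!mis]))

  expect_error(simulate_labeled_tree(10, 20, 0, 1), "n_classes")
  expect_error(simulate_labeled_tree(10, 2, 10, 1), "n_mislabel")
})
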