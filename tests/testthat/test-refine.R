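test_that("column consensus follows majority with gaps and U as missing", {
  expect_equal(column_consensus(c("M", "M", "M")), "M")
  expect_equal(column_consensus(c("M", "M", "E", "-")), "M")
  expect_equal(column_consensus(c("M", "E")), "U")          # tie
  expect_equal(column_consensus(c("-", "-", "U")), "U")      # no evidence
})

test_that("vectorized consensus equals the brute-force oracle", {
  withr::with_seed(90, {
    for (rep in 1:20) {
      n_rows <- sample(2:50, 1)
      width <- sample(5:40, 1)
      mat <- matrix(sample(c("E", "M", "I", "U", "-"), n_rows * width,
                           replace = TRUE, prob = c(.25, .25, .2, .1, .2)),
                    n_rows, width)
      rownames(mat) <- sprintf("r%02d", seq_len(n_rows))
      prof <- consensus_profile(mat)
      want <- apply(mat, 2, oracle_consensus)
      expect_identical(prof$consensus, unname(want))
      expect_identical(unname(vapply(seq_len(width), function(j)
        column_consensus(mat[, j]), "")), unname(want))
    }
  })
})

test_that("sequence discordance counts evaluable residues correctly", {
  # 100 evaluable residues, 5 discordant -> exactly 0.05
  cons <- rep("M", 100)
  row <- c(rep("M", 95), rep("E", 5))
  d <- sequence_discordance(row, cons)
  expect_equal(d$fraction, 0.05)
  expect_equal(d$evaluable, 100L)

  # full concordance
  expect_equal(sequence_discordance(rep("M", 30), rep("M", 30))$fraction, 0)

  # 200-column fixture, 9 discordant among 200 evaluable -> 0.045, retained at 5%
  cons2 <- rep(c("M", "E"), each = 100)
  row2 <- cons2
  row2[c(3, 17, 40, 77, 101, 120, 155, 180, 199)] <- c("E", "E", "E", "E",
                                                       "M", "M", "M", "M", "M")
  d2 <- sequence_discordance(row2, cons2)
  expect_equal(d2$discordant, 9L)
  expect_equal(d2$fraction, 0.045)
  expect_lt(d2$fraction, 0.05)

  # gaps, U residues and U-consensus columns are excluded from the denominator
  cons3 <- c("M", "M", "U", "M")
  row3 <- c("M", "-", "E", "U")
  d3 <- sequence_discordance(row3, cons3)
  expect_equal(d3$evaluable, 1L)
  expect_equal(d3$fraction, 0)

  expect_warning(z <- sequence_discordance(c("-", "-"), c("M", "M")),
                 "no evaluable")
  expect_equal(z$fraction, 0)
  expect_error(sequence_discordance(c("M"), c("M", "M")), "length")
})

test_that("the column denominator variant divides by alignment width", {
  cons <- rep("M", 100)
  row <- c(rep("M", 45), rep("E", 5), rep("-", 50))
  expect_equal(sequence_discordance(row, cons)$fraction, 0.1)
  expect_equal(sequence_discordance(row, cons, denominator = "columns")$fraction,
               0.05)
})

test_that("culling removes exactly the rows at or above the threshold", {
  # 3 concordant rows and one row built to sit at exactly 6% discordance
  width <- 50L
  good <- strrep("M", width)
  bad_labels <- paste0(strrep("E", 3), strrep("M", width - 3))  # 3/50 = 6%
  msa <- msa_of(c("g1", "g2", "g3", "b1"),
                rep(paste(rep("L", width), collapse = ""), 4))
  labels <- label_mat_of(c("g1", "g2", "g3", "b1"),
                         c(good, good, good, bad_labels))
  res <- cull_pass(msa, labels, threshold = 0.05)
  expect_equal(res$removed$id, "b1")
  expect_equal(res$removed$fraction, 0.06)
  expect_equal(res$retained$id, c("g1", "g2", "g3"))

  # boundary semantics: >= removes a row at exactly the threshold
  res2 <- cull_pass(msa, labels, threshold = 0.06)
  expect_equal(res2$removed$id, "b1")
  # nothing above 1.0 except fully discordant rows
  res3 <- cull_pass(msa, labels, threshold = 1.0)
  expect_equal(nrow(res3$removed), 0L)

  # a fixture where every sequence carries some discordance errors out
  msa3 <- msa_of(c("x", "y", "z"), c("LLL", "LLL", "LLL"))
  mixed <- label_mat_of(c("x", "y", "z"), c("EEM", "EME", "MEE"))
  expect_error(cull_pass(msa3, mixed, threshold = 1e-9),
               "no sequences survive culling")
})

test_that("iterative refinement reaches a fixpoint and removes planted shifts", {
  ds <- sample_family_set(family_spec(n_families = 2, members_per_family = 15,
                                      seed = 21))
  cds <- corrupt_dataset(ds, n_shifted = 4, shift = 10, n_decoys = 0, seed = 22)
  ref <- iterative_refine(cds$records, cds$annotation)
  planted <- names(cds$truth$flag)[cds$truth$flag == "shifted"]
  removed <- unlist(lapply(ref$audit$iterations, function(it) it$removed$id))
  expect_setequal(removed, planted)
  expect_lte(ref$audit$total_iterations, 5L)
  # final alignment is below threshold everywhere
  expect_true(all(ref$report$fraction < 0.05))
  # counts decrease monotonically and the last pass removes nothing
  n_out <- vapply(ref$audit$iterations, function(it) it$n_output, 1L)
  n_in <- vapply(ref$audit$iterations, function(it) it$n_input, 1L)
  expect_true(all(diff(n_in) < 0) || length(n_in) == 1L)
  expect_equal(nrow(ref$audit$iterations[[length(n_in)]]$removed), 0L)

  # fixpoint: refining the refined set again is a one-iteration no-op
  kept <- cds$records[cds$records$id %in% msa_ids(ref$alignment), ]
  ref2 <- iterative_refine(kept, cds$annotation)
  expect_equal(ref2$audit$total_iterations, 1L)
  expect_equal(nrow(ref2$audit$iterations[[1]]$removed), 0L)
})

test_that("a fully concordant family converges in one iteration", {
  ds <- small_family_set()
  ref <- iterative_refine(ds$records, ds$annotation)
  expect_equal(ref$audit$total_iterations, 1L)
  # threshold 1.0 can never remove a partially concordant sequence
  ref2 <- iterative_refine(ds$records, ds$annotation, threshold = 1.0)
  expect_equal(ref2$audit$total_iterations, 1L)
  expect_equal(nrow(ref2$audit$iterations[[1]]$removed), 0L)
})

test_that("masking replaces exactly the discordant labeled residues", {
  msa <- msa_of(c("a", "b", "c"), c("LLKL", "LLRL", "LL-L"))
  labels <- label_mat_of(c("a", "b", "c"), c("MMMM", "MMEM", "MM-U"))
  masked <- mask_discordant(msa, labels)
  # column consensus is M everywhere (col 3: one M, one E, one gap -> tie? no:
  # a=M, b=E, c=gap -> tie M/E -> U, so nothing masked in col 3)
  expect_equal(unname(masked$matrix["b", 3]), "R")
  expect_equal(sum(masked$mask), 0L)

  labels2 <- label_mat_of(c("a", "b", "c"), c("MMMM", "MMEM", "MMMU"))
  masked2 <- mask_discordant(msa_of(c("a", "b", "c"),
                                    c("LLKL", "LLRL", "LLAL")), labels2)
  expect_equal(unname(masked2$matrix["b", 3]), "?")   # E against M consensus
  expect_equal(unname(masked2$matrix["a", 3]), "K")   # concordant untouched
  expect_equal(unname(masked2$matrix["c", 4]), "L")   # U label untouched
  expect_equal(sum(masked2$mask), 1L)
  # unmasking restores the original residues
  expect_identical(unmask(masked2)$matrix[, 3], c(a = "K", b = "R", c = "A"))
})

test_that("partition extraction maps consensus labels to TM/EM coverage", {
  prof <- consensus_profile(label_mat_of("r", paste(
    c("M", "M", "M", "E", "E", "I", "I", "I"), collapse = "")))
  sch <- extract_partitions(prof)
  expect_equal(unname(sch$TM), cbind(1L, 3L), ignore_attr = TRUE)
  expect_equal(unname(sch$EM), cbind(4L, 8L), ignore_attr = TRUE)

  prof2 <- consensus_profile(label_mat_of("r", "EMEM"))
  sch2 <- extract_partitions(prof2)
  expect_equal(nrow(sch2$TM), 2L)
  expect_equal(as.vector(t(sch2$TM)), c(2L, 2L, 4L, 4L))
  expect_equal(as.vector(t(sch2$EM)), c(1L, 1L, 3L, 3L))

  # all-U profile: everything lands in EM with a warning
  prof3 <- consensus_profile(label_mat_of(c("a", "b"), c("UUUU", "----")))
  expect_warning(sch3 <- extract_partitions(prof3), "no TM")
  expect_equal(nrow(sch3$TM), 0L)
  expect_equal(as.vector(sch3$EM), c(1L, 4L))
  expect_equal(attr(sch3, "n_unassigned"), 4L)
})

test_that("motif location finds planted windows at the stated fraction", {
  rows <- c("AADRYLL", "AADRYLL", "AAERYLL", "AA-RYLL")
  msa <- msa_of(sprintf("s%d", 1:4), rows)
  hits <- locate_motif(msa, "[DE]RY")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 5L)
  expect_equal(hits$fraction, 1.0)        # the gapped row is excluded
  expect_equal(hits$n_evaluable, 3L)

  expect_equal(nrow(locate_motif(msa, "WWWW")), 0L)
  expect_error(locate_motif(msa, "[DE"), "unclosed")
  expect_error(locate_motif(msa, "D*Y"), "unexpected character")

  # planted NP..Y in 80% of rows at known columns
  withr::with_seed(91, {
    n <- 20
    width <- 30
    mat <- matrix(sample(c("A", "L", "S", "G"), n * width, replace = TRUE),
                  n, width, dimnames = list(sprintf("m%02d", 1:n), NULL))
    carriers <- 1:16  # 80%
    mat[carriers, 12] <- "N"; mat[carriers, 13] <- "P"; mat[carriers, 16] <- "Y"
    hits2 <- locate_motif(new_msa(mat), "NP..Y", min_fraction = 0.5)
    expect_true(any(hits2$start == 12 & hits2$end == 16))
    got <- hits2[hits2$start == 12, ]
    expect_equal(got$fraction, 0.8)
  })
})
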