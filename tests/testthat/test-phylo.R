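test_that("the likelihood ratio test computes 2*dlnL against chi-square", {
  # equal likelihoods: statistic 0, p = 1
  r <- lrt(model_fit(-1000, 10), model_fit(-1000, 15))
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 5L)
  expect_equal(r$p_value, 1)

  # canonical 5% quantile at 1 degree of freedom
  r2 <- lrt(model_fit(-1000, 10), model_fit(-1000 + 3.841 / 2, 11))
  expect_equal(r2$statistic, 3.841)
  expect_equal(r2$p_value, 0.05, tolerance = 1e-3)

  # misordered / non-nested models are rejected
  expect_error(lrt(model_fit(-1000, 15), model_fit(-1000, 10)),
               "not nested or misordered")
  expect_error(lrt(model_fit(-1000, 10), model_fit(-1001, 15)),
               "not nested or misordered")
})

test_that("LRT p-values match an incomplete-gamma series oracle to 1e-10", {
  withr::with_seed(60, {
    stats_ <- runif(100, 0.5, 80)
    dfs <- sample(1:40, 100, replace = TRUE)
    for (i in 1:100) {
      r <- lrt(model_fit(0, 1), model_fit(stats_[i] / 2, 1 + dfs[i]))
      want <- oracle_chisq_p(stats_[i], dfs[i])
      expect_lt(abs(r$p_value - want) / want, 1e-10)
    }
  })
})

test_that("LRT p decreases in the statistic and matches Wilson-Hilferty at high df", {
  p <- vapply(seq(0.1, 30, by = 0.4), function(s)
    lrt(model_fit(0, 1), model_fit(s / 2, 4))$p_value, 1)
  expect_true(all(diff(p) < 0))

  wh <- function(x, df) {
    pnorm(((x / df)^(1 / 3) - (1 - 2 / (9 * df))) / sqrt(2 / (9 * df)),
          lower.tail = FALSE)
  }
  for (df in c(60, 120, 300)) {
    for (ratio in seq(0.5, 2, by = 0.25)) {
      got <- lrt(model_fit(0, 1), model_fit(ratio * df / 2, 1 + df))$p_value
      expect_lt(abs(got - wh(ratio * df, df)), 1e-3)
    }
  }
})

test_that("a single mislabeled leaf inside a pure clade is reclassified", {
  withr::with_seed(61, {
    ids <- sprintf("L%02d", 1:25)
    nwk <- paste0("(", paste(sprintf("(%s:1,%s:1):1", ids[seq(1, 24, 2)],
                                     ids[seq(2, 24, 2)]), collapse = ","),
                  ",", ids[25], ":1);")
  })
  tree <- ape::read.tree(text = nwk)
  ann <- setNames(rep("DRD-3", 25), ids)
  ann["L05"] <- "DRD-2"
  lt <- labeled_tree(tree, ann, vocabulary = c("DRD-2", "DRD-3"))
  props <- concordance_scan(lt, min_clade = 5, min_purity = 0.9)
  expect_equal(nrow(props), 1L)
  expect_equal(props$current, "DRD-2")
  expect_equal(props$proposed, "DRD-3")
  expect_gte(props$purity, 0.9)

  # a uniformly annotated tree yields nothing
  lt2 <- labeled_tree(tree, setNames(rep("DRD-3", 25), ids),
                      vocabulary = c("DRD-2", "DRD-3"))
  expect_equal(nrow(concordance_scan(lt2)), 0L)
})

test_that("uncharacterized leaves always receive their clade's majority class", {
  ids <- sprintf("L%02d", 1:12)
  nwk <- paste0("((", paste(ids[1:6], collapse = ","), "),(",
                paste(ids[7:12], collapse = ","), "));")
  tree <- ape::read.tree(text = nwk)
  ann <- setNames(c(rep("HRH-2", 5), "uncharacterized", rep("TAAR", 6)), ids)
  lt <- labeled_tree(tree, ann, vocabulary = c("HRH-2", "TAAR"))
  props <- concordance_scan(lt, min_clade = 5, min_purity = 0.9)
  expect_equal(props$id, "L06")
  expect_equal(props$proposed, "HRH-2")
})

test_that("out-of-vocabulary clades are reported as a single Unknown group", {
  in_ids <- sprintf("A%02d", 1:10)
  oov_ids <- sprintf("B%02d", 1:12)
  nwk <- paste0("((", paste(in_ids, collapse = ","), "),(",
                paste(oov_ids, collapse = ","), "));")
  tree <- ape::read.tree(text = nwk)
  ann <- setNames(c(rep("5HTR-7", 10),
                    rep(c("Octopamine receptor-like", "Probable GPCR No9-like"), 6)),
                  c(in_ids, oov_ids))
  lt <- labeled_tree(tree, ann, vocabulary = c("5HTR-7", "HRH-2"))
  props <- concordance_scan(lt, min_clade = 5, min_purity = 0.9)
  unk <- props[props$type == "unknown_clade", ]
  expect_setequal(unk$id, oov_ids)
  expect_true(all(unk$proposed == "Unknown"))
  expect_equal(length(unique(unk$group)), 1L)
  expect_equal(nrow(props[props$type == "reclassify", ]), 0L)
})

test_that("planted mislabels on a simulated tree are recovered exactly", {
  lt <- simulate_labeled_tree(n_leaves = 120, n_classes = 4, n_mislabel = 6,
                              seed = 62)
  props <- concordance_scan(lt, min_clade = 5, min_purity = 0.9)
  planted <- lt$truth$id[lt$truth$mislabeled]
  expect_setequal(props$id, planted)
  # every proposal recovers the true class
  truth <- setNames(lt$truth$true_class, lt$truth$id)
  expect_identical(unname(truth[props$id]), props$proposed)
})

test_that("no proposal is emitted below the purity floor", {
  withr::with_seed(63, {
    for (i in 1:20) {
      lt <- simulate_labeled_tree(n_leaves = sample(30:80, 1),
                                  n_classes = sample(2:5, 1),
                                  n_mislabel = sample(0:6, 1),
                                  seed = sample.int(1e6, 1))
      props <- concordance_scan(lt, min_clade = 4, min_purity = 0.8)
      if (nrow(props)) expect_true(all(props$purity >= 0.8))
    }
  })
})

test_that("the scan is invariant to leaf-order rotations of the tree", {
  lt <- simulate_labeled_tree(n_leaves = 60, n_classes = 3, n_mislabel = 4,
                              seed = 64)
  base <- concordance_scan(lt, min_clade = 5, min_purity = 0.9)
  base <- base[order(base$id), c("id", "current", "proposed")]
  withr::with_seed(65, {
    for (i in 1:10) {
      phy <- lt$tree
      nodes <- (length(phy$tip.label) + 1):(length(phy$tip.label) + phy$Nnode)
      for (nd in sample(nodes, 8)) {
        phy <- tryCatch(ape::rotate(phy, nd), error = function(e) phy)
      }
      # re-read through Newick to reorder internal structure
      phy <- ape::read.tree(text = ape::write.tree(phy))
      lt2 <- labeled_tree(phy, lt$annotations, vocabulary = lt$vocabulary)
      got <- concordance_scan(lt2, min_clade = 5, min_purity = 0.9)
      got <- got[order(got$id), c("id", "current", "proposed")]
      expect_equal(got, base, ignore_attr = TRUE)
    }
  })
})

test_that("engine input bundles round-trip and reject hostile columns", {
  ds <- small_family_set()
  ref <- iterative_refine(ds$records, ds$annotation)
  masked <- mask_discordant(ref$alignment, ref$labels, ref$profile)
  scheme <- extract_partitions(ref$profile)
  out <- withr::local_tempdir()
  files <- prepare_engine_inputs(masked, scheme, out)
  expect_true(all(file.exists(unlist(files))))

  manifest <- jsonlite::read_json(files$manifest)
  expect_equal(length(manifest$partitions), 2L)
  expect_equal(manifest$searches, 100L)
  expect_equal(manifest$rate_categories, 25L)
  # config passthrough
  files2 <- prepare_engine_inputs(masked, scheme, out,
                                  settings = list(searches = 2))
  expect_equal(jsonlite::read_json(files2$manifest)$searches, 2L)

  # the written PHYLIP reproduces the masked matrix exactly
  back <- read_phylip_relaxed(files$alignment)
  expect_identical(back, masked$matrix)
  # and the partition file reproduces the scheme
  expect_equal(unclass(read_partition_file(files$partitions))[names(scheme)],
               unclass(scheme)[names(scheme)], ignore_attr = TRUE)

  # an all-'?' column is refused
  bad <- masked
  bad$matrix[, 3] <- "?"
  expect_error(prepare_engine_inputs(bad, scheme, out), "engine-hostile")
})
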