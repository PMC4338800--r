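# Independent oracles, implemented without reference to package internals.

# brute-force column consensus: tabulate E/M/I, unique argmax or U
oracle_consensus <- function(labels) {
  counts <- table(factor(labels, levels = c("E", "M", "I")))
  if (max(counts) == 0 || sum(counts == max(counts)) > 1) return("U")
  names(counts)[which.max(counts)]
}

# regularized upper incomplete gamma Q(a, x) via power series / continued
# fraction (Numerical Recipes gser/gcf), to ~1e-15 relative
oracle_gamma_q <- function(a, x) {
  if (x < 0 || a <= 0) stop("bad arguments")
  if (x == 0) return(1)
  if (x < a + 1) {
    # series for P(a, x)
    ap <- a
    del <- sum <- 1 / a
    for (i in 1:1000) {
      ap <- ap + 1
      del <- del * x / ap
      sum <- sum + del
      if (abs(del) < abs(sum) * 1e-16) break
    }
    p <- sum * exp(-x + a * log(x) - lgamma(a))
    return(1 - p)
  }
  # Lentz continued fraction for Q(a, x)
  tiny <- 1e-300
  b <- x + 1 - a
  c <- 1 / tiny
  d <- 1 / b
  h <- d
  for (i in 1:1000) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < tiny) d <- tiny
    c <- b + an / c
    if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < 1e-16) break
  }
  h * exp(-x + a * log(x) - lgamma(a))
}

# upper-tail chi-square p-value through the gamma oracle
oracle_chisq_p <- function(stat, df) oracle_gamma_q(df / 2, stat / 2)

# plain-R affine-gap global alignment score (Gotoh, full matrices, no
# traceback); gap of length L costs open + L * ext (positive penalties)
oracle_affine_score <- function(a, b, submat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e300
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) Y[i + 1, 1] <- -(open + i * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - ext,
                             Y[i + 1, j] - open - ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - open - ext,
                             Y[i, j + 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# unrooted bipartitions of a phylo tree as canonical strings: for every
# internal edge, the split side containing the lexicographically first tip
oracle_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  tree <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  first_tip <- min(tree$tip.label)
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next  # trivial split
    side <- sort(desc[[ch]])
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (!(first_tip %in% side)) side <- sort(setdiff(tree$tip.label, side))
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

oracle_rf_distance <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# random amino-acid string
random_peptide <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
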