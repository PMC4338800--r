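# fixture builders shared across test files

msa_of <- function(ids, rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- ids
  new_msa(mat)
}

label_mat_of <- function(ids, rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- ids
  mat
}

# small concordant synthetic dataset (cached per session: generation is
# seeded and cheap, but several files reuse the same conditions)
small_family_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_family_set(family_spec(n_families = 2,
                                              members_per_family = 10,
                                              seed = 11))
    }
    cache
  }
})
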