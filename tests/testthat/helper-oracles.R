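# Independent brute-force oracle for selfing transmission: enumerate all
# 4^L ordered gamete pairs of the parent and tabulate offspring dosages.
enumerate_selfing <- function(parent) {
  stopifnot(all(parent %in% 0:2))
  ids <- names(parent)
  homologs <- lapply(parent, function(d) {
    if (d == 0) c(0, 0) else if (d == 1) c(1, 0) else c(1, 1)
  })
  # each gamete: choose one homolog at every locus -> 2^L gametes
  gamete_choices <- expand.grid(rep(list(1:2), length(parent)))
  gametes <- apply(gamete_choices, 1, function(ch) {
    vapply(seq_along(parent), function(l) homologs[[l]][ch[l]], numeric(1))
  })
  gametes <- matrix(gametes, nrow = length(parent))  # loci x gametes
  n_g <- ncol(gametes)
  counts <- list()
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_g)) {
      child <- gametes[, i] + gametes[, j]
      key <- paste(child, collapse = ",")
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- names(counts)
  probs <- unlist(counts, use.names = FALSE) / (n_g * n_g)
  dosages <- do.call(rbind, lapply(strsplit(keys, ","), as.numeric))
  colnames(dosages) <- ids
  d <- as.data.frame(dosages)
  d$prob <- probs
  d[do.call(order, d[, ids, drop = FALSE]), , drop = FALSE]
}

# sort a distribution tibble into canonical order for comparison
sort_dist <- function(d) {
  ids <- setdiff(names(d), "prob")
  d <- as.data.frame(d)[, c(ids, "prob"), drop = FALSE]
  d[do.call(order, d[, ids, drop = FALSE]), , drop = FALSE]
}

# binomial three-standard-deviation check
within_3sd <- function(observed_fraction, p, n) {
  abs(observed_fraction - p) <= 3 * sqrt(p * (1 - p) / n)
}
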