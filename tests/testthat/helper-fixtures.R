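# shared fixtures and independent oracles used across test files

# build a tissue_profile directly from a genes x tissues matrix
make_profile <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  structure(list(means = m, n_tissues = ncol(m)), class = "tissue_profile")
}

# small atlas: one gene per row of `means` (genes x tissues), nrep replicates
# per tissue, exact replicate values (no noise)
make_atlas <- function(means, nrep = 2) {
  if (is.null(rownames(means)))
    rownames(means) <- sprintf("g%03d", seq_len(nrow(means)))
  tissues <- sprintf("t%02d", seq_len(ncol(means)))
  tpm <- means[, rep(seq_len(ncol(means)), each = nrep), drop = FALSE]
  colnames(tpm) <- paste0(rep(tissues, each = nrep), "_r",
                          rep(seq_len(nrep), ncol(means)))
  design <- data.frame(sample_id = colnames(tpm),
                       tissue = rep(tissues, each = nrep))
  expression_atlas(tpm, design)
}

# scalar-loop tau oracle, straight from the index definition
tau_oracle <- function(x) {
  N <- length(x)
  s <- 0
  for (i in seq_len(N)) s <- s + (1 - x[i] / max(x))
  s / (N - 1)
}

# adjusted Rand index from the standard pair-counting formula
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_index - expected)
}
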