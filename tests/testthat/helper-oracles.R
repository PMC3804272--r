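# independent closed-form Welch evaluation (kept free of welch_t's code path)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

# brute-force raw node depth via ape's path enumeration
nd_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  raw <- vapply(seq_len(ntip), function(tip) {
    length(ape::nodepath(tree, root, tip)) - 2L
  }, integer(1))
  stats::setNames(raw / max(raw), tree$tip.label)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# n x 20 composition matrix of iid sequences, for group-comparison tests
random_compositions <- function(n, len = 50, prob = NULL) {
  t(vapply(seq_len(n), function(i) {
    relative_abundance(paste(sample(AMINO_ACIDS, len, TRUE, prob),
                             collapse = ""))
  }, numeric(20)))
}
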