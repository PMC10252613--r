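# Shared fixtures: simple rasters and small feature tables, built in code.

make_disk <- function(r, pad = 5L) {
  n <- 2L * r + 2L * pad
  ctr <- (n + 1) / 2
  m <- matrix(0, n, n)
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2))
  m[idx] <- 1
  m
}

make_square <- function(a, pad = 5L) {
  n <- a + 2L * pad
  m <- matrix(0, n, n)
  m[(pad + 1L):(pad + a), (pad + 1L):(pad + a)] <- 1
  m
}

make_line <- function(len, pad = 5L) {
  m <- matrix(0, 2L * pad + 1L, len + 2L * pad)
  m[pad + 1L, (pad + 1L):(pad + len)] <- 1
  m
}

# A crop with one bright cell disk containing a darker nucleus disk, on a
# dark noisy background; nucleus offset from the crop centre by `offset`.
make_cell_crop <- function(n = 81L, cell_r = 25L, nuc_r = 7L,
                           offset = c(0, 0), seed = 1L) {
  set.seed(seed)
  ctr <- (n + 1) / 2
  m <- matrix(pmax(0, rnorm(n * n, 0, 0.004)), n, n)
  di <- outer(seq_len(n) - ctr, rep(1, n))
  dj <- outer(rep(1, n), seq_len(n) - ctr)
  cell <- di^2 + dj^2 <= cell_r^2
  m[cell] <- pmax(0, rnorm(sum(cell), 0.25, 0.03))
  nin <- (di - offset[1])^2 + (dj - offset[2])^2 <= nuc_r^2
  m[nin] <- abs(rnorm(sum(nin), 0, 0.003))
  m
}

# Tiny normalized 3-cluster feature table for clustering tests.
make_blob_points <- function(n_per = 50L, centres = c(0, 2, 4), sd = 0.05,
                             d = 3L, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(centres, function(mu) {
    matrix(rnorm(n_per * d, mu, sd), ncol = d)
  }))
}

expect_no_failure <- function(expr) expect_error(expr, NA)
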