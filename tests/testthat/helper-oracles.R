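# Fixture builders and independent brute-force oracles used across tests.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# write an 8-bit RGB TIFF directly through the tiff package (independent of
# the package's own writers)
make_rgb_tiff <- function(path, red, green, blue) {
  arr <- array(0, dim = c(nrow(red), ncol(red), 3))
  arr[, , 1] <- red / 255
  arr[, , 2] <- green / 255
  arr[, , 3] <- blue / 255
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  path
}

const_channel <- function(value, stain, nr = 10, nc = 12) {
  channel_image(matrix(as.integer(value), nr, nc), stain)
}

# two-level capture: a rectangular "nucleus" block over flat background
block_capture <- function(bg_dapi = 10, nuc_dapi = 100, bg_fitc = 100,
                          nuc_fitc = 200, nr = 60, nc = 80,
                          rows = 11:40, cols = 21:50) {
  dapi <- matrix(bg_dapi, nr, nc)
  fitc <- matrix(bg_fitc, nr, nc)
  dapi[rows, cols] <- nuc_dapi
  fitc[rows, cols] <- nuc_fitc
  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- TRUE
  list(capture = paired_capture("block",
                                channel_image(dapi, "DAPI"),
                                channel_image(fitc, "FITC")),
       mask = mask)
}

# AUC as the tie-adjusted probability that a positive outscores a negative
# (explicit double loop; ties count half)
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

accuracy_at <- function(scores, labels, t) mean((scores >= t) == labels)

# rank-then-Pearson from first principles
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exact two-sided Mann-Whitney p by enumerating group assignments, with U
# computed from its pairwise-comparison definition (not the rank sum)
mw_exact_brute <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(ix) {
    x <- pooled[ix]; y <- pooled[-ix]
    s <- 0
    for (p in x) for (q in y) s <- s + (p > q) + 0.5 * (p == q)
    s
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, u_of)
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}
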