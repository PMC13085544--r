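# Naive independent reimplementations of the coherence metrics, used as
# oracles: an explicit double loop for the masked MSE and the textbook SSIM
# formula on the extracted mask pixels.
naive_mse <- function(a, b, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (mask[i, j]) { s <- s + (a[i, j] - b[i, j])^2; n <- n + 1 }
  s / n
}
naive_ssim <- function(a, b, mask) {
  x <- a[mask]; y <- b[mask]
  C1 <- 1e-4; C2 <- 9e-4
  ((2 * mean(x) * mean(y) + C1) * (2 * cov(x, y) + C2)) /
    ((mean(x)^2 + mean(y)^2 + C1) * (var(x) + var(y) + C2))
}
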