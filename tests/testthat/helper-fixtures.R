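# Shared fixtures and independent oracles, built in code at test time.

# a solid-colour image with optional arm rectangles in a part label map
solid_image <- function(h = 40, w = 40, rgb = c(119L, 119L, 119L)) {
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

paint_rect <- function(img, rows, cols, rgb) {
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# brute-force tolerance counting, independent of the metrics implementation
brute_accuracy <- function(gold, pred, margin, K) {
  hits <- 0
  for (i in seq_along(gold)) {
    if (abs(pred[i] - gold[i]) <= floor(margin * K)) hits <- hits + 1
  }
  hits / length(gold)
}

brute_balanced <- function(gold, pred, margin, K) {
  recalls <- c()
  for (k in seq_len(K)) {
    idx <- which(gold == k)
    if (length(idx) > 0) {
      recalls <- c(recalls, brute_accuracy(gold[idx], pred[idx], margin, K))
    }
  }
  mean(recalls)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (no ties assumed)
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  combos <- utils::combn(length(pooled), n_a)
  mu <- n_a * length(b) / 2
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# interval-scan classifier, independent of classify_ita's counting rule
scan_classify <- function(x, scale) {
  hi <- c(Inf, scale$boundaries)
  lo <- c(scale$boundaries, -Inf)
  for (k in seq_len(scale$K)) {
    if (x < hi[k] && x >= lo[k]) return(k)
  }
  stop("unclassifiable value")
}
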