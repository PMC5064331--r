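# Independent oracles kept deliberately naive: they are what the fast
# implementations are checked against.

# AUC by exhaustive enumeration of all (case, control) pairs
brute_auc <- function(control, case) {
  wins <- 0
  for (a in case) for (b in control)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(case) * length(control))
}

# morphological opening of a vector by brute-force sliding min then max
brute_opening <- function(x, h) {
  n <- length(x)
  win <- function(i) max(1L, i - h):min(n, i + h)
  er <- vapply(seq_len(n), function(i) min(x[win(i)]), numeric(1))
  vapply(seq_len(n), function(i) max(er[win(i)]), numeric(1))
}

# 2D median filter by direct neighborhood medians (replicated edges)
brute_median2d <- function(img, k) {
  h <- (k - 1L) %/% 2L
  out <- img
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    rs <- pmin(pmax((r - h):(r + h), 1L), nrow(img))
    cs <- pmin(pmax((cc - h):(cc + h), 1L), ncol(img))
    out[r, cc] <- median(img[rs, cs])
  }
  out
}
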