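## Shared fixtures and independent oracles for the test suite.

## Small, fast phantom settings used across module tests.
small_params <- function(seed = 1L, ...) {
  phantomParams(extentMM = c(2.2, 1.2, 2.2),
                ispimSpacingMM = rep(0.02, 3),
                truthSpacingMM = rep(0.02, 3),
                seed = seed, ...)
}

## One cached small phantom (generated on first use).
.fixtures <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- generatePhantom(small_params(seed = 4L),
                                    sides = "anterior")
  .fixtures$ph
}

## Build a PhantomTruth by hand for closed-form render checks.
make_truth <- function(labels, lipid = NULL, hemoglobin = NULL,
                       nuclei = matrix(0, 0, 3), spacing = rep(0.02, 3)) {
  d <- dim(labels)
  if (is.null(lipid)) {
    lipid <- array(0, d); lipid[labels == 1L] <- 1
  }
  if (is.null(hemoglobin)) {
    hemoglobin <- array(0, d); hemoglobin[labels == 6L] <- 1
  }
  new("PhantomTruth", labels = labels, lipid = lipid,
      hemoglobin = hemoglobin, nuclei = nuclei,
      tissue = array(labels > 0L, d), spacingMM = spacing)
}

## --- independent oracles -------------------------------------------------

## Exhaustive Otsu: between-class variance computed directly from pixels
## for every candidate bin-edge threshold; first (lowest) argmax wins.
otsu_brute_force <- function(v, nBins = 256L) {
  v <- as.vector(v)
  lo <- min(v); hi <- max(v)
  edges <- lo + seq_len(nBins - 1L) * (hi - lo) / nBins
  best_t <- NA_real_; best_s <- -Inf
  for (t in edges) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (!length(c0) || !length(c1)) next
    w0 <- length(c0) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-15) { best_s <- s; best_t <- t }
  }
  best_t
}

## Per-pixel loop sum of binary slices.
composition_loop_sum <- function(slices) {
  d <- dim(slices[[1]])
  out <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (s in slices)
        out[i, j] <- out[i, j] + as.integer(s[i, j])
  out
}

## All-pairs Mann-Whitney AUC with half-credit ties.
auc_brute_force <- function(scores, labels, polarity = "high",
                            positive = "cancerous") {
  s <- if (polarity == "low") -as.numeric(scores) else as.numeric(scores)
  sp <- s[labels == positive]; sn <- s[labels != positive]
  tot <- 0
  for (a in sp)
    for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## Count strict 6-neighbour local maxima above a floor.
count_local_maxima <- function(arr, floor = 0.5) {
  d <- dim(arr)
  n <- 0L
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    v <- arr[i, j, k]
    if (v <= floor) next
    if (v > arr[i - 1, j, k] && v > arr[i + 1, j, k] &&
        v > arr[i, j - 1, k] && v > arr[i, j + 1, k] &&
        v > arr[i, j, k - 1] && v > arr[i, j, k + 1])
      n <- n + 1L
  }
  n
}
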