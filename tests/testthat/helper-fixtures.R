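# Shared fixtures built in code.

default_array <- function(condition = "organized", seed = 0L)
  build_array(condition = condition, seed = seed)

# recall order: all targets grouped by category (maximal clustering)
blocked_order <- function(arr) {
  tg <- arr$items[arr$items$is_target, ]
  tg$item[order(tg$category)]
}

# an array whose 12 targets fill rows 0-1 (a 2x6 block), plus a
# snake-path recall order through that block
two_row_block_array <- function() {
  # geometric fixture: the 12 targets fill rows 0-1 (a contiguous 2x6
  # block), so the target adjacency graph admits a Hamiltonian path
  arr <- build_array(condition = "organized")
  arr$items$is_target <- arr$items$row <= 1
  arr
}

snake_order <- function(arr) {
  tg <- arr$items[arr$items$is_target, ]
  stopifnot(nrow(tg) == 12, all(tg$row %in% 0:1))
  r0 <- tg[tg$row == 0, ]; r0 <- r0$item[order(r0$col)]
  r1 <- tg[tg$row == 1, ]; r1 <- r1$item[order(-r1$col)]
  c(r0, r1)
}

# independent single-pass scoring oracle over an arbitrary circled
# sequence: returns the three scores by brute-force pair checks
score_oracle <- function(seqn, arr) {
  tg <- arr$items$item[arr$items$is_target]
  hits <- seqn[seqn %in% tg]
  tot <- length(hits)
  clu <- 0L; vis <- 0L
  if (tot >= 2) for (i in 1:(tot - 1)) {
    ca <- arr$items$category[arr$items$item == hits[i]]
    cb <- arr$items$category[arr$items$item == hits[i + 1]]
    if (ca == cb) clu <- clu + 1L
    pa <- arr$items[arr$items$item == hits[i], c("row", "col")]
    pb <- arr$items[arr$items$item == hits[i + 1], c("row", "col")]
    if (abs(pa$row - pb$row) + abs(pa$col - pb$col) == 1) vis <- vis + 1L
  }
  c(total = tot, clustering = clu, scanning = vis)
}

# moment-matched raw data: n values with exact mean m and sd s
moment_matched <- function(m, s, n) {
  x <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  m + s * x
}

# small recording with known artifact structure
flat_recording <- function(value = 0, duration_s = 2, fs = 256) {
  eeg_recording(matrix(value, 19, duration_s * fs), fs = fs)
}
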