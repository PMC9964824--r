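# Independent oracles for segmentation.

# Nearest-haze-neighbour oracle: a non-haze day is bridged iff the haze days
# closest to it on both sides leave a gap of at most max_bridge days; the
# episode-day mask is haze | bridged. Vectorized over a calendar matrix
# (rows = calendars, columns = days).
oracle_episode_masks <- function(H, max_bridge) {
  n <- ncol(H)
  prev <- matrix(0L, nrow(H), n)
  nxt <- matrix(n + 1L, nrow(H), n)
  prev[, 1] <- ifelse(H[, 1], 1L, 0L)
  for (j in seq_len(n)[-1])
    prev[, j] <- pmax(prev[, j - 1], ifelse(H[, j], j, 0L))
  nxt[, n] <- ifelse(H[, n], n, n + 1L)
  for (j in rev(seq_len(n - 1)))
    nxt[, j] <- pmin(nxt[, j + 1], ifelse(H[, j], j, n + 1L))
  bridged <- !H & prev > 0L & nxt <= n & (nxt - prev - 1L) <= max_bridge
  H | bridged
}

# Fixpoint merge oracle for a single calendar: start from single-run
# episodes, repeatedly merge neighbours while the separating gap is small.
oracle_merge_episodes <- function(haze, max_bridge) {
  idx <- which(haze)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  spans <- lapply(idx, function(i) c(i, i))
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(spans)) {
      if (spans[[i + 1]][1] - spans[[i]][2] - 1L <= max_bridge) {
        spans[[i]] <- c(spans[[i]][1], spans[[i + 1]][2])
        spans[[i + 1]] <- NULL
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  do.call(rbind, spans)
}

# episode-day mask implied by segment_episodes() output, over `dates`
episodes_to_mask <- function(episodes, dates) {
  mask <- logical(length(dates))
  for (i in seq_len(nrow(episodes)))
    mask[dates >= episodes$start[i] & dates <= episodes$end[i]] <- TRUE
  mask
}
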