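# Descending within-row ranks of a small-width numeric matrix, via pairwise
# comparison counts (ties share the lower rank; callers break ties by adding
# sub-resolution jitter first). O(ncol^2) vectorised passes, no row apply.
row_rank_desc <- function(m) {
  p <- ncol(m)
  cnt <- matrix(0L, nrow(m), p)
  for (j in seq_len(p)) {
    for (l in seq_len(p)) {
      if (l != j) cnt[, j] <- cnt[, j] + (m[, l] > m[, j])
    }
  }
  cnt + 1L
}
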