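# independent oracle implementations shared by the unit and acceptance
# suites; written as literal restatements of the published rules, kept
# separate from the package's own code paths

# cluster join rule applied exhaustively, without the package's scan
brute_force_clusters <- function(pos, m, gap = 200000, r_threshold = 0.8) {
  n <- length(pos)
  cluster <- seq_len(n)
  if (n >= 2) {
    for (k in 2:n) {
      joined <- FALSE
      if (pos[k] - pos[k - 1] < gap) {
        mid <- (pos[k] + pos[k - 1]) / 2
        for (a in seq_len(n)) for (b in seq_len(n)) {
          if (pos[a] > mid - gap && pos[a] <= mid &&
              pos[b] > mid && pos[b] < mid + gap &&
              m[a, b] > r_threshold) joined <- TRUE
        }
      }
      if (joined) cluster[k] <- cluster[k - 1]
    }
  }
  match(cluster, unique(cluster))
}

# all multisets of size 6 over the 0.05-resolution frequency grid; the
# pattern rules are symmetric in populations, so this covers the full
# 21^6 grid up to permutation
pattern_grid_multisets <- function(by = 0.05) {
  grid <- seq(0, 1, by = by)
  combos <- utils::combn(length(grid) + 5L, 6L)
  idx <- combos - 0:5
  matrix(grid[idx], ncol = 6, byrow = TRUE)
}

# scalar restatement of the frequency-pattern classification
oracle_classify <- function(v) {
  hi <- sum(v >= 0.75); lost <- sum(v < 0.05)
  if (hi == 6 || (hi == 5 && lost == 1)) return("high_frequency")
  if (all(v >= 0.1 & v <= 0.9) && mean(v) >= 0.25 && mean(v) <= 0.75)
    return("mid_frequency")
  "other"
}
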