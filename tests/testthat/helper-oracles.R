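# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no findInterval binning, no subset sampling).

# All-pairs Ripley h: i and j both range over every localization (m = n),
# pairs at distance exactly 0 score 0, strict < d.
ripley_h_allpairs <- function(x, y, area, distances) {
  n <- length(x)
  total <- numeric(length(distances))
  for (i in seq_len(n)) {
    di <- sqrt((x - x[i])^2 + (y - y[i])^2)
    di <- di[di > 0]
    for (k in seq_along(distances)) {
      total[k] <- total[k] + sum(di < distances[k])
    }
  }
  K <- area * total / (n * (n - 1))
  sqrt(K / pi) - distances
}

# per-test-point neighbour counts at one distance, for subset-SE estimates
neighbor_counts_at <- function(x, y, idx, d) {
  vapply(idx, function(i) {
    di <- sqrt((x - x[i])^2 + (y - y[i])^2)
    sum(di > 0 & di < d)
  }, double(1))
}

# standard 5 x 5 um^2 analysis window
reg55 <- function() region(0, 5000, 0, 5000)

# truth-derived track partition of a blinking scene, as a canonical string
partition_signature <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")),
        collapse = ";")
}
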