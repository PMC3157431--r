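# Fixtures are built in code: small intensity tables with known structure.

# Table whose every spot carries the same value.
uniform_table <- function(nR = 8, nC = 8, value = 100, two = FALSE,
                          ch2value = value) {
  g <- expand.grid(row = seq_len(nR) - 1L, col = seq_len(nC) - 1L)
  spotIntensityTable(
    data.frame(row = g$row, col = g$col, ch1 = value,
               ch2 = if (two) ch2value else NA_real_),
    nR, nC)
}

# Table with exact (noise-free) per-ring means taken from `means[ring]`.
ring_profile_table <- function(means, nR = 8, nC = 8) {
  g <- expand.grid(row = seq_len(nR) - 1L, col = seq_len(nC) - 1L)
  ring <- ringPosition(g$row, g$col, nR, nC)
  spotIntensityTable(
    data.frame(row = g$row, col = g$col, ch1 = means[ring]),
    nR, nC)
}

# Independent ring oracle: 1 + Chebyshev distance to the nearest border
# cell, by explicit minimisation over the border set.
ring_oracle <- function(r, c, nR, nC) {
  border <- unique(rbind(
    expand.grid(r = 0:(nR - 1), c = c(0L, nC - 1L)),
    expand.grid(r = c(0L, nR - 1L), c = 0:(nC - 1))))
  1L + min(pmax(abs(border$r - r), abs(border$c - c)))
}
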