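# Small shared fixtures. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly on one CPU.

small_spec <- function(channels = 8L, head_depth = 1L, ...) {
  net_spec(donut_K = 3L, paths = list(c(2L, 1L), c(3L, 1L)),
           channels = channels, head_depth = head_depth, ...)
}

small_net <- function(seed = 1L, ...) build_network(small_spec(...), seed = seed)

# Deterministic structured image pair used for frozen metric oracles.
metric_fixture <- function(n = 48L) {
  i <- matrix(rep(seq_len(n), n), n, n)
  j <- t(i)
  x <- ((i * 7 + j * 13) %% 29) / 29
  y <- pmin(pmax(x + 0.08 * sin(0.3 * i) * cos(0.2 * j), 0), 1)
  list(x = x, y = y)
}

offsets_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), check.attributes = FALSE)) &&
    nrow(a) == nrow(b)
}
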