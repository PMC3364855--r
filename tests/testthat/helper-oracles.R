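# Independent oracles and fixture builders used across the suite.

# Hypergeometric upper tail by direct combinatorial summation (no phyper).
hyper_tail_oracle <- function(N, K, n, k) {
  j <- seq.int(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Hypergeometric upper tail by literal enumeration of every size-n draw.
hyper_tail_enumeration <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Classic (weight-0) KS enrichment score by an explicit position walk.
es_walk_oracle <- function(n, hit_positions) {
  m <- length(hit_positions)
  rs <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + if (i %in% hit_positions) 1 / m else -1 / (n - m)
    rs[i] <- s
  }
  hi <- max(rs)
  lo <- min(rs)
  if (hi >= -lo) hi else lo
}

# Write a small CSV plate fixture; returns its path.
write_plate_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

# Two-gene, two-dose fixture with hand-computable normalization.
demo_plate_rows <- function() {
  tibble::tibble(
    plate = "P1",
    well = sprintf("%s%02d", rep(LETTERS[1:8], each = 2), rep(1:2, 8)),
    gene = c("UNTREATED", "UNTREATED", "SCRAMBLE", "SCRAMBLE",
             "GENEA", "GENEA", "GENEB", "GENEB",
             "GENEA", "GENEA", "GENEB", "GENEB",
             "SCRAMBLE", "SCRAMBLE", "DRUG_ONLY", "DRUG_ONLY"),
    sirna_id = c(NA, NA, NA, NA,
                 "si-A", "si-A", "si-B", "si-B",
                 "si-A", "si-A", "si-B", "si-B",
                 NA, NA, NA, NA),
    dose = c(0, 0, 0, 0, 0, 0, 0, 0, 5, 5, 5, 5, 5, 5, 5, 5),
    replicate = rep(1:2, 8),
    signal = c(1000, 1000, 950, 1050,  # untreated mean 1000, scramble(0) 1000
               900, 900, 800, 800,     # gene baselines
               450, 450, 600, 600,     # gene at dose 5
               700, 700, 720, 680)     # scramble(5) 700, drug-only 700
  )
}

write_gmt_fixture <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}
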