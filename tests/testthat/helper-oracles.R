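# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (diagonal scans and nested loops) so they share no code
# with the suffix-array / union-find implementation paths they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# longest maximal repeated substring by diagonal runs: for every position
# offset d, match runs between s[i] and s[i+d] give the repeat at (i, i+d)
brute_longest_exact <- function(s) {
  ch <- chars(s)
  n <- length(ch)
  best <- 0
  for (d in seq2(1L, n - 1L)) {
    eq <- ch[seq_len(n - d)] == ch[seq_len(n - d) + d]
    r <- rle(eq)
    if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
  }
  best
}

# longest substring occurring at >= 3 distinct positions
brute_longest_triple <- function(s) {
  n <- nchar(s)
  for (len in rev(seq_len(n - 2))) {
    subs <- substring(s, 1:(n - len + 1), len:n)
    if (any(table(subs) >= 3)) return(len)
  }
  0L
}

# all maximal repeated position pairs (0-based) with length >= floor_len
brute_repeat_pairs <- function(s, floor_len) {
  ch <- chars(s)
  n <- length(ch)
  out <- NULL
  for (t1 in seq2(0L, n - 2L)) {
    for (t2 in seq2(t1 + 1L, n - 1L)) {
      if (t1 > 0 && ch[t1] == ch[t2]) next  # not left-maximal
      len <- 0L
      while (t2 + len < n && ch[t1 + len + 1L] == ch[t2 + len + 1L]) {
        len <- len + 1L
      }
      if (len >= floor_len) {
        out <- rbind(out, data.frame(t1 = t1, t2 = t2, len = len))
      }
    }
  }
  if (is.null(out)) data.frame(t1 = integer(0), t2 = integer(0),
                               len = integer(0)) else out
}

# longest interleaved pair by nested loops over brute repeat pairs
brute_interleaved <- function(s, floor_len = 1L) {
  pr <- brute_repeat_pairs(s, floor_len)
  best <- 0L
  if (nrow(pr) < 2) return(best)
  for (a in seq_len(nrow(pr) - 1)) {
    for (b in seq2(a + 1L, nrow(pr))) {
      pos <- c(pr$t1[a], pr$t2[a], pr$t1[b], pr$t2[b])
      if (length(unique(pos)) < 4) next
      inside <- (pr$t1[b] > pr$t1[a] && pr$t1[b] < pr$t2[a]) +
        (pr$t2[b] > pr$t1[a] && pr$t2[b] < pr$t2[a])
      if (inside == 1) best <- max(best, min(pr$len[a], pr$len[b]))
    }
  }
  best
}

# is `a` a rotation of `b`?
rotation_equal <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

# model genome used throughout the assembly benchmarks: longest flanked
# repeat 500 (exact), interleaving partner of flanked length 200 whose two
# polymorphic sites leave a longest exact run of 100
fig8_spec <- function(G, seed, circular = FALSE) {
  genome_spec(G = G, flanked_max = 500, flanked_int = 200,
              exact_max = 500, exact_int = 100, n_int = 2,
              circular = circular, seed = seed)
}

# noiseless-limit overlap parameters for a given genome size
noiseless_params <- function(G, epsilon = 0.05) {
  solve_liid_alpha(0, epsilon, G)
}
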