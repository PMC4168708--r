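test_that("longest exact repeat matches examples and brute force", {
  r <- longest_exact_repeat("ACGTACGT")
  expect_equal(r$len, 4)
  expect_equal(c(r$t1, r$t2), c(0, 4))
  expect_equal(longest_exact_repeat("ACGT")$len, 0)

  set.seed(31)
  for (k in 1:120) {
    n <- sample(10:80, 1)
    s <- rand_dna(n)
    expect_equal(longest_exact_repeat(s)$len, brute_longest_exact(s),
                 info = s)
  }
  # a few longer cases
  for (k in 1:10) {
    s <- rand_dna(200)
    expect_equal(longest_exact_repeat(s)$len, brute_longest_exact(s))
  }
})

test_that("longest triple repeat matches examples and brute force", {
  expect_equal(longest_triple_repeat("ACACAC")$len, brute_longest_triple("ACACAC"))
  expect_equal(longest_triple_repeat("ACGTTGCA")$len, 0)
  set.seed(32)
  for (k in 1:80) {
    n <- sample(12:60, 1)
    s <- rand_dna(n)
    expect_equal(longest_triple_repeat(s)$len, brute_longest_triple(s),
                 info = s)
  }
})

test_that("interleaved pair detection matches construction and brute force", {
  # -X-Y-X-Y- with |X| = 8, |Y| = 5
  set.seed(33)
  X <- rand_dna(8); Y <- rand_dna(5)
  s <- paste0(rand_dna(15), X, rand_dna(12), Y, rand_dna(14), X,
              rand_dna(11), Y, rand_dna(13))
  got <- longest_interleaved_pair(s, floor_len = 4)
  expect_equal(got$len, brute_interleaved(s, 4))
  expect_gte(got$len, 5)

  # tandem -X-X- only: no alternating pair
  X <- rand_dna(10)
  s2 <- paste0(rand_dna(20), X, rand_dna(20), X, rand_dna(20))
  expect_equal(longest_interleaved_pair(s2, floor_len = 4)$len,
               brute_interleaved(s2, 4))

  # random property cases
  for (k in 1:25) {
    s3 <- rand_dna(sample(30:70, 1))
    expect_equal(longest_interleaved_pair(s3, floor_len = 3)$len,
                 brute_interleaved(s3, 3), info = s3)
  }
})

test_that("flanked repeats extend exact seeds through sparse polymorphism", {
  # exact repeat with clean random flanks stays close to its exact length
  set.seed(34)
  R <- rand_dna(120)
  s <- paste0(rand_dna(150), R, rand_dna(150), R, rand_dna(150))
  fr <- flanked_repeats(s, floor_len = 12)
  expect_true(any(abs(fr$len - 120) <= 20))

  # two exact 80-mers separated by a 2-mismatch gap of 10 merge into one
  # flanked repeat of about 170
  A <- rand_dna(80); B <- rand_dna(80); gap <- rand_dna(10)
  gap2 <- chars(gap)
  gap2[c(3, 7)] <- vapply(gap2[c(3, 7)], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  copy1 <- paste0(A, gap, B)
  copy2 <- paste0(A, paste(gap2, collapse = ""), B)
  s <- paste0(rand_dna(100), copy1, rand_dna(100), copy2, rand_dna(100))
  fr <- flanked_repeats(s, floor_len = 12)
  expect_true(any(fr$len >= 160))

  # planted flanked length 200 with 2 sites detected within one window
  for (sd in 201:210) {
    g <- simulate_genome(fig8_spec(6000, sd))
    fr <- flanked_repeats(g, floor_len = 12)
    expect_true(any(abs(fr$len - 200) <= 25), info = sd)
  }
})

test_that("critical lengths are the pairwise maxima", {
  st <- list(exact_int = 100, exact_tri = 80, flanked_int = 210,
             flanked_tri = 90)
  cl <- critical_lengths(st)
  expect_equal(cl$exact_crit, 100)
  expect_equal(cl$flanked_crit, 210)
})

test_that("circular statistics are rotation invariant", {
  g <- simulate_genome(fig8_spec(6000, 55, circular = TRUE))
  s <- g$bases
  rot <- paste0(substr(s, 2001, 6000), substr(s, 1, 2000))
  a <- repeat_stats(s, circular = TRUE)
  b <- repeat_stats(rot, circular = TRUE)
  expect_equal(a$exact_max, b$exact_max)
  expect_equal(a$exact_int, b$exact_int)
  expect_equal(a$exact_tri, b$exact_tri)
})

test_that("appending random bases never shrinks the planted exact repeat", {
  g <- simulate_genome(fig8_spec(6000, 77))
  base <- longest_exact_repeat(g)$len
  set.seed(78)
  ext <- paste0(g$bases, rand_dna(500))
  expect_gte(longest_exact_repeat(ext)$len, base)
})
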