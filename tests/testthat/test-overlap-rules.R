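test_that("KL divergence matches closed forms", {
  expect_equal(kl_divergence(0.5, 0.5), 0)
  expect_equal(kl_divergence(0, 0.75), log(4))
  expect_equal(kl_divergence(0.25, 0.75), 0.5493, tolerance = 1e-4)
  expect_equal(kl_divergence(0, 0), 0)
  expect_true(is.infinite(kl_divergence(0.5, 0)))
  expect_error(kl_divergence(1.2, 0.5), "out of")
})

test_that("same-base mismatch rate follows 2p - 4p^2/3", {
  expect_equal(same_base_mismatch_rate(0), 0)
  expect_equal(same_base_mismatch_rate(0.75), 0.75)
  expect_equal(same_base_mismatch_rate(0.01), 0.019867, tolerance = 1e-4)
})

test_that("the (l_iid, alpha) solver satisfies both budget equations", {
  for (G in c(1e4, 1e6)) {
    op <- solve_liid_alpha(0.01, 0.05, G)
    target <- log(0.05 / 6)
    lhs1 <- 2 * log(G) - op$l_iid * kl_divergence(op$alpha, 3 / 4)
    lhs2 <- log(G) - op$l_iid *
      kl_divergence(op$alpha, same_base_mismatch_rate(0.01))
    expect_lte(lhs1, target + 1e-9)
    expect_lte(lhs2, target + 1e-9)
    expect_gt(op$alpha, same_base_mismatch_rate(0.01))
    expect_lt(op$alpha, 0.75)
  }
})

test_that("l_iid is nondecreasing in G and of order tens", {
  ls <- vapply(c(1e5, 1e6, 1e7), function(G) {
    solve_liid_alpha(0.01, 0.05, G)$l_iid
  }, numeric(1))
  expect_true(all(diff(ls) >= 0))
  # anchor lengths are tens of bases, far below repeat scales
  op <- solve_liid_alpha(0.01, 0.05, 5e6)
  expect_true(op$l_iid >= 10 && op$l_iid <= 99)
})

test_that("noiseless limit gives exact-match anchors", {
  op <- solve_liid_alpha(0, 0.05, 1e4)
  expect_lt(op$alpha * op$l_iid, 1)
})

test_that("hamming distance counts mismatches", {
  expect_equal(hamming("ACGT", "ACGT"), 0)
  expect_equal(hamming("AAAA", "TTTT"), 4)
  expect_error(hamming("AC", "ACG"), "equal length")
  set.seed(41)
  x <- rand_dna(1e4); y <- rand_dna(1e4)
  expect_true(abs(hamming(x, y) - 7500) < 150)
})

test_that("RA-matching requires whole-segment and both anchors to pass", {
  par <- overlap_params(l_iid = 20, alpha = 0.25)
  set.seed(42)
  x <- rand_dna(100)
  expect_true(ra_match(x, x, par))

  flip <- function(s, idx) {
    ch <- chars(s)
    ch[idx] <- vapply(ch[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  # 30 mismatches all inside positions 21..80: whole test fails (30 >= 25)
  y <- flip(x, sample(21:80, 30))
  expect_false(ra_match(x, y, par))
  # clean interior, 10 mismatches in the last 20 bases: suffix anchor fails
  y2 <- flip(x, sample(81:100, 10))
  expect_false(ra_match(x, y2, par))
  # 4 anchor mismatches and a clean interior passes (4 < 5, total 8 < 25)
  y3 <- flip(x, c(1:4, 97:100))
  expect_true(ra_match(x, y3, par))
  expect_error(ra_match("ACGTA", "ACGTA", par), "shorter than l_iid")
})

test_that("RA-overlap returns the maximal qualifying W", {
  par <- overlap_params(l_iid = 15, alpha = 0.25)
  set.seed(43)
  r1 <- rand_dna(100)
  expect_equal(ra_overlap(r1, r1, par), 100)

  # noiseless reads offset by k on random background overlap by L - k
  g <- rand_dna(300)
  for (k in c(10, 40, 80)) {
    a <- substr(g, 1, 100)
    b <- substr(g, 1 + k, 100 + k)
    expect_equal(ra_overlap(a, b, par), 100 - k)
  }
  # below l_iid: no overlap
  b <- substr(g, 95, 194)
  expect_equal(ra_overlap(substr(g, 1, 100), b, par), 0)
})

test_that("noisy same-locus overlaps are recovered within the error budget", {
  G <- 1e4
  op <- solve_liid_alpha(0.01, 0.05, G)
  set.seed(44)
  fails <- 0
  trials <- 300
  for (t in seq_len(trials)) {
    g <- rand_dna(120)
    a <- corrupt_substitution(substr(g, 1, 100), 0.01)
    b <- corrupt_substitution(substr(g, 11, 110), 0.01)
    if (ra_overlap(a, b, op) != 90) fails <- fails + 1
  }
  # the per-pair failure budget is far below epsilon/3; allow Monte Carlo slack
  expect_lte(fails, 3)
})

test_that("fingerprint candidates find shared f-mers with correct offsets", {
  set.seed(45)
  g <- rand_dna(200)
  a <- substr(g, 1, 80)
  b <- substr(g, 31, 110)
  cand <- fingerprint_candidates(c(a, b), f = 16)
  expect_true(any(cand$i == 1 & cand$j == 2 & cand$offset == 30))

  # f longer than the reads: empty candidate set
  cand2 <- fingerprint_candidates(c("ACGTACGT", "ACGTACGT"), f = 16)
  expect_equal(nrow(cand2), 0)
})

test_that("noiseless candidates are a superset of true overlapping pairs", {
  g <- simulate_genome(genome_spec(G = 5000, seed = 46))
  reads <- sample_reads(g, 200, 80, seed = 47)
  cand <- fingerprint_candidates(reads$bases, f = 16)
  key <- paste(pmin(cand$i, cand$j), pmax(cand$i, cand$j))
  st <- reads$truth_start
  for (i in 1:199) {
    for (j in (i + 1):200) {
      ov <- 80 - abs(st[i] - st[j])
      if (ov >= 16) {
        expect_true(paste(i, j) %in% key,
                    info = paste(i, j, "overlap", ov))
      }
    }
  }
})

test_that("RA-overlap is suffix/prefix dual on noiseless data", {
  par <- overlap_params(l_iid = 15, alpha = 0.25)
  set.seed(48)
  g <- rand_dna(200)
  a <- substr(g, 1, 100); b <- substr(g, 26, 125)
  revstr <- function(s) paste(rev(chars(s)), collapse = "")
  expect_equal(ra_overlap(a, b, par), ra_overlap(revstr(b), revstr(a), par))
})
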