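test_that("background generation is seeded, uniform and sized", {
  expect_equal(generate_background(0), "")
  expect_identical(generate_background(500, seed = 9),
                   generate_background(500, seed = 9))
  s <- generate_background(100000, seed = 1)
  freq <- table(chars(s)) / 100000
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("background composition passes a chi-square check across seeds", {
  pvals <- vapply(1:20, function(sd) {
    s <- generate_background(4000, seed = sd)
    stats::chisq.test(table(factor(chars(s),
                                   levels = c("A", "C", "G", "T"))))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("polymorphism placement hits the exact target run length", {
  # no edits: single run over the whole repeat
  set.seed(2)
  pm <- place_polymorphism(rand_dna(80), 0, 80)
  expect_length(pm$sites, 0)
  expect_identical(pm$copies[1], pm$copies[2])

  # the interior runs between sites are exactly the target
  longest_common_run <- function(c1, c2) {
    eq <- chars(c1) == chars(c2)
    r <- rle(eq)
    max(c(0, r$lengths[r$values]))
  }
  set.seed(3)
  pm <- place_polymorphism(rand_dna(200), 2, 100)
  expect_equal(longest_common_run(pm$copies[1], pm$copies[2]), 100)
  expect_equal(length(pm$sites), 2)
  expect_true(all(substring(pm$copies[1], pm$sites + 1, pm$sites + 1) !=
                  substring(pm$copies[2], pm$sites + 1, pm$sites + 1)))

  # exhaustive small case: flanked 20, target 7, 2 sites
  for (rep in 1:10) {
    pm <- place_polymorphism(rand_dna(20), 2, 7)
    expect_equal(longest_common_run(pm$copies[1], pm$copies[2]), 7)
  }

  expect_error(place_polymorphism(rand_dna(20), 0, 7), "at least")
  expect_error(place_polymorphism(rand_dna(20), 1, 25), "target exceeds")
})

test_that("planted interleaved copies alternate along the genome", {
  for (sd in 1:5) {
    g <- simulate_genome(fig8_spec(8000, sd))
    x <- g$truth[[1]]$copy_starts
    y <- g$truth[[2]]$copy_starts
    pos <- sort(c(x, y))
    expect_equal(pos, c(x[1], y[1], x[2], y[2]))
  }
})

test_that("copies are identical except at recorded polymorphism sites", {
  g <- simulate_genome(fig8_spec(8000, 21))
  for (occ in g$truth) {
    cps <- vapply(occ$copy_starts, function(t0) {
      substr(g$bases, t0 + 1, t0 + occ$flanked_length)
    }, character(1))
    diffs <- which(chars(cps[1]) != chars(cps[2]))
    expect_equal(diffs - 1L, occ$polymorphism_sites)
  }
})

test_that("re-measured repeat statistics recover the planted spec", {
  for (sd in 101:110) {
    spec <- fig8_spec(8000, sd)
    g <- simulate_genome(spec)
    st <- repeat_stats(g)
    expect_equal(st$exact_max, 500)
    expect_equal(st$exact_int, 100)
    expect_equal(st$exact_crit, max(spec$exact_int, st$exact_tri))
    # flanked detector is window-resolution accurate
    expect_true(abs(st$flanked_max - 500) <= 25)
    expect_true(abs(st$flanked_int - 200) <= 25)
  }
})

test_that("triple repeats plant three copies with recoverable length", {
  spec <- genome_spec(G = 12000, flanked_max = 400, flanked_int = 150,
                      flanked_tri = 120, exact_int = 75, n_int = 1,
                      exact_tri = 120, seed = 5)
  g <- simulate_genome(spec)
  expect_equal(length(g$truth), 3)
  tri <- g$truth[[3]]
  expect_equal(length(tri$copy_starts), 3)
  st <- repeat_stats(g)
  expect_equal(st$exact_tri, 120)
})

test_that("spec invariants are enforced", {
  expect_error(genome_spec(G = 5000, flanked_max = 100, flanked_int = 200,
                           seed = 1),
               "flanked_max")
  expect_error(genome_spec(G = 5000, flanked_max = 200, exact_max = 300,
                           seed = 1),
               "exceeds flanked")
  expect_error(genome_spec(G = 900, flanked_max = 400, seed = 1),
               "do not fit")
  expect_error(genome_spec(G = 5000, flanked_max = 200, exact_max = 50,
                           n_max = 0, seed = 1),
               "at least")
  expect_error(generate_background(-1), "nonnegative")
})
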