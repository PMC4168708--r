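test_that("greedy requirement has its asymptote and is self-consistent", {
  G <- 1e6; l <- 30; eps <- 0.05; fmax <- 2000
  expect_equal(prop1_requirement(G, fmax, l, eps, fmax + 2 * l), Inf)

  L <- fmax + 2 * l + 300
  N <- prop1_requirement(G, fmax, l, eps, L)
  denom <- L - fmax - 2 * l
  ok <- function(m) m > G * log(3 / eps) / denom &&
    m > G * log(3 * m / eps) / denom
  expect_true(ok(N))
  expect_false(ok(N - 1))

  Ls <- seq(fmax + 2 * l + 100, fmax + 2 * l + 2000, length.out = 10)
  Ns <- vapply(Ls, function(x) prop1_requirement(G, fmax, l, eps, x),
               numeric(1))
  expect_true(all(diff(Ns) < 0))
})

test_that("multibridging requirement dominates and uses both denominators", {
  G <- 1e6; l <- 30; eps <- 0.05; fmax <- 2000; fcrit <- 800
  expect_equal(prop2_requirement(G, fcrit, l, eps, fcrit + 2 * l), Inf)
  Ls <- seq(fmax + 2 * l + 100, fmax + 2 * l + 3000, length.out = 8)
  for (L in Ls) {
    n1 <- prop1_requirement(G, fmax, l, eps, L)
    n2 <- prop2_requirement(G, fcrit, l, eps, L)
    expect_lte(n2, n1)
  }
  # at large L the coverage term G ln(3N/eps)/(L - 2l) dominates
  L <- 50000
  N <- prop2_requirement(G, fcrit, l, eps, L)
  cov_term <- G * log(3 * N / eps) / (L - 2 * l)
  bridge_term <- G * log(3 / eps) / (L - fcrit - 2 * l)
  expect_gt(cov_term, bridge_term)
})

test_that("X-phased requirement has the exact-repeat asymptote", {
  G <- 1e6; l <- 30; eps <- 0.05
  expect_equal(xphase_requirement(G, 800, l, 3, eps, 800 + 2 * l), Inf)
  # asymptote strictly left of the multibridging one when flanked > exact
  expect_lt(800 + 2 * l, 2000 + 2 * l)
  # k = 1 with the flanked length behaves like a prop-2-style bridging bound
  N1 <- xphase_requirement(G, 800, l, 1, eps, 1200)
  N3 <- xphase_requirement(G, 800, l, 3, eps, 1200)
  expect_lte(N1, N3)
})

test_that("Poisson bridging model matches direct read-placement simulation", {
  G <- 5e4; L <- 150; N <- 4000; k <- 3
  spans <- c(110, 90, 120)
  dc <- delta_cov(N, L, G, spans, k)
  # direct simulation of uniform read starts
  set.seed(111)
  fails <- 0
  mc <- 3000
  anchors <- c(0, 5000, 11000)  # link start positions (arbitrary, disjoint)
  for (t in seq_len(mc)) {
    starts <- sample.int(G - L + 1L, N, TRUE) - 1L
    bad <- FALSE
    for (j in seq_along(spans)) {
      cnt <- sum(starts <= anchors[j] & starts + L >= anchors[j] + spans[j])
      if (cnt < k) { bad <- TRUE; break }
    }
    fails <- fails + bad
  }
  mc_rate <- fails / mc
  expect_lt(abs(mc_rate - dc$delta_cov), max(0.1 * dc$delta_cov, 0.02))
})

test_that("delta_cov limits are exact", {
  expect_equal(delta_cov(1e9, 100, 1e4, c(50, 60), 3)$delta_cov, 0)
  expect_equal(delta_cov(100, 100, 1e4, c(50, 60), 0)$delta_cov, 0)
  expect_warning(out <- delta_cov(100, 100, 1e4, c(150), 3), "exceeds")
  expect_equal(out$delta_cov, 1)
})

test_that("read-extension error is zero without noise and small with k reads", {
  expect_equal(estimate_eps2(0, 3, trials = 2000, seed = 1)$eps2, 0)
  e1 <- estimate_eps2(0.01, 1, trials = 20000, seed = 2)
  e3 <- estimate_eps2(0.01, 3, trials = 20000, seed = 3)
  expect_gt(e1$eps2, e3$eps2)
})

test_that("consensus-step error vanishes at deep coverage", {
  e <- estimate_eps1(repeat_len = 600, n_sites = 2, coverage = 60,
                     p = 0.01, trials = 100, L = 100, seed = 4)
  expect_equal(e$eps1, 0)
})

test_that("feasibility curves are ordered by algorithm efficiency", {
  st <- list(flanked_max = 500, flanked_int = 200, flanked_tri = 0,
             exact_int = 100, exact_tri = 0)
  G <- 1e4; p <- 0.015; eps <- 0.05
  L_grid <- seq(320, 600, by = 40)
  cg <- feasibility_curve("greedy", st, G, p, eps, L_grid)
  cm <- feasibility_curve("multibridge", st, G, p, eps, L_grid)
  cx <- feasibility_curve("xphase", st, G, p, eps, L_grid)
  feas <- is.finite(cg$N_min)
  expect_true(all(cm$N_min[feas] <= cg$N_min[feas]))
  a_g <- attr(cg, "asymptote_L"); a_m <- attr(cm, "asymptote_L")
  a_x <- attr(cx, "asymptote_L")
  expect_true(a_x < a_m && a_m < a_g)
  # X-phased closes the read-length gap: finite requirement strictly left
  # of the multibridging asymptote, and a lower requirement just above it
  # (for long reads the three-bridging-read condition costs more coverage
  # than single bridging, so the curves cross further right)
  L_gap <- ceiling((a_x + a_m) / 2)
  expect_true(is.finite(xphase_requirement(G, st$exact_int,
                                           attr(cx, "l_iid"), 3, eps, L_gap)))
  expect_equal(prop2_requirement(G, st$flanked_int, attr(cm, "l_iid"),
                                 eps, L_gap), Inf)
  L_near <- a_m + 20
  expect_lt(xphase_requirement(G, st$exact_int, attr(cx, "l_iid"), 3, eps,
                               L_near),
            prop2_requirement(G, st$flanked_int, attr(cm, "l_iid"), eps,
                              L_near))
})
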