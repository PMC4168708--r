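toy_params <- function(l_iid = 6L, alpha = 0.3, f = 8L) {
  overlap_params(l_iid = l_iid, alpha = alpha, f = f)
}

test_that("De Bruijn construction on single reads matches the definition", {
  par <- toy_params()
  set.seed(61)
  r <- rand_dna(30)
  cl <- cluster_kmers(r, 30, par)
  g <- build_debruijn(cl)
  expect_equal(n_nodes(g), 1)
  expect_equal(nrow(g$edges), 0)

  cl2 <- cluster_kmers(r, 29, par)
  g2 <- build_debruijn(cl2)
  expect_equal(n_nodes(g2), 2)
  expect_equal(nrow(g2$edges), 1)
})

test_that("noiseless full-coverage clusters equal distinct genome windows", {
  set.seed(62)
  g <- rand_dna(120)
  starts <- 0:(120 - 30)
  reads <- substring(g, starts + 1, starts + 30)
  par <- toy_params(l_iid = 8)
  cl <- cluster_kmers(reads, 16, par)
  expect_equal(length(cl$reps), 120 - 16 + 1)
  asm <- multibridge_assemble(reads, par, K = 16)
  expect_identical(asm$contigs, g)
})

test_that("overlap clustering agrees with the brute-force RA closure", {
  par <- toy_params(l_iid = 6, alpha = 0.2, f = 8)
  set.seed(63)
  repeat {
    g <- rand_dna(70)
    if (longest_exact_repeat(g)$len < 8) break
  }
  starts <- sort(sample(0:40, 10, replace = TRUE))
  reads <- substring(g, starts + 1, starts + 30)
  a <- cluster_kmers(reads, 16, par, method = "overlap")
  b <- cluster_kmers(reads, 16, par, method = "oracle")
  # same partitions up to label renaming
  expect_equal(length(unique(a$assign)), length(unique(b$assign)))
  relabel <- function(x) match(x, unique(x))
  expect_equal(relabel(a$assign), relabel(b$assign))
})

test_that("exact repeat K-mers land in one cluster", {
  set.seed(65)
  R <- rand_dna(24)
  g <- paste0(rand_dna(40), R, rand_dna(40), R, rand_dna(40))
  starts <- 0:(nchar(g) - 30)
  reads <- substring(g, starts + 1, starts + 30)
  par <- toy_params(l_iid = 8)
  cl <- cluster_kmers(reads, 20, par)
  # the window fully inside both repeat copies shares a cluster
  i1 <- 40 + 2  # 0-based window start inside first copy
  i2 <- 104 + 2
  s1 <- which(cl$slot_read == i1 + 1 & cl$slot_pos == 0)
  s2 <- which(cl$slot_read == i2 + 1 & cl$slot_pos == 0)
  expect_equal(cl$assign[s1], cl$assign[s2])
})

test_that("condense contracts chains and preserves the spelled sequence", {
  par <- toy_params()
  set.seed(66)
  g <- rand_dna(60)
  starts <- 0:(60 - 20)
  reads <- substring(g, starts + 1, starts + 20)
  cl <- cluster_kmers(reads, 12, par)
  gr <- build_debruijn(cl)
  gc <- condense(gr)
  expect_equal(n_nodes(gc), 1)
  expect_equal(length(gc$labels[[1]]), 60 - 12 + 1)
  expect_identical(as.character(euler_spell(gc)),
                   as.character(euler_spell(gr)))
  expect_identical(as.character(euler_spell(gc)), g)
})

test_that("condensation leaves branch centers untouched", {
  # two-in/two-out X built directly from an interleaved repeat fixture
  g <- simulate_genome(genome_spec(G = 4000, flanked_max = 300,
                                   flanked_int = 120, exact_int = 120,
                                   seed = 67))
  par <- noiseless_params(4000)
  reads <- sample_reads(g, 2200, 60, seed = 68)
  asm <- suppressWarnings(multibridge_assemble(reads, par, K = 40))
  deg <- xmb:::node_degrees(asm$graph)
  expect_true(any(deg$ind >= 2 & deg$outd >= 2))
})

test_that("spell is preserved through condense on random chain graphs", {
  par <- toy_params()
  set.seed(69)
  for (k in 1:20) {
    n <- sample(40:90, 1)
    g <- rand_dna(n)
    L <- sample(16:24, 1)
    starts <- 0:(n - L)
    reads <- substring(g, starts + 1, starts + L)
    K <- sample(10:(L - 2), 1)
    cl <- cluster_kmers(reads, K, par)
    gr <- build_debruijn(cl)
    expect_identical(paste(sort(euler_spell(condense(gr))), collapse = "+"),
                     paste(sort(euler_spell(gr)), collapse = "+"))
  }
})

test_that("join bridges a coverage gap at the implied overlap", {
  set.seed(70)
  g <- rand_dna(200)
  K <- 30
  # reads covering everything except windows starting in 84..86 (gap of 3)
  starts <- setdiff(0:(200 - 40), 60:86)
  reads <- substring(g, starts + 1, starts + 40)
  par <- toy_params(l_iid = 8, f = 8)
  cl <- cluster_kmers(reads, K, par)
  gr <- build_debruijn(cl)
  deg0 <- xmb:::node_degrees(gr)
  expect_true(any(deg0$outd == 0 & deg0$ind > 0) || any(deg0$outd == 0))
  gj <- join_components(gr, par)
  expect_gt(sum(gj$edges$joined), 0)
  ctg <- euler_spell(condense(gj))
  expect_equal(length(ctg), 1)
  expect_identical(as.character(ctg), g)
})

test_that("fully connected graphs pass through join unchanged", {
  set.seed(71)
  g <- rand_dna(100)
  starts <- 0:(100 - 25)
  reads <- substring(g, starts + 1, starts + 25)
  par <- toy_params(l_iid = 6)
  cl <- cluster_kmers(reads, 15, par)
  gr <- build_debruijn(cl)
  gj <- join_components(gr, par)
  expect_equal(nrow(gj$edges), nrow(gr$edges))
})

test_that("clear_branches removes short bubbles and keeps legitimate paths", {
  # hand-built graph: chain with a 1-node bubble
  par <- toy_params()
  set.seed(72)
  g <- rand_dna(80)
  starts <- 0:(80 - 20)
  reads <- substring(g, starts + 1, starts + 20)
  cl <- cluster_kmers(reads, 12, par)
  gr <- build_debruijn(cl)
  # duplicate one middle cluster as a parallel bubble node
  v <- 30L
  n0 <- n_nodes(gr)
  gr$labels[[n0 + 1L]] <- gr$labels[[v]]
  gr$label_ov[[n0 + 1L]] <- gr$label_ov[[v]]
  gr$node_support[n0 + 1L] <- 1
  gr$site_overrides[n0 + 1L] <- list(NULL)
  gr$dropped <- c(gr$dropped, FALSE)
  e <- gr$edges
  prev_e <- which(e$to == v)[1]
  next_e <- which(e$from == v)[1]
  gr$edges <- rbind(e, data.frame(from = e$from[prev_e], to = n0 + 1L,
                                  ov = 11L, n = 1L, joined = FALSE),
                    data.frame(from = n0 + 1L, to = e$to[next_e],
                               ov = 11L, n = 1L, joined = FALSE))
  gc <- condense(gr)
  deg <- xmb:::node_degrees(gc)
  expect_true(any(deg$outd > 1))
  gb <- clear_branches(gc, l_iid = 6)
  degb <- xmb:::node_degrees(gb)
  expect_false(any(degb$outd > 1))
  expect_identical(as.character(euler_spell(condense(gb))), g)
  # noiseless clean graphs are fixed points
  cl2 <- cluster_kmers(reads, 12, par)
  gr2 <- condense(build_debruijn(cl2))
  gb2 <- clear_branches(gr2, l_iid = 6)
  expect_equal(n_nodes(gb2), n_nodes(gr2))
})

test_that("euler spelling resolves a lone repeat but not interleaved repeats", {
  # single two-copy repeat: unique Euler path reconstructs the genome
  set.seed(73)
  R <- rand_dna(40)
  g1 <- paste0(rand_dna(60), R, rand_dna(60), R, rand_dna(60))
  starts <- 0:(nchar(g1) - 30)
  reads <- substring(g1, starts + 1, starts + 30)
  # noiseless data: strict threshold (alpha * l_iid < 1) for exact matching
  par <- toy_params(l_iid = 8, alpha = 0.1)
  asm <- multibridge_assemble(reads, par, K = 20)
  expect_equal(length(asm$contigs), 1)
  expect_identical(asm$contigs, g1)

  # interleaved -X-Y-X-Y-: two Euler paths, honest multi-contig output
  X <- rand_dna(40); Y <- rand_dna(40)
  g2 <- paste0(rand_dna(60), X, rand_dna(60), Y, rand_dna(60), X,
               rand_dna(60), Y, rand_dna(60))
  starts <- 0:(nchar(g2) - 30)
  reads2 <- substring(g2, starts + 1, starts + 30)
  asm2 <- suppressWarnings(multibridge_assemble(reads2, par, K = 20))
  expect_gt(length(asm2$contigs), 1)
  expect_true(asm2$ambiguous)
})

test_that("multibridging matches greedy on an unbridged-free fixture", {
  G <- 4000
  spec <- genome_spec(G = G, flanked_max = 150, flanked_int = 60,
                      exact_int = 60, seed = 74)
  g <- simulate_genome(spec)
  p <- 0.01
  op <- solve_liid_alpha(p, 0.05, G)
  L <- 150 + 2 * op$l_iid + 60
  N <- prop1_requirement(G, 150, op$l_iid, 0.05, L)
  reads <- simulate_reads(g, sequencing_params(N, L, p = p), seed = 75)
  a1 <- greedy_assemble(reads, op)
  a2 <- multibridge_assemble(reads, op, flanked_crit = 60)
  ev1 <- evaluate_assembly(a1, g, delta = 2 * p * G)
  ev2 <- evaluate_assembly(a2, g, delta = 2 * p * G)
  expect_true(ev1$success_delta)
  expect_true(ev2$success_delta)
})

test_that("an unbridged flanked approximate interleaved repeat defeats multibridging", {
  # exact interior 100 < L < flanked length 200: the X-node cannot be
  # separated by the RA-rule and the Euler path is ambiguous
  G <- 5000
  p <- 0.015
  op <- solve_liid_alpha(p, 0.05, G)
  g <- simulate_genome(fig8_spec(G, 76))
  N <- xphase_requirement(G, 100, op$l_iid, 3, 0.05, 195)
  reads <- simulate_reads(g, sequencing_params(N, 195, p = p), seed = 77)
  asm <- suppressWarnings(multibridge_assemble(reads, op, K = 120))
  expect_gt(length(asm$contigs), 1)
})

test_that("pairwise overlap alignment handles indels", {
  par <- toy_params(l_iid = 10, f = 8)
  set.seed(78)
  g <- rand_dna(120)
  a <- substr(g, 1, 80)
  bch <- chars(substr(g, 21, 100))
  b <- paste(bch[-40], collapse = "")  # one deletion
  st <- pairwise_overlap_align(c(a, b), par, band = 8)
  row <- st[st$offset > 0, , drop = FALSE][1, ]
  expect_equal(row$dist, 1)
  expect_true(row$accepted)

  # identity on true overlaps under the stated generator
  reads <- sample_reads(g, 40, 60, seed = 79)
  noisy <- corrupt_indel(reads, 0.015, 0.015, seed = 80)
  st2 <- pairwise_overlap_align(noisy$bases, par, band = 12)
  acc <- st2[st2$accepted & st2$W >= 30, ]
  ident <- 1 - acc$dist / acc$W
  # pairwise edit density is about twice the per-read indel rate plus
  # alignment end effects; far from the 0.75 random mismatch rate
  expect_gt(mean(ident), 1 - 0.03 * 3)
})

test_that("edge-direction repair fixes inverted edges and spares clean data", {
  # constructed 3-node graph with one inverted minority edge
  gr <- list(
    K = 10L, reps = c("A", "B", "C"), sizes = c(5L, 5L, 5L),
    cons_last = c("A", "B", "C"), read_bases = NULL,
    labels = list(1L, 2L, 3L), label_ov = rep(list(integer(0)), 3),
    node_support = c(5, 5, 5), dropped = logical(3),
    edges = data.frame(from = c(1L, 2L, 3L), to = c(2L, 3L, 2L),
                       ov = 9L, n = c(6L, 6L, 1L), joined = FALSE),
    site_overrides = rep(list(NULL), 3),
    assign = integer(0), slot_read = integer(0), slot_pos = integer(0))
  class(gr) <- "xmb_graph"
  fixed <- repair_edge_directions(gr)
  expect_equal(attr(fixed, "n_repaired"), 1)
  expect_equal(nrow(fixed$edges), 2)

  # substitution-only data has no inverted adjacencies
  set.seed(81)
  g <- rand_dna(300)
  starts <- 0:(300 - 40)
  reads <- corrupt_substitution(substring(g, starts + 1, starts + 40),
                                0.01, seed = 82)
  par <- toy_params(l_iid = 10, f = 8)
  cl <- cluster_kmers(reads, 25, par)
  gb <- build_debruijn(cl)
  rep_ <- repair_edge_directions(gb)
  expect_equal(attr(rep_, "n_repaired"), 0)
})
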