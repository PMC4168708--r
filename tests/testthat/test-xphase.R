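test_that("chain graphs have no X-nodes; a 2-in/2-out node is found", {
  par <- overlap_params(l_iid = 8, alpha = 0.1, f = 8)
  set.seed(91)
  g <- rand_dna(80)
  starts <- 0:(80 - 20)
  reads <- substring(g, starts + 1, starts + 20)
  cl <- cluster_kmers(reads, 12, par)
  gc <- condense(build_debruijn(cl))
  expect_equal(nrow(find_xnodes(gc)), 0)

  R <- rand_dna(40)
  g2 <- paste0(rand_dna(60), R, rand_dna(60), R, rand_dna(60))
  starts <- 0:(nchar(g2) - 30)
  reads2 <- substring(g2, starts + 1, starts + 30)
  cl2 <- cluster_kmers(reads2, 20, par)
  gc2 <- condense(build_debruijn(cl2))
  xn <- find_xnodes(gc2)
  expect_equal(nrow(xn), 1)
  expect_equal(xn$ind, 2)
  expect_equal(xn$outd, 2)
})

test_that("the consensus step calls sites from mixture counts", {
  # synthetic alignment: one column with a 10/10 A/G split, one homogeneous
  al <- structure(list(
    reads_idx = 1:20,
    offset = rep(0L, 20),
    bases = c(rep("AA", 10), rep("GA", 10)),
    in_flank = rep(NA_integer_, 20), out_flank = rep(NA_integer_, 20),
    in_nodes = integer(0), out_nodes = integer(0),
    node = 1L, node_len = 2L), class = "xmb_xalign")
  sites <- consensus_sites(al, p = 0.01)
  expect_equal(sites$col, 1L)
  expect_equal(sort(c(sites$b1, sites$b2)), c("A", "G"))
})

test_that("count-to-extend composes links and never guesses on ties", {
  g <- simulate_genome(fig8_spec(5000, 92))
  op <- solve_liid_alpha(0.015, 0.05, 5000)
  N <- xphase_requirement(5000, 100, op$l_iid, 3, 0.05, 195)
  reads <- simulate_reads(g, sequencing_params(N, 195, p = 0.015), seed = 93)
  cl <- cluster_kmers(reads, 120, op)
  gc <- condense(clear_branches(condense(join_components(
    build_debruijn(cl), op)), op$l_iid))
  xn <- find_xnodes(gc)
  # locate the planted polymorphic repeat among the X-nodes: it is the one
  # whose consensus shows heterozygous sites
  resolved_with_sites <- FALSE
  for (v in xn$node[xn$ind == 2 & xn$outd == 2]) {
    al <- align_reads_to_xnode(gc, v, reads$bases)
    if (!length(al$reads_idx)) next
    sites <- consensus_sites(al, 0.015)
    ph <- count_to_extend(al, sites)
    if (nrow(sites) >= 2 && isTRUE(ph$resolved)) {
      resolved_with_sites <- TRUE
      # removing non-spanning reads does not change the vote outcome
      keep <- !is.na(al$in_flank) | !is.na(al$out_flank) |
        vapply(seq_along(al$reads_idx), function(k) {
          cols <- sites$col - al$offset[k]
          any(cols >= 1 & cols <= nchar(al$bases[k]))
        }, logical(1))
      al2 <- al
      for (f in c("reads_idx", "offset", "bases", "in_flank", "out_flank")) {
        al2[[f]] <- al[[f]][keep]
      }
      ph2 <- count_to_extend(al2, sites)
      expect_identical(ph$pairing, ph2$pairing)
    }
  }
  expect_true(resolved_with_sites)
})

test_that("count-to-extend leaves zero-vote links unresolved", {
  al <- structure(list(
    reads_idx = 1:4, offset = rep(0L, 4),
    bases = rep("ACGT", 4),
    in_flank = c(7L, 7L, 8L, 8L), out_flank = rep(NA_integer_, 4),
    in_nodes = c(7L, 8L), out_nodes = c(11L, 12L),
    node = 1L, node_len = 4L), class = "xmb_xalign")
  sites <- data.frame(col = integer(0), b1 = character(0),
                      b2 = character(0), margin = numeric(0))
  ph <- count_to_extend(al, sites)
  expect_false(ph$resolved)
})

test_that("MAP phasing agrees with the majority vote on single-site toys", {
  # reads spanning in-flank and one site
  mk_al <- function(bases, inf, outf) {
    structure(list(
      reads_idx = seq_along(bases), offset = rep(0L, length(bases)),
      bases = bases, in_flank = inf, out_flank = outf,
      in_nodes = c(7L, 8L), out_nodes = c(11L, 12L),
      node = 1L, node_len = nchar(bases[1])), class = "xmb_xalign")
  }
  sites <- data.frame(col = 2L, b1 = "A", b2 = "C", margin = 10)
  # W1-anchored reads see A, W2-anchored see C; Y1 reads see A
  al <- mk_al(c("GAG", "GAG", "GCG", "GCG", "GAG", "GCG"),
              c(7L, 7L, 8L, 8L, NA, NA),
              c(NA, NA, NA, NA, 11L, 12L))
  ct <- count_to_extend(al, sites)
  mp <- map_phase(al, sites, p = 0.01)
  expect_true(ct$resolved)
  expect_true(mp$resolved)
  expect_identical(ct$pairing, mp$pairing)
  expect_identical(as.integer(ct$assignment), as.integer(mp$assignment))

  # noiseless unambiguous data gives an overwhelming posterior margin
  expect_gt(mp$margin, 5)
})

test_that("resolving an X-node restores a unique Euler path end to end", {
  G <- 5000
  op <- solve_liid_alpha(0.015, 0.05, G)
  N <- xphase_requirement(G, 100, op$l_iid, 3, 0.05, 195)
  g <- simulate_genome(fig8_spec(G, 94))
  reads <- simulate_reads(g, sequencing_params(N, 195, p = 0.015), seed = 95)
  am <- suppressWarnings(multibridge_assemble(reads, op, K = 120))
  ax <- xphase_assemble(reads, op, K = 120)
  expect_gt(length(am$contigs), 1)
  expect_equal(length(ax$contigs), 1)
  ev <- evaluate_assembly(ax, g)
  expect_gte(ev$percent_match, 99)
  expect_true(any(ax$phasing$resolved))
})

test_that("without X-nodes, X-phased output equals multibridging output", {
  set.seed(96)
  g <- rand_dna(3000)
  op <- solve_liid_alpha(0.01, 0.05, 3000)
  reads <- simulate_reads(g, sequencing_params(900, 120, p = 0.01), seed = 97)
  am <- multibridge_assemble(reads, op, K = 80)
  ax <- xphase_assemble(reads, op, K = 80)
  expect_identical(am$contigs, ax$contigs)
})

test_that("unresolved X-nodes degrade gracefully to more contigs", {
  # same fixture but far too few reads to span any anchors: X-node remains
  G <- 5000
  op <- solve_liid_alpha(0.015, 0.05, G)
  g <- simulate_genome(fig8_spec(G, 98))
  reads <- simulate_reads(g, sequencing_params(900, 195, p = 0.015),
                          seed = 99)
  ax <- suppressWarnings(xphase_assemble(reads, op, K = 120,
                                         log_factor = 1e6))
  # with site calling disabled the repeat cannot be phased
  expect_gt(length(ax$contigs), 1)
})
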