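#' Evaluate an assembly against the reference
#'
#' A single contig is scored by banded global edit distance against the
#' reference, minimized over rotations for circular genomes (the contig is
#' located on the doubled reference via shared fingerprints before
#' alignment). Multi-contig output is scored by greedily tiling contigs onto
#' the reference (longest first, non-overlapping placements) and summing
#' matched bases. percent_match = 100 (1 - edits / max(|contig|, G)) for a
#' single contig, and 100 * matched / G for a tiling.
#'
#' @param contigs character vector (or `xmb_assembly`).
#' @param reference `xmb_genome` or DNA string.
#' @param circular minimize over rotations.
#' @param delta edit-distance tolerance for `success_delta` (use 2 p G).
#' @return object of class `xmb_eval`: `n_contigs`, `edit_distance`,
#'   `percent_match`, `success_delta`, `success_99`, `success_95`.
#' @export
evaluate_assembly <- function(contigs, reference, circular = FALSE,
                              delta = 0) {
  if (inherits(contigs, "xmb_assembly")) contigs <- contigs$contigs
  ref <- genome_string(reference)
  G <- nchar(ref)
  if (G == 0) stop("evaluate_assembly: empty reference")
  if (!length(contigs) || all(nchar(contigs) == 0)) {
    return(structure(list(n_contigs = 0L, edit_distance = NA_integer_,
                          percent_match = 0, success_delta = FALSE,
                          success_99 = FALSE, success_95 = FALSE),
                     class = "xmb_eval"))
  }
  n_contigs <- length(contigs)
  if (n_contigs == 1) {
    ed <- contig_edit_distance(contigs, ref, circular)
    pm <- 100 * (1 - ed / max(nchar(contigs), G))
    out <- list(n_contigs = 1L, edit_distance = as.integer(ed),
                percent_match = pm,
                success_delta = is.finite(ed) && ed <= delta,
                success_99 = pm >= 99, success_95 = pm >= 95)
  } else {
    matched <- tile_contigs(contigs, ref, circular)
    pm <- 100 * matched / G
    out <- list(n_contigs = as.integer(n_contigs),
                edit_distance = NA_integer_, percent_match = pm,
                success_delta = FALSE, success_99 = FALSE,
                success_95 = pm >= 95)
  }
  structure(out, class = "xmb_eval")
}

# banded edit distance with adaptive band doubling; circular references are
# doubled and the contig anchored by fingerprint offset vote first
contig_edit_distance <- function(contig, ref, circular) {
  G <- nchar(ref)
  if (circular) {
    ref2 <- paste0(ref, ref)
    off <- locate_offset(contig, ref2)
    if (is.na(off)) off <- 0L
    ref_rot <- substr(paste0(substr(ref, off %% G + 1L, G),
                             substr(ref, 1L, off %% G)), 1L, G)
    ref <- ref_rot
  }
  band <- max(abs(nchar(contig) - nchar(ref)) + 32L, 64L)
  repeat {
    d <- cpp_banded_edit(contig, ref, band)
    if (d >= 0) return(d)
    band <- band * 2L
    if (band > max(nchar(contig), nchar(ref))) {
      return(cpp_banded_edit(contig, ref, band))
    }
  }
}

# most-voted diagonal of exact shared 16-mers between contig and reference
locate_offset <- function(contig, ref) {
  cand <- cpp_fingerprint_candidates(c(contig, ref), 16L, 3L, 1L)
  cand <- cand[cand$i == 1 & cand$j == 2, , drop = FALSE]
  if (!nrow(cand)) return(NA_integer_)
  -cand$offset[which.max(cand$votes)]  # contig starts here on the reference
}

tile_contigs <- function(contigs, ref, circular) {
  G <- nchar(ref)
  ref2 <- if (circular) paste0(ref, ref) else ref
  ord <- order(-nchar(contigs))
  contigs <- contigs[ord]
  keep <- nchar(contigs) >= 16
  contigs <- contigs[keep]
  if (!length(contigs)) return(0)
  # one shared fingerprint pass: reference is the last sequence
  m <- length(contigs)
  cand <- cpp_fingerprint_candidates(c(contigs, ref2), 16L, 3L, 1L)
  cand <- cand[cand$j == m + 1L, , drop = FALSE]
  covered <- logical(G)
  matched_total <- 0
  for (k in seq_len(m)) {
    ct <- contigs[k]
    ck <- cand[cand$i == k, , drop = FALSE]
    if (!nrow(ck)) next
    off <- -ck$offset[which.max(ck$votes)]
    if (is.na(off) || off < 0) next
    len <- min(nchar(ct), nchar(ref2) - off)
    seg <- substr(ref2, off + 1L, off + len)
    band <- max(abs(nchar(ct) - len) + 32L, 64L)
    d <- cpp_banded_edit(ct, seg, band)
    if (d < 0) d <- band  # clipped: count what the band allows
    mm <- max(0, len - d)
    pos <- ((off + seq_len(len) - 1L) %% G) + 1L
    new <- !covered[pos]
    matched_total <- matched_total + mm * mean(new)
    covered[pos[new]] <- TRUE
  }
  min(matched_total, G)
}

#' @export
print.xmb_eval <- function(x, ...) {
  cat(sprintf(
    "assembly eval: %d contig(s), edit distance %s, %.2f%% match\n",
    x$n_contigs, ifelse(is.na(x$edit_distance), "NA", x$edit_distance),
    x$percent_match))
  invisible(x)
}

#' Run a seeded simulation experiment
#'
#' Drives genome simulation, read simulation, assembly and evaluation over a
#' number of rounds, one row per round. This is the engine behind the
#' synthetic benchmark sweeps (substitution- and indel-noise success rates).
#'
#' @param spec_fn function(seed) returning an `xmb_genome_spec`.
#' @param N,L read count and length.
#' @param noise `"sub"` or `"indel"`.
#' @param p substitution rate (sub mode).
#' @param p_i,p_d indel rates (indel mode).
#' @param epsilon failure budget (calibrates l_iid).
#' @param algorithm `"greedy"`, `"multibridge"` or `"xphase"`.
#' @param rounds number of seeded rounds.
#' @param seed base seed; round r uses seed + r.
#' @param K K-mer length override passed to the graph assemblers.
#' @param index_stride fingerprint stride.
#' @param phase_mode phasing mode for xphase.
#' @return data.frame with one row per round: seed, n_contigs,
#'   percent_match, success flags.
#' @export
run_experiment <- function(spec_fn, N, L, noise = "sub", p = 0.015,
                           p_i = 0.015, p_d = 0.015, epsilon = 0.05,
                           algorithm = "xphase", rounds = 30L, seed = 1L,
                           K = NULL, index_stride = 1L,
                           phase_mode = "count") {
  rows <- vector("list", rounds)
  for (r in seq2(1L, rounds)) {
    rseed <- seed + r
    spec <- spec_fn(rseed)
    genome <- simulate_genome(spec)
    G <- nchar(genome$bases)
    params <- sequencing_params(N = N, L = L, p = p, p_i = p_i, p_d = p_d,
                                epsilon = epsilon, G = G)
    reads <- simulate_reads(genome, params, seed = rseed, noise = noise)
    p_eff <- if (noise == "sub") p else p_i + p_d
    op <- solve_liid_alpha(if (noise == "sub") p else p_eff, epsilon, G)
    asm <- switch(algorithm,
      greedy = greedy_assemble(reads, op, index_stride = index_stride),
      multibridge = multibridge_assemble(reads, op, K = K, noise = noise,
                                         p_indel = p_i + p_d,
                                         index_stride = index_stride),
      xphase = xphase_assemble(reads, op, K = K, noise = noise,
                               p_indel = p_i + p_d,
                               phase_mode = phase_mode,
                               index_stride = index_stride))
    ev <- evaluate_assembly(asm, genome, delta = params$delta)
    rows[[r]] <- data.frame(
      seed = rseed, N = N, L = L, coverage = N * L / G,
      algorithm = algorithm, n_contigs = ev$n_contigs,
      percent_match = ev$percent_match,
      success_delta = ev$success_delta, success_99 = ev$success_99,
      success_95 = ev$success_95)
  }
  if (!rounds) {
    return(data.frame(seed = integer(0), N = integer(0), L = integer(0),
                      coverage = numeric(0), algorithm = character(0),
                      n_contigs = integer(0), percent_match = numeric(0),
                      success_delta = logical(0), success_99 = logical(0),
                      success_95 = logical(0)))
  }
  do.call(rbind, rows)
}
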