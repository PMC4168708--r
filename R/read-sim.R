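#' Sequencing model parameters
#'
#' Holds the shotgun model: N reads of length L sampled uniformly from the
#' genome, corrupted either by substitution noise (each base replaced by one
#' of the three other bases with total probability p) or by indel noise
#' (per-base deletion probability p_d; geometric insertion chains with
#' per-base probability p_i). epsilon is the overall failure budget of an
#' assembly run, and delta the edit-distance tolerance of a successful
#' reconstruction (default 2 p G, the expected noise floor when the spelled
#' output is not consensus-polished).
#'
#' @param N number of reads.
#' @param L read length (bases).
#' @param p substitution probability per base.
#' @param p_i,p_d insertion / deletion probabilities per base.
#' @param epsilon failure budget in (0, 1).
#' @param delta edit-distance tolerance; default 2 * p * G when G is given.
#' @param G genome length (used only for the delta default).
#' @return object of class `xmb_seq_params`.
#' @export
sequencing_params <- function(N, L, p = 0, p_i = 0, p_d = 0, epsilon = 0.05,
                              delta = NULL, G = NULL) {
  if (N < 1 || L < 1) stop("sequencing_params: N and L must be >= 1")
  if (p < 0 || p > 1 || p_i < 0 || p_i >= 1 || p_d < 0 || p_d >= 1) {
    stop("sequencing_params: noise probabilities out of range")
  }
  if (is.null(delta)) delta <- if (!is.null(G)) 2 * p * G else 0
  if (delta < 0) stop("sequencing_params: delta must be >= 0")
  structure(list(N = as.integer(N), L = as.integer(L), p = p, p_i = p_i,
                 p_d = p_d, epsilon = epsilon, delta = delta),
            class = "xmb_seq_params")
}

#' Sample noiseless reads uniformly from a genome
#'
#' Linear genomes draw start positions from [0, G - L] (no ragged ends);
#' circular genomes draw from [0, G) and wrap around the origin. Bases are
#' copied exactly; noise is applied separately so the true origin of every
#' read is recorded for oracle tests.
#'
#' @param genome an `xmb_genome` or a DNA string.
#' @param N number of reads.
#' @param L read length; must be <= G.
#' @param seed optional integer seed.
#' @param circular overrides the genome's own flag when it is a plain string.
#' @return object of class `xmb_reads`: `bases`, `truth_start` (0-based), `L`.
#' @export
sample_reads <- function(genome, N, L, seed = NULL, circular = NULL) {
  s <- genome_string(genome)
  if (is.null(circular)) {
    circular <- if (inherits(genome, "xmb_genome")) genome$circular else FALSE
  }
  G <- nchar(s)
  if (L > G) stop("sample_reads: L exceeds genome length")
  if (!is.null(seed)) set.seed(seed)
  if (circular) {
    starts <- sample.int(G, N, replace = TRUE) - 1L
    s2 <- paste0(s, substr(s, 1L, L))
    bases <- substring(s2, starts + 1L, starts + L)
  } else {
    starts <- sample.int(G - L + 1L, N, replace = TRUE) - 1L
    bases <- substring(s, starts + 1L, starts + L)
  }
  structure(list(bases = bases, truth_start = starts, L = as.integer(L),
                 circular = circular, G = G),
            class = "xmb_reads")
}

genome_string <- function(genome) {
  if (inherits(genome, "xmb_genome")) genome$bases
  else if (is.character(genome) && length(genome) == 1) genome
  else stop("expected an xmb_genome or a single DNA string")
}

#' Substitution noise
#'
#' Each base is independently replaced, with total probability p, by one of
#' the three other bases (probability p/3 each). Length is preserved.
#'
#' @param reads `xmb_reads` or character vector.
#' @param p substitution probability in [0, 1].
#' @param seed optional integer seed.
#' @return same shape as the input with corrupted bases.
#' @export
corrupt_substitution <- function(reads, p, seed = NULL) {
  if (p < 0 || p > 1) stop("corrupt_substitution: p out of [0,1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (p > 0 && length(bases)) {
    lens <- nchar(bases)
    ch <- strsplit(bases, "", fixed = TRUE)
    flat <- unlist(ch, use.names = FALSE)
    hit <- which(runif(length(flat)) < p)
    if (length(hit)) {
      # uniform over the three other bases: shift by 1..3 in alphabet order
      code <- match(flat[hit], DNA_ALPHABET)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      flat[hit] <- DNA_ALPHABET[((code - 1L + shift) %% 4L) + 1L]
    }
    idx <- rep.int(seq_along(bases), lens)
    bases <- vapply(split(flat, idx), paste, character(1), collapse = "")
    names(bases) <- NULL
  }
  if (inherits(reads, "xmb_reads")) { reads$bases <- bases; reads }
  else bases
}

#' Indel noise
#'
#' Per input base: the base is deleted with probability p_d; independently, a
#' geometric chain of uniformly random bases is inserted before it with
#' per-insertion probability p_i (so the number of inserted bases before each
#' input base is Geometric(1 - p_i)). Output length is random with
#' expectation L * (1 + p_i/(1-p_i) - p_d); at the parameter scales used here
#' that is approximately L * (1 + p_i - p_d).
#'
#' @param reads `xmb_reads` or character vector.
#' @param p_i,p_d insertion / deletion probabilities in [0, 1).
#' @param seed optional integer seed.
#' @return same shape as input; read lengths vary.
#' @export
corrupt_indel <- function(reads, p_i, p_d, seed = NULL) {
  if (p_i < 0 || p_i > 1 || p_d < 0 || p_d > 1) {
    stop("corrupt_indel: probabilities out of range")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if ((p_i > 0 || p_d > 0) && length(bases)) {
    lens <- nchar(bases)
    ch <- strsplit(bases, "", fixed = TRUE)
    flat <- unlist(ch, use.names = FALSE)
    n <- length(flat)
    keep <- if (p_d >= 1) rep(FALSE, n) else runif(n) >= p_d
    nins <- if (p_i > 0) rgeom(n, 1 - p_i) else integer(n)
    total_ins <- sum(nins)
    read_of <- rep.int(seq_along(bases), lens)
    # interleave: for base k, its insertions come first, then (if kept) itself
    reps <- nins + as.integer(keep)
    out_read <- rep.int(read_of, reps)
    out <- character(sum(reps))
    # positions of the kept original bases within the output
    ends <- cumsum(reps)
    if (total_ins > 0) {
      ins_flag <- rep(TRUE, length(out))
      ins_flag[ends[keep]] <- FALSE  # kept base sits last in its block
      out[!ins_flag] <- flat[keep]
      out[ins_flag] <- sample(DNA_ALPHABET, total_ins, replace = TRUE)
    } else {
      out[ends[keep]] <- flat[keep]
    }
    pieces <- split(out, factor(out_read, levels = seq_along(bases)))
    bases <- vapply(pieces, paste, character(1), collapse = "")
    names(bases) <- NULL
  }
  if (inherits(reads, "xmb_reads")) { reads$bases <- bases; reads }
  else bases
}

#' Simulate a full noisy read set
#'
#' @param genome `xmb_genome` or DNA string.
#' @param params `xmb_seq_params`.
#' @param seed integer seed (drives sampling and corruption).
#' @param noise `"sub"` or `"indel"`.
#' @return `xmb_reads` with noisy bases and recorded true origins.
#' @export
simulate_reads <- function(genome, params, seed = 1L, noise = c("sub", "indel")) {
  noise <- match.arg(noise)
  set.seed(seed)
  reads <- sample_reads(genome, params$N, params$L)
  if (noise == "sub") {
    if (params$p > 0) reads <- corrupt_substitution(reads, params$p)
  } else {
    reads <- corrupt_indel(reads, params$p_i, params$p_d)
  }
  reads
}

#' Reads for a target coverage depth
#'
#' Sets N = ceiling(coverage * G / L).
#'
#' @param coverage target NL/G.
#' @param G genome length.
#' @param L read length.
#' @return integer N.
#' @export
reads_for_coverage <- function(coverage, G, L) {
  as.integer(ceiling(coverage * G / L))
}
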