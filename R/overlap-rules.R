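#' Kullback-Leibler divergence between two Bernoulli rates
#'
#' D(a || b) = a log(a/b) + (1-a) log((1-a)/(1-b)) in nats, with the usual
#' convention 0 log 0 = 0. Controls the exponential decay of binomial tail
#' probabilities and hence the anchor-length calibration of the RA-rule.
#'
#' @param a observed rate in [0, 1].
#' @param b reference rate in (0, 1) (b in \{0, 1\} with a != b gives Inf).
#' @return divergence in nats.
#' @export
kl_divergence <- function(a, b) {
  if (a < 0 || a > 1 || b < 0 || b > 1) stop("kl_divergence: rates out of [0,1]")
  if (b %in% c(0, 1) && a != b) return(Inf)
  term <- function(x, y) if (x == 0) 0 else x * log(x / y)
  term(a, b) + term(1 - a, 1 - b)
}

#' Mismatch rate between two noisy observations of the same base
#'
#' Two independent substitution-noisy reads of one base disagree with
#' probability 2p - (4/3) p^2: either exactly one is corrupted, or both are
#' corrupted to different bases.
#'
#' @param p substitution probability per base.
#' @return disagreement probability.
#' @export
same_base_mismatch_rate <- function(p) {
  if (p < 0 || p > 1) stop("same_base_mismatch_rate: p out of [0,1]")
  2 * p - (4 / 3) * p^2
}

#' Solve the anchor-length / threshold calibration of the RA-rule
#'
#' Finds the pair (l_iid, alpha) satisfying simultaneously
#' \deqn{G^2 \exp(-\ell_{iid} D(\alpha \| 3/4)) = \epsilon/6}
#' \deqn{G \exp(-\ell_{iid} D(\alpha \| 2p - \tfrac{4}{3}p^2)) = \epsilon/6}
#' which bounds the total false-positive plus false-negative probability of
#' anchor matching by epsilon/3 over all segment pairs of a length-G genome.
#' Each equation defines a curve l_iid(alpha); the intersection is found by
#' bisection on alpha strictly between the same-base rate and 3/4. l_iid is
#' rounded up to an integer and alpha then re-tightened so both left sides
#' remain at most epsilon/6.
#'
#' The noiseless limit p = 0 has an infinite false-negative exponent; there
#' l_iid is taken from the false-positive equation at alpha -> 0 and alpha is
#' set to 0.5 / l_iid so that alpha * l_iid < 1, i.e. exact matching.
#'
#' @param p substitution rate (0 <= p < 0.3).
#' @param epsilon failure budget in (0, 1).
#' @param G genome length (>= 2).
#' @param f fingerprint length carried along in the parameter object.
#' @return object of class `xmb_overlap_params` with fields `l_iid`, `alpha`,
#'   `W_min` (= l_iid), `f`, and the two residual left sides.
#' @export
solve_liid_alpha <- function(p, epsilon, G, f = 16L) {
  if (p < 0 || p >= 0.3) stop("solve_liid_alpha: need 0 <= p < 0.3")
  if (epsilon <= 0 || epsilon >= 1) stop("solve_liid_alpha: epsilon in (0,1)")
  if (G < 2) stop("solve_liid_alpha: G must be >= 2")
  target <- log(epsilon / 6)
  if (p == 0) {
    l_fp <- ceiling((2 * log(G) - target) / kl_divergence(0, 3 / 4))
    return(overlap_params(l_iid = l_fp, alpha = 0.5 / l_fp, f = f,
                          p = p, epsilon = epsilon, G = G))
  }
  q <- same_base_mismatch_rate(p)
  if (q >= 3 / 4) stop("solve_liid_alpha: reference rates not distinct")
  # l1(alpha): anchor length needed against unrelated segments (rate 3/4)
  # l2(alpha): anchor length needed against same-locus segments (rate q)
  l1 <- function(a) (2 * log(G) - target) / kl_divergence(a, 3 / 4)
  l2 <- function(a) (log(G) - target) / kl_divergence(a, q)
  g <- function(a) l1(a) - l2(a)  # increasing in alpha
  lo <- q + 1e-6; hi <- 3 / 4 - 1e-6
  if (g(lo) > 0 || g(hi) < 0) {
    stop("solve_liid_alpha: no alpha strictly between the reference rates")
  }
  root <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  l_iid <- as.integer(ceiling(max(l1(root), l2(root))))
  # re-tighten alpha at the integer l_iid: any alpha with both residuals
  # <= epsilon/6 works; pick the midpoint of the feasible interval
  a_lo <- uniroot(function(a) l2(a) - l_iid, c(lo, root))$root
  a_hi <- uniroot(function(a) l1(a) - l_iid, c(root, hi))$root
  alpha <- (a_lo + a_hi) / 2
  overlap_params(l_iid = l_iid, alpha = alpha, f = f,
                 p = p, epsilon = epsilon, G = G)
}

#' Construct RA-rule overlap parameters directly
#'
#' @param l_iid anchor length (>= 1).
#' @param alpha mismatch-fraction threshold.
#' @param f fingerprint length.
#' @param p,epsilon,G provenance of the calibration (optional).
#' @return `xmb_overlap_params`.
#' @export
overlap_params <- function(l_iid, alpha, f = 16L, p = NA, epsilon = NA,
                           G = NA) {
  if (l_iid < 1) stop("overlap_params: l_iid must be >= 1")
  res1 <- if (is.na(G)) NA else
    2 * log(G) - l_iid * kl_divergence(alpha, 3 / 4)
  res2 <- if (is.na(G) || is.na(p) || p == 0) NA else
    log(G) - l_iid * kl_divergence(alpha, same_base_mismatch_rate(p))
  structure(list(l_iid = as.integer(l_iid), alpha = alpha,
                 W_min = as.integer(l_iid), f = as.integer(f),
                 p = p, epsilon = epsilon, G = G,
                 log_resid_fp = res1, log_resid_fn = res2),
            class = "xmb_overlap_params")
}

#' @export
print.xmb_overlap_params <- function(x, ...) {
  cat(sprintf("RA-rule params: l_iid = %d, alpha = %.4f (f = %d)\n",
              x$l_iid, x$alpha, x$f))
  invisible(x)
}

#' Hamming distance between equal-length DNA strings
#'
#' @param x,y strings of equal length.
#' @return number of mismatching positions.
#' @export
hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("hamming: sequences must have equal length")
  cpp_hamming(x, y)
}

#' RA-matching of two equal-length segments
#'
#' Segments x, y of length W match under the repeat-aware rule iff the
#' Hamming distance over the whole segments is strictly below alpha * W AND
#' both length-l_iid end windows are strictly below alpha * l_iid. The end
#' anchors are what distinguishes two copies of a long flanked repeat: at
#' least one anchor falls into the random flanking region where the mismatch
#' density between different copies is about 0.75.
#'
#' @param x,y equal-length DNA strings, length >= l_iid.
#' @param params `xmb_overlap_params`.
#' @return logical.
#' @export
ra_match <- function(x, y, params) {
  if (nchar(x) != nchar(y)) stop("ra_match: segments must have equal length")
  if (nchar(x) < params$l_iid) stop("ra_match: segment shorter than l_iid")
  cpp_ra_match(x, y, params$l_iid, params$alpha)
}

#' RA-overlap score between a read and a candidate successor
#'
#' The maximum W in [l_iid, min(|r1|, |r2|)] such that the length-W suffix of
#' r1 RA-matches the length-W prefix of r2; 0 when no W qualifies.
#'
#' @param r1,r2 DNA strings.
#' @param params `xmb_overlap_params`.
#' @return integer overlap length (0 = none).
#' @export
ra_overlap <- function(r1, r2, params) {
  if (min(nchar(r1), nchar(r2)) < params$l_iid) return(0L)
  cpp_ra_overlap(r1, r2, params$l_iid, params$alpha)
}

#' Fingerprint-based candidate overlap pairs
#'
#' Extracts all consecutive f-mers of the reads and finds read pairs sharing
#' at least one exact f-mer, with the implied offsets (lexicographic-sort
#' equivalent, implemented with a hash index). Under noise this is a
#' probabilistic superset of the truly overlapping pairs: a true overlap of
#' length W contains about (W - f) (1-p)^{2f} clean shared f-mers.
#'
#' @param reads `xmb_reads` or character vector.
#' @param f fingerprint length (f > read length gives an empty set).
#' @param max_offsets distinct offsets retained per pair (default 5).
#' @param index_stride subsampling stride of indexed positions (default 1).
#' @return data.frame with columns `i`, `j`, `offset` (read j starts `offset`
#'   bases after read i; may be negative), `votes`.
#' @export
fingerprint_candidates <- function(reads, f = 16L, max_offsets = 5L,
                                   index_stride = 1L) {
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (f > 32) stop("fingerprint_candidates: f must be <= 32")
  cpp_fingerprint_candidates(bases, as.integer(f), as.integer(max_offsets),
                             as.integer(index_stride))
}
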