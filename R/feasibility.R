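#' Read-count requirement of the greedy assembler
#'
#' The greedy assembler needs every flanked repeat bridged by a read with
#' l_iid anchors on both sides and the genome covered; it is epsilon-feasible
#' when L > flanked_max + 2 l_iid and
#' N > max\{ G ln(3/eps) / (L - flanked_max - 2 l_iid),
#'           G ln(3N/eps) / (L - flanked_max - 2 l_iid) \}.
#' The self-referential coverage term is solved by fixed-point iteration
#' (logarithmic dependence, converges in a few steps).
#'
#' @param G genome length.
#' @param flanked_max longest flanked repeat length.
#' @param l_iid anchor length.
#' @param epsilon failure budget.
#' @param L read length.
#' @return smallest integer N satisfying both terms, or `Inf` when L is at or
#'   below the asymptote L = flanked_max + 2 l_iid.
#' @export
prop1_requirement <- function(G, flanked_max, l_iid, epsilon, L) {
  denom <- L - flanked_max - 2 * l_iid
  if (denom <= 0) return(Inf)
  solve_n_requirement(
    explicit = G * log(3 / epsilon) / denom,
    implicit_denom = denom, G = G, epsilon = epsilon)
}

#' Read-count requirement of the multibridging assembler
#'
#' Feasible when L > flanked_crit + 2 l_iid and
#' N > max\{ G ln(3/eps) / (L - flanked_crit - 2 l_iid),
#'           G ln(3N/eps) / (L - 2 l_iid) \}:
#' the bridging term now only involves the critical flanked repeat (the
#' De Bruijn graph resolves everything longer via K-mer bridging), while the
#' coverage term keeps the full effective read length.
#'
#' @inheritParams prop1_requirement
#' @param flanked_crit critical flanked repeat length.
#' @export
prop2_requirement <- function(G, flanked_crit, l_iid, epsilon, L) {
  denom_b <- L - flanked_crit - 2 * l_iid
  if (denom_b <= 0) return(Inf)
  solve_n_requirement(
    explicit = G * log(3 / epsilon) / denom_b,
    implicit_denom = L - 2 * l_iid, G = G, epsilon = epsilon)
}

solve_n_requirement <- function(explicit, implicit_denom, G, epsilon,
                                max_iter = 100L, tol = 1) {
  n <- max(explicit, 1)
  for (k in seq_len(max_iter)) {
    n2 <- max(explicit, G * log(3 * n / epsilon) / implicit_denom)
    if (abs(n2 - n) < tol) { n <- n2; break }
    n <- n2
  }
  n <- ceiling(n)
  # smallest integer: step down while still satisfying both strict bounds
  ok <- function(m) m > explicit && m > G * log(3 * m / epsilon) / implicit_denom
  while (n > 1 && ok(n - 1)) n <- n - 1
  if (!ok(n)) n <- n + 1
  as.integer(n)
}

#' Read-count requirement of X-phased multibridging
#'
#' Phasing succeeds when at least k reads bridge the shorter exact repeat of
#' the longest pair of exact interleaved repeats (plus l_iid anchor margins)
#' and the genome is covered. Bridging counts are Poisson with mean
#' N (L - exact_int - 2 l_iid) / G; the smallest N is returned for which
#' P(fewer than k bridging reads) plus the coverage-gap probability is at
#' most epsilon.
#'
#' @inheritParams prop1_requirement
#' @param exact_int shorter exact repeat length of the critical interleaved
#'   pair.
#' @param k required number of bridging reads (3 for noisy reads at p ~ 1%,
#'   1 in the noiseless case).
#' @export
xphase_requirement <- function(G, exact_int, l_iid, k, epsilon, L) {
  span <- L - exact_int - 2 * l_iid
  if (span <= 0) return(Inf)
  cov_gap <- function(N) {
    # expected uncovered-position probability union bound (Lander-Waterman)
    G * exp(-N * (L - 2 * l_iid) / G)
  }
  bridge_fail <- function(N) ppois(k - 1, N * span / G)
  lo <- 1
  hi <- 2
  while (bridge_fail(hi) + cov_gap(hi) > epsilon && hi < 1e12) hi <- hi * 2
  if (hi >= 1e12) return(Inf)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (bridge_fail(mid) + cov_gap(mid) <= epsilon) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Monte Carlo calibration of the consensus-step error probability
#'
#' Replicates the phasing calibration experiment: a flanked repeat of length
#' `repeat_len` with `n_sites` polymorphic sites partitioning it into equally
#' spaced segments is planted twice in a genome of length `genome_len`; reads
#' of length `L` at the given genome-wide coverage are sampled over both
#' copies, substitution-corrupted at rate p, and handed (with their true
#' offsets) to the consensus step. A trial errs when any site is mislocated,
#' any base pair miscalled, or a spurious site called.
#'
#' @param repeat_len flanked repeat length (default 5000).
#' @param genome_len genome length (default 5e6); only sets the read budget
#'   through the coverage, the flanking context is simulated locally.
#' @param n_sites number of polymorphic sites (default 2).
#' @param coverage genome-wide coverage NL/G.
#' @param p substitution rate.
#' @param trials Monte Carlo trials (>= 100).
#' @param L read length (default 100).
#' @param seed integer seed.
#' @param log_factor polymorphism call threshold (nats).
#' @return list with `eps1`, binomial 95% interval, and `trials`.
#' @export
estimate_eps1 <- function(repeat_len = 5000L, genome_len = 5e6,
                          n_sites = 2L, coverage = 20, p = 0.01,
                          trials = 200L, L = 100L, seed = 1L,
                          log_factor = 2) {
  if (trials < 100) stop("estimate_eps1: trials must be >= 100")
  set.seed(seed)
  # site columns at equal spacing (thirds for n_sites = 2)
  sites_true <- round(seq_len(n_sites) * repeat_len / (n_sites + 1))
  errs <- 0L
  for (tr in seq_len(trials)) {
    interior <- sample(DNA_ALPHABET, repeat_len, TRUE)
    x1 <- interior; x2 <- interior
    b1 <- character(n_sites); b2 <- character(n_sites)
    for (j in seq_len(n_sites)) {
      b1[j] <- x1[sites_true[j]]
      b2[j] <- sample(setdiff(DNA_ALPHABET, b1[j]), 1)
      x2[sites_true[j]] <- b2[j]
    }
    # reads covering the repeat from both copies: per-column depth is
    # coverage per copy; starts uniform over [-(L-1), repeat_len)
    span <- repeat_len + L - 1L
    n_reads <- rpois(1, 2 * coverage * span / L)
    starts <- sample.int(span, n_reads, TRUE) - L  # 0-based vs repeat
    from2 <- runif(n_reads) < 0.5
    counts <- matrix(0L, 4, repeat_len)
    src <- rbind(match(x1, DNA_ALPHABET), match(x2, DNA_ALPHABET))
    cols <- unlist(lapply(starts, function(s) {
      cs <- (s + 1L):(s + L)
      cs[cs >= 1L & cs <= repeat_len]
    }))
    copy_of <- rep(from2 + 1L, vapply(starts, function(s) {
      sum((s + 1L):(s + L) >= 1L & (s + 1L):(s + L) <= repeat_len)
    }, integer(1)))
    code <- src[cbind(copy_of, cols)]
    hit <- runif(length(code)) < p
    if (any(hit)) {
      code[hit] <- ((code[hit] - 1L + sample.int(3L, sum(hit), TRUE)) %% 4L) + 1L
    }
    idx <- (cols - 1L) * 4L + code
    counts <- matrix(tabulate(idx, 4L * repeat_len), nrow = 4)
    called <- consensus_from_counts(counts, p, log_factor)
    err <- !identical(called$col, as.integer(sites_true))
    if (!err) {
      for (j in seq_len(n_sites)) {
        want <- sort(c(b1[j], b2[j]))
        got <- sort(c(called$b1[j], called$b2[j]))
        if (!identical(want, got)) { err <- TRUE; break }
      }
    }
    errs <- errs + err
  }
  ci <- stats::binom.test(errs, trials)$conf.int
  list(eps1 = errs / trials, ci = as.numeric(ci), trials = trials)
}

# consensus over a 4 x len count matrix (shared with consensus_sites logic)
consensus_from_counts <- function(counts, p, log_factor) {
  pairs <- utils::combn(4, 2)
  q <- function(c_, b_) ifelse(c_ == b_, 1 - p, p / 3)
  ll_for <- function(b1, b2) {
    pr <- (q(1:4, b1) + q(1:4, b2)) / 2
    colSums(counts * log(pr))
  }
  ll_hom <- sapply(1:4, function(b) ll_for(b, b))
  ll_het <- sapply(seq_len(ncol(pairs)),
                   function(k) ll_for(pairs[1, k], pairs[2, k]))
  best_hom <- apply(ll_hom, 1, max)
  bi <- apply(ll_het, 1, which.max)
  best_het <- ll_het[cbind(seq_along(bi), bi)]
  cols <- which(best_het - best_hom > log_factor & colSums(counts) > 0)
  list(col = as.integer(cols),
       b1 = DNA_ALPHABET[pairs[1, bi[cols]]],
       b2 = DNA_ALPHABET[pairs[2, bi[cols]]])
}

#' Monte Carlo calibration of the read-extension error probability
#'
#' Error frequency of count-to-extend given exactly k spanning reads per
#' link, with the true sites known. Each trial has n_sites + 1 consecutive
#' anchor links; each spanning read reports both anchor states through
#' substitution noise (a site base is misread to the opposite allele with
#' probability p/3 and to a non-allele base, which casts no vote, with
#' probability 2p/3). A trial errs when any link's strict majority is wrong,
#' tied, or voteless.
#'
#' @param p substitution rate.
#' @param k spanning reads per link.
#' @param n_sites number of polymorphic sites (default 2).
#' @param trials Monte Carlo trials.
#' @param seed integer seed.
#' @return list with `eps2`, binomial 95% interval, `trials`.
#' @export
estimate_eps2 <- function(p, k, n_sites = 2L, trials = 1e5, seed = 1L) {
  set.seed(seed)
  n_links <- n_sites + 1L
  # per read and link: both anchor observations; flank anchors are certain,
  # interior anchors are site bases. Link l connects anchor l and l+1:
  # anchors 1 and n_sites+2 are flanks (no misread), the rest are sites.
  err_trials <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < trials) {
    m <- min(chunk, trials - done)
    # state observation codes per anchor: 1 correct allele, 2 opposite, 0 none
    obs_anchor <- function(is_site, nn) {
      if (!is_site) return(rep(1L, nn))
      u <- runif(nn)
      ifelse(u < p / 3, 2L, ifelse(u < p, 0L, 1L))
    }
    bad <- rep(FALSE, m)
    for (l in seq_len(n_links)) {
      a_site <- l > 1L
      b_site <- l < n_links + 1L && l + 1L <= n_sites + 1L
      same <- integer(m); cross <- integer(m)
      for (r in seq_len(k)) {
        a <- obs_anchor(a_site, m)
        b <- obs_anchor(b_site, m)
        valid <- a != 0L & b != 0L
        same <- same + (valid & a == b)
        cross <- cross + (valid & a != b)
      }
      bad <- bad | !(same > cross)
    }
    err_trials <- err_trials + sum(bad)
    done <- done + m
  }
  ci <- stats::binom.test(err_trials, trials)$conf.int
  list(eps2 = err_trials / trials, ci = as.numeric(ci), trials = trials)
}

#' Probability of insufficient bridging coverage across phasing links
#'
#' Poisson union bound for P(some consecutive-anchor link is spanned by
#' fewer than k reads). A read spans a link when it covers the two anchors
#' plus l_iid margin at flank anchors; the caller passes each link's
#' required span. Includes an optional Monte Carlo cross-check mode.
#'
#' @param N number of reads.
#' @param L read length.
#' @param G genome length.
#' @param spans required covered span per link (vector; gap + margins).
#' @param k required spanning reads.
#' @param mc number of Monte Carlo rounds for the cross-check (0 = analytic
#'   only).
#' @param seed seed for the cross-check.
#' @return list with `delta_cov` (analytic), and `mc` estimate when requested.
#' @export
delta_cov <- function(N, L, G, spans, k, mc = 0L, seed = 1L) {
  if (k == 0) return(list(delta_cov = 0, mc = NULL))
  if (any(spans > L)) {
    warning("delta_cov: a link span exceeds the read length")
    return(list(delta_cov = 1, mc = NULL))
  }
  lam <- N * (L - spans) / G
  analytic <- min(1, sum(ppois(k - 1, lam)))
  out <- list(delta_cov = analytic, mc = NULL)
  if (mc > 0) {
    set.seed(seed)
    fails <- 0L
    for (tr in seq_len(mc)) {
      cnt <- rpois(length(spans), lam)
      # rpois is the thinned-Poisson equivalent of uniform read starts
      if (any(cnt < k)) fails <- fails + 1L
    }
    out$mc <- fails / mc
  }
  out
}

#' Information-requirement curve of an assembler
#'
#' Minimum read count (and normalized coverage) as a function of read length
#' for the greedy, multibridging and X-phased multibridging assemblers,
#' given the genome's repeat statistics.
#'
#' @param algorithm `"greedy"`, `"multibridge"` or `"xphase"`.
#' @param stats `xmb_repeat_stats` (or a list with the needed lengths).
#' @param G genome length.
#' @param p substitution rate (calibrates l_iid).
#' @param epsilon failure budget.
#' @param L_grid read lengths to evaluate.
#' @param k bridging reads for the X-phased condition (default 3).
#' @return data.frame with `L`, `N_min`, `coverage`; attribute `asymptote_L`.
#' @export
feasibility_curve <- function(algorithm = c("greedy", "multibridge", "xphase"),
                              stats, G, p, epsilon, L_grid, k = 3L) {
  algorithm <- match.arg(algorithm)
  op <- solve_liid_alpha(p, epsilon, G)
  l <- op$l_iid
  fmax <- stats$flanked_max
  fcrit <- max(stats$flanked_int, stats$flanked_tri)
  eint <- stats$exact_int
  nmin <- vapply(L_grid, function(L) {
    switch(algorithm,
      greedy = prop1_requirement(G, fmax, l, epsilon, L),
      multibridge = prop2_requirement(G, fcrit, l, epsilon, L),
      xphase = xphase_requirement(G, eint, l, k, epsilon, L))
  }, numeric(1))
  asym <- switch(algorithm,
    greedy = fmax + 2 * l,
    multibridge = fcrit + 2 * l,
    xphase = eint + 2 * l)
  out <- data.frame(L = L_grid, N_min = nmin,
                    coverage = nmin * L_grid / G)
  attr(out, "asymptote_L") <- asym
  attr(out, "l_iid") <- l
  out
}
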