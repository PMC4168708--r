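#' Longest exact repeat of a genome
#'
#' The longest substring occurring at two distinct positions, maximal in the
#' sense that it cannot be extended equally on either side (a copy touching a
#' sequence boundary counts as maximal on that side). Computed from the
#' suffix array with the Kasai LCP array; circular genomes are evaluated on
#' the doubled string with occurrence positions de-duplicated modulo G and
#' lengths capped at G.
#'
#' @param genome `xmb_genome` or DNA string.
#' @param circular overrides the genome's flag for plain strings.
#' @return list with `len` and 0-based witness positions `t1`, `t2`
#'   (`len = 0` when no base repeats).
#' @export
longest_exact_repeat <- function(genome, circular = NULL) {
  s <- genome_string(genome)
  circular <- resolve_circular(genome, circular)
  if (nchar(s) == 0) stop("longest_exact_repeat: empty genome")
  if (circular) {
    r <- cpp_longest_exact(paste0(s, s), nchar(s))
  } else {
    r <- cpp_longest_exact(s, 0L)
  }
  list(len = r$len, t1 = r$t1, t2 = r$t2)
}

resolve_circular <- function(genome, circular) {
  if (!is.null(circular)) return(isTRUE(circular))
  if (inherits(genome, "xmb_genome")) return(genome$circular)
  FALSE
}

#' Longest exact triple repeat
#'
#' Longest substring occurring at three distinct positions such that neither
#' all left-extensions nor all right-extensions agree.
#'
#' @inheritParams longest_exact_repeat
#' @return list with `len` and sorted witness vector `t` (0-based).
#' @export
longest_triple_repeat <- function(genome, circular = NULL) {
  s <- genome_string(genome)
  circular <- resolve_circular(genome, circular)
  if (circular) {
    r <- cpp_longest_triple(paste0(s, s), nchar(s))
  } else {
    r <- cpp_longest_triple(s, 0L)
  }
  list(len = r$len, t = r$t)
}

# maximal repeated position pairs (len >= floor), de-duplicated; circular
# genomes use the doubled string with positions mapped mod G
repeat_pairs <- function(genome, floor_len = 12L, circular = NULL) {
  s <- genome_string(genome)
  circular <- resolve_circular(genome, circular)
  if (circular) {
    G <- nchar(s)
    df <- cpp_repeat_pairs(paste0(s, s), floor_len)
    if (nrow(df)) {
      a <- pmin(df$t1 %% G, df$t2 %% G)
      b <- pmax(df$t1 %% G, df$t2 %% G)
      keep <- a != b
      df <- data.frame(t1 = a[keep], t2 = b[keep],
                       len = pmin(df$len[keep], G))
      df <- df[!duplicated(df[c("t1", "t2")]), , drop = FALSE]
    }
    df
  } else {
    cpp_repeat_pairs(s, floor_len)
  }
}

#' Longest pair of interleaved exact repeats
#'
#' Two exact repeats, one at positions (t1, t3) and one at (t2, t4), are
#' interleaved when their copies alternate along the genome (t1 < t2 < t3 <
#' t4; on circular genomes, when the chords connecting the two copies cross).
#' The length of the pair is the length of the shorter repeat. Enumeration is
#' restricted to maximal exact repeats of length at least `floor_len` for
#' tractability; the brute-force oracle in the test-suite validates small
#' cases.
#'
#' @inheritParams longest_exact_repeat
#' @param floor_len minimum repeat length considered (default 12).
#' @return list with `len` and `witness` (t1, t2, t3, t4; 0-based) or
#'   `len = 0`.
#' @export
longest_interleaved_pair <- function(genome, floor_len = 12L,
                                     circular = NULL) {
  circular <- resolve_circular(genome, circular)
  pr <- repeat_pairs(genome, floor_len, circular)
  best <- list(len = 0L, witness = NULL)
  if (nrow(pr) < 2) return(best)
  pr <- pr[order(-pr$len), , drop = FALSE]
  m <- nrow(pr)
  for (a in seq_len(m - 1)) {
    if (pr$len[a] <= best$len) break
    for (b in seq2(a + 1L, m)) {
      sc <- min(pr$len[a], pr$len[b])
      if (sc <= best$len) break
      pos <- c(pr$t1[a], pr$t2[a], pr$t1[b], pr$t2[b])
      if (length(unique(pos)) < 4) next
      # alternation = exactly one copy of b inside the (t1a, t2a) interval
      inside <- (pr$t1[b] > pr$t1[a] & pr$t1[b] < pr$t2[a]) +
        (pr$t2[b] > pr$t1[a] & pr$t2[b] < pr$t2[a])
      if (inside == 1) {
        best <- list(len = sc,
                     witness = sort(pos))
      }
    }
  }
  best
}

#' Flanked repeat statistics by seed-and-extend
#'
#' A flanked repeat is a repeated region terminated on each end by
#' statistically uncorrelated sequence, where the mismatch density between
#' copies jumps to about 0.75. Starting from maximal exact repeat seeds, both
#' copies are extended outward while the mismatch density in a trailing
#' window stays below `density_threshold`; seeds on the same copy diagonal
#' whose extensions touch are chained. The detector is heuristic with a
#' resolution of about one window width.
#'
#' @inheritParams longest_exact_repeat
#' @param mismatch_window window width in bases (default 20).
#' @param density_threshold stop threshold in (0, 0.75) (default 0.35,
#'   between polymorphism-level density and the 0.75 random ratio).
#' @param floor_len seed floor (default 12).
#' @return data.frame of flanked repeats: `t1`, `t2` (0-based flanked starts
#'   of both copies), `len` (flanked length).
#' @export
flanked_repeats <- function(genome, mismatch_window = 20L,
                            density_threshold = 0.35, floor_len = 12L,
                            circular = NULL) {
  if (density_threshold <= 0 || density_threshold >= 0.75) {
    stop("flanked_repeats: density_threshold must be in (0, 0.75)")
  }
  s <- genome_string(genome)
  circular <- resolve_circular(genome, circular)
  G <- nchar(s)
  if (circular) s <- paste0(s, s)  # extensions may cross the origin
  pr <- repeat_pairs(genome, floor_len, circular)
  if (!nrow(pr)) {
    return(data.frame(t1 = integer(0), t2 = integer(0), len = integer(0)))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  w <- mismatch_window
  thr <- density_threshold * w
  ext <- function(a, b, dir) {
    # extend positions a,b (1-based, first comparison) in direction dir
    mism <- integer(0)
    k <- 0L
    good <- 0L
    repeat {
      pa <- a + dir * k; pb <- b + dir * k
      if (pa < 1 || pb < 1 || pa > length(ch) || pb > length(ch)) break
      mism <- c(mism, as.integer(ch[pa] != ch[pb]))
      k <- k + 1L
      win <- tail(mism, w)
      if (length(win) >= w && sum(win) >= thr) break
      if (sum(win) < thr) good <- k
    }
    # back off trailing mismatches
    while (good > 0 && mism[good] == 1L) good <- good - 1L
    good
  }
  out <- lapply(seq_len(nrow(pr)), function(r) {
    t1 <- pr$t1[r]; t2 <- pr$t2[r]; len <- pr$len[r]
    er <- ext(t1 + len + 1L, t2 + len + 1L, +1L)
    el <- ext(t1, t2, -1L)
    data.frame(t1 = t1 - el, t2 = t2 - el, len = len + el + er)
  })
  fr <- do.call(rbind, out)
  # chain seeds on the same diagonal with touching extents
  fr$diag <- fr$t2 - fr$t1
  fr <- fr[order(fr$diag, fr$t1), , drop = FALSE]
  merged <- list()
  cur <- NULL
  for (r in seq_len(nrow(fr))) {
    row <- fr[r, ]
    if (!is.null(cur) && row$diag == cur$diag && row$t1 <= cur$t1 + cur$len) {
      cur$len <- max(cur$len, row$t1 + row$len - cur$t1)
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
      cur <- row
    }
  }
  if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
  fr <- do.call(rbind, merged)
  fr$diag <- NULL
  rownames(fr) <- NULL
  fr
}

#' Full repeat statistics of a genome
#'
#' Computes the exact statistics (longest repeat, longest interleaved pair,
#' longest triple, and their critical maximum) by suffix-array enumeration,
#' and the flanked statistics by the seed-and-extend detector.
#'
#' @inheritParams flanked_repeats
#' @return object of class `xmb_repeat_stats` with fields `exact_max`,
#'   `exact_int`, `exact_tri`, `exact_crit`, `flanked_max`, `flanked_int`,
#'   `flanked_tri`, `flanked_crit` and `witnesses`.
#' @export
repeat_stats <- function(genome, mismatch_window = 20L,
                         density_threshold = 0.35, floor_len = 12L,
                         circular = NULL) {
  circular <- resolve_circular(genome, circular)
  le <- longest_exact_repeat(genome, circular)
  lt <- longest_triple_repeat(genome, circular)
  li <- longest_interleaved_pair(genome, floor_len, circular)
  fr <- flanked_repeats(genome, mismatch_window, density_threshold,
                        floor_len, circular)
  fmax <- if (nrow(fr)) max(fr$len) else 0L
  # flanked interleaved: chord-crossing pairs of flanked repeats
  fint <- 0L
  if (nrow(fr) >= 2) {
    fr2 <- fr[order(-fr$len), , drop = FALSE]
    for (a in seq_len(nrow(fr2) - 1)) {
      if (fr2$len[a] <= fint) break
      for (b in seq2(a + 1L, nrow(fr2))) {
        sc <- min(fr2$len[a], fr2$len[b])
        if (sc <= fint) break
        inside <- (fr2$t1[b] > fr2$t1[a] & fr2$t1[b] < fr2$t2[a]) +
          (fr2$t2[b] > fr2$t1[a] & fr2$t2[b] < fr2$t2[a])
        if (inside == 1) fint <- sc
      }
    }
  }
  # flanked triple: pairwise-minimal extension of the longest exact triple
  ftri <- 0L
  if (lt$len > 0 && length(lt$t) == 3) {
    exts <- utils::combn(lt$t, 2, function(pp) {
      sub <- flanked_extend_pair(genome_string(genome), pp[1], pp[2], lt$len,
                                 mismatch_window, density_threshold, circular)
      sub
    })
    ftri <- min(exts)
  }
  structure(list(
    exact_max = le$len, exact_int = li$len, exact_tri = lt$len,
    exact_crit = max(li$len, lt$len),
    flanked_max = max(fmax, le$len), flanked_int = max(fint, li$len),
    flanked_tri = max(ftri, lt$len),
    flanked_crit = max(fint, li$len, ftri, lt$len),
    witnesses = list(exact_max = le, exact_tri = lt, exact_int = li,
                     flanked = fr)
  ), class = "xmb_repeat_stats")
}

# flanked extension length for one explicit copy pair
flanked_extend_pair <- function(s, t1, t2, len, w, dens, circular) {
  if (circular) s <- paste0(s, s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  thr <- dens * w
  ext1 <- function(a, b, dir) {
    mism <- integer(0); k <- 0L; good <- 0L
    repeat {
      pa <- a + dir * k; pb <- b + dir * k
      if (pa < 1 || pb < 1 || pa > length(ch) || pb > length(ch)) break
      mism <- c(mism, as.integer(ch[pa] != ch[pb]))
      k <- k + 1L
      win <- tail(mism, w)
      if (length(win) >= w && sum(win) >= thr) break
      if (sum(win) < thr) good <- k
    }
    while (good > 0 && mism[good] == 1L) good <- good - 1L
    good
  }
  len + ext1(t1 + len + 1L, t2 + len + 1L, +1L) + ext1(t1, t2, -1L)
}

#' Critical repeat lengths
#'
#' The critical exact length is max(exact interleaved, exact triple); the
#' critical flanked length is the analogous maximum of the flanked
#' statistics. They are the read-length thresholds for reconstructibility
#' with noiseless and noisy reads respectively.
#'
#' @param stats `xmb_repeat_stats`.
#' @return list with `exact_crit` and `flanked_crit`.
#' @export
critical_lengths <- function(stats) {
  list(exact_crit = max(stats$exact_int, stats$exact_tri),
       flanked_crit = max(stats$flanked_int, stats$flanked_tri))
}

#' @export
print.xmb_repeat_stats <- function(x, ...) {
  cat(sprintf(
    "repeat stats: exact max/int/tri/crit = %d/%d/%d/%d, flanked = %d/%d/%d/%d\n",
    x$exact_max, x$exact_int, x$exact_tri, x$exact_crit,
    x$flanked_max, x$flanked_int, x$flanked_tri, x$flanked_crit))
  invisible(x)
}
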