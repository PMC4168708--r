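#' Specification of a parametric repeat-bearing genome
#'
#' The genome model is a uniform random background on which three long
#' flanked repeats are planted: the longest flanked repeat, a partner that
#' interleaves it (forming the longest pair of flanked interleaved repeats,
#' in -X-Y-X-Y- order), and a flanked triple repeat. Polymorphic edits inside
#' each repeat interior are placed so that the longest *exact* repeat lengths
#' hit prescribed targets.
#'
#' Lengths of zero disable the corresponding planted structure.
#'
#' @param G genome length in bases.
#' @param flanked_max,flanked_int,flanked_tri flanked repeat lengths
#'   (interleaved partner and triple may be 0 = absent).
#' @param exact_max,exact_int,exact_tri target longest exact repeat lengths
#'   inside each planted repeat (defaults: equal to the flanked lengths,
#'   i.e. no polymorphism).
#' @param n_max,n_int,n_tri polymorphism edit counts per repeat.
#' @param circular logical; circular genomes wrap reads around the origin.
#' @param seed integer seed for reproducible generation.
#' @param gap_min minimum random-background gap kept around planted copies so
#'   their flanking regions are genuinely uncorrelated (default 100, about
#'   twice a typical anchor length).
#' @return an object of class `xmb_genome_spec`.
#' @export
genome_spec <- function(G, flanked_max = 0L, flanked_int = 0L,
                        flanked_tri = 0L, exact_max = flanked_max,
                        exact_int = flanked_int, exact_tri = flanked_tri,
                        n_max = 0L, n_int = 0L, n_tri = 0L, circular = FALSE,
                        seed = 1L, gap_min = 100L) {
  if (G < 0) stop("genome_spec: G must be nonnegative")
  present <- c(flanked_max, flanked_int, flanked_tri) > 0
  if (present[1] && any(present[-1]) &&
      flanked_max <= max(flanked_int, flanked_tri)) {
    stop("genome_spec: flanked_max must exceed max(flanked_int, flanked_tri)")
  }
  if (any(present[-1]) && !present[1]) {
    stop("genome_spec: interleaved/triple repeats require a longest repeat")
  }
  chk <- function(fl, ex, n, what) {
    if (fl == 0) return(invisible())
    if (ex > fl) stop("genome_spec: exact ", what, " length exceeds flanked")
    if (ex < 1) stop("genome_spec: exact ", what, " length must be >= 1")
    if (n < n_sites_min(fl, ex)) {
      stop("genome_spec: ", what, ": need at least ", n_sites_min(fl, ex),
           " edits to realize exact length ", ex, " inside flanked length ", fl)
    }
  }
  chk(flanked_max, exact_max, n_max, "max")
  chk(flanked_int, exact_int, n_int, "int")
  chk(flanked_tri, exact_tri, n_tri, "tri")
  footprint <- 2 * flanked_max + 2 * flanked_int + 3 * flanked_tri +
    gap_min * (2 * sum(present[1:2]) + 3 * present[3] + 1)
  if (footprint >= G) {
    stop("genome_spec: planted repeats (footprint ", footprint,
         ") do not fit in G = ", G)
  }
  structure(list(
    G = as.integer(G), flanked_max = as.integer(flanked_max),
    flanked_int = as.integer(flanked_int), flanked_tri = as.integer(flanked_tri),
    exact_max = as.integer(exact_max), exact_int = as.integer(exact_int),
    exact_tri = as.integer(exact_tri), n_max = as.integer(n_max),
    n_int = as.integer(n_int), n_tri = as.integer(n_tri),
    circular = isTRUE(circular), seed = as.integer(seed),
    gap_min = as.integer(gap_min)
  ), class = "xmb_genome_spec")
}

# minimum number of interior edits needed so the longest exact run inside a
# flanked repeat of length fl is exactly ex (sites at ex, 2 ex + 1, ... leave
# interior runs of ex and a final run <= ex)
n_sites_min <- function(fl, ex) {
  if (ex >= fl) return(0L)
  as.integer(ceiling((fl - ex) / (ex + 1)))
}

#' Generate uniform random genome background
#'
#' @param G length in bases (>= 0).
#' @param seed integer seed.
#' @return a single DNA string with i.i.d. uniform bases.
#' @export
generate_background <- function(G, seed = NULL) {
  if (G < 0) stop("generate_background: G must be nonnegative")
  if (G == 0) return("")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_ALPHABET, G, replace = TRUE), collapse = "")
}

#' Place polymorphic sites inside a repeat copy
#'
#' Given one repeat interior, produce `n_copies` edited copies whose longest
#' exact common run is exactly `target_exact_len`. The minimum number of
#' sites is placed deterministically (at target, 2*target+1, ...); surplus
#' sites are placed uniformly at random in the largest remaining run while a
#' run of exactly the target length is preserved. At each site the copies
#' receive distinct bases (for three copies, at least two distinct).
#'
#' @param copy repeat interior as a single DNA string (flanked length).
#' @param n_edits number of polymorphic sites (>= required minimum).
#' @param target_exact_len desired longest exact run.
#' @param n_copies number of copies to emit (2 or 3).
#' @return list with `copies` (character vector), `sites` (0-based positions)
#'   and `site_bases` (matrix, copies x sites).
#' @export
place_polymorphism <- function(copy, n_edits, target_exact_len, n_copies = 2L) {
  fl <- nchar(copy)
  t <- target_exact_len
  if (t > fl) stop("place_polymorphism: target exceeds flanked length")
  if (t < 1) stop("place_polymorphism: target must be >= 1")
  nmin <- n_sites_min(fl, t)
  if (n_edits < nmin) {
    stop("place_polymorphism: need at least ", nmin, " edits for target ",
         t, " in length ", fl)
  }
  if (n_edits == 0 && t < fl) stop("place_polymorphism: infeasible")
  sites <- integer(0)
  if (nmin > 0) sites <- t + (seq_len(nmin) - 1L) * (t + 1L)  # 0-based
  surplus <- n_edits - nmin
  if (surplus > 0) {
    for (k in seq_len(surplus)) {
      # current runs between boundaries {-1, sites, fl}
      bnd <- c(-1L, sort(sites), fl)
      lens <- diff(bnd) - 1L
      protect <- which(lens == t)[1]  # keep one exact-target run intact
      cand <- setdiff(which(lens >= 1), protect)
      if (!length(cand)) {
        stop("place_polymorphism: cannot place ", n_edits,
             " sites while keeping an exact run of ", t)
      }
      g <- cand[which.max(lens[cand])]
      pos <- bnd[g] + sample.int(lens[g], 1)  # 0-based position inside run
      sites <- sort(c(sites, pos))
    }
  }
  sites <- sort(sites)
  ch <- strsplit(copy, "", fixed = TRUE)[[1]]
  copies <- matrix(rep(ch, n_copies), nrow = n_copies, byrow = TRUE)
  site_bases <- matrix("", nrow = n_copies, ncol = length(sites))
  for (j in seq_along(sites)) {
    p <- sites[j] + 1L
    site_bases[1, j] <- ch[p]
    for (cc in seq2(2L, n_copies)) {
      b <- sample(setdiff(DNA_ALPHABET, ch[p]), 1)
      copies[cc, p] <- b
      site_bases[cc, j] <- b
    }
  }
  list(
    copies = apply(copies, 1, paste, collapse = ""),
    sites = as.integer(sites),
    site_bases = site_bases
  )
}

#' Plant flanked repeats with polymorphism on a random background
#'
#' Places the longest flanked repeat and its interleaving partner in
#' -X-Y-X-Y- order, and (if requested) a disjoint flanked triple repeat, by
#' rejection sampling of non-overlapping positions separated by at least
#' `gap_min` of random background. The single background base adjacent to
#' each planted copy is forced to differ between copies so the planted
#' exact-run lengths are realized exactly.
#'
#' @param background DNA string of length `spec$G`.
#' @param spec an `xmb_genome_spec`.
#' @param max_tries placement retry cap (default 1000).
#' @return an object of class `xmb_genome` with fields `bases`, `circular`,
#'   `truth` (list of repeat occurrence records).
#' @export
plant_repeats <- function(background, spec, max_tries = 1000L) {
  G <- spec$G
  stopifnot(nchar(background) == G)
  gmin <- spec$gap_min
  segs <- list()
  if (spec$flanked_max > 0) {
    lens <- if (spec$flanked_int > 0) {
      c(spec$flanked_max, spec$flanked_int, spec$flanked_max, spec$flanked_int)
    } else {
      c(spec$flanked_max, spec$flanked_max)
    }
    ntri <- if (spec$flanked_tri > 0) 3L else 0L
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      # keep one base of margin at each end for the forced flank difference
      xy <- sort(sample.int(G - max(lens) - 2L, length(lens)) + 1L)
      tri <- if (ntri) sample.int(G - spec$flanked_tri - 2L, ntri) + 1L else integer(0)
      starts <- c(xy, tri)
      slens <- c(lens, rep(spec$flanked_tri, ntri))
      o <- order(starts)
      s <- starts[o]; l <- slens[o]
      if (all(diff(s) >= l[-length(l)] + gmin) &&
          s[1] >= gmin && s[length(s)] + l[length(l)] + gmin <= G) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("plant_repeats: could not place repeats after ", max_tries,
           " tries (seed ", spec$seed, "); increase G or reduce lengths")
    }
  } else {
    xy <- integer(0); tri <- integer(0)
  }

  ch <- strsplit(background, "", fixed = TRUE)[[1]]
  truth <- list()
  put <- function(start0, s) {  # write string s at 0-based start
    ch[seq2(start0 + 1L, start0 + nchar(s))] <<-
      strsplit(s, "", fixed = TRUE)[[1]]
  }
  force_flank_diff <- function(starts0, len) {
    # base immediately before/after every copy must differ across copies
    for (side in c("pre", "post")) {
      # 0-based copy start s: previous base has 1-based index s, the base
      # after the copy has 1-based index s + len + 1
      idx <- if (side == "pre") starts0 else starts0 + len + 1L
      bases <- ch[idx]
      if (length(unique(bases)) < length(bases)) {
        # reassign: keep first, draw the rest distinct from the previous ones
        for (k in seq2(2L, length(idx))) {
          avoid <- bases[seq_len(k - 1L)]
          pick <- setdiff(DNA_ALPHABET, avoid)
          if (!length(pick)) pick <- setdiff(DNA_ALPHABET, bases[k - 1L])
          bases[k] <- sample(pick, 1)
          ch[idx[k]] <<- bases[k]
        }
      }
    }
  }

  if (spec$flanked_max > 0) {
    if (spec$flanked_int > 0) {
      x_starts <- xy[c(1, 3)] ; y_starts <- xy[c(2, 4)]
    } else {
      x_starts <- xy ; y_starts <- integer(0)
    }
    interior <- paste(sample(DNA_ALPHABET, spec$flanked_max, TRUE), collapse = "")
    pm <- place_polymorphism(interior, spec$n_max, spec$exact_max, 2L)
    put(x_starts[1], pm$copies[1]); put(x_starts[2], pm$copies[2])
    force_flank_diff(x_starts, spec$flanked_max)
    truth[[length(truth) + 1]] <- list(
      kind = "max", copy_starts = x_starts, flanked_length = spec$flanked_max,
      polymorphism_sites = pm$sites, site_bases = pm$site_bases)
    if (spec$flanked_int > 0) {
      interior <- paste(sample(DNA_ALPHABET, spec$flanked_int, TRUE), collapse = "")
      pm <- place_polymorphism(interior, spec$n_int, spec$exact_int, 2L)
      put(y_starts[1], pm$copies[1]); put(y_starts[2], pm$copies[2])
      force_flank_diff(y_starts, spec$flanked_int)
      truth[[length(truth) + 1]] <- list(
        kind = "interleaved_partner", copy_starts = y_starts,
        flanked_length = spec$flanked_int,
        polymorphism_sites = pm$sites, site_bases = pm$site_bases)
    }
    if (spec$flanked_tri > 0) {
      interior <- paste(sample(DNA_ALPHABET, spec$flanked_tri, TRUE), collapse = "")
      pm <- place_polymorphism(interior, spec$n_tri, spec$exact_tri, 3L)
      tri <- sort(tri)
      for (k in 1:3) put(tri[k], pm$copies[k])
      force_flank_diff(tri, spec$flanked_tri)
      truth[[length(truth) + 1]] <- list(
        kind = "triple", copy_starts = tri, flanked_length = spec$flanked_tri,
        polymorphism_sites = pm$sites, site_bases = pm$site_bases)
    }
  }
  structure(list(
    bases = paste(ch, collapse = ""), circular = spec$circular, truth = truth,
    spec = spec
  ), class = "xmb_genome")
}

#' Simulate a genome from a model specification
#'
#' Convenience wrapper: seeded background generation followed by repeat
#' planting.
#'
#' @param spec an `xmb_genome_spec`.
#' @return an `xmb_genome`.
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  bg <- generate_background(spec$G)
  plant_repeats(bg, spec)
}

#' @export
print.xmb_genome <- function(x, ...) {
  cat("xmb genome: ", nchar(x$bases), " bases, ",
      if (x$circular) "circular" else "linear", ", ",
      length(x$truth), " planted repeat structure(s)\n", sep = "")
  invisible(x)
}
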