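#' Greedy assembly by descending RA-overlap
#'
#' The noisy-read generalisation of the classical greedy assembler: contigs
#' are initialised to the reads, and for W from L down to l_iid any contig
#' pair with RA-overlap W is merged (suffix fused with prefix, overlap bases
#' taken from the predecessor; no consensus). Candidate overlaps come from
#' shared-fingerprint pairs verified under the RA-rule; merging is a
#' deterministic sweep in (W descending, lowest id) order in which each
#' contig gains at most one successor and one predecessor and no cycle is
#' closed. For circular genomes a final self-overlap of the single remaining
#' contig is reported via the `circularised` attribute.
#'
#' @param reads `xmb_reads` or character vector (all of length >= l_iid).
#' @param params `xmb_overlap_params`.
#' @param index_stride fingerprint index stride.
#' @param circular attempt end-closure for circular genomes.
#' @return object of class `xmb_assembly` with `contigs`.
#' @export
greedy_assemble <- function(reads, params, index_stride = 1L,
                            circular = FALSE) {
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (!length(bases)) stop("greedy_assemble: empty read set")
  if (min(nchar(bases)) < params$l_iid) {
    stop("greedy_assemble: reads shorter than l_iid")
  }
  n <- length(bases)
  # collapse exact duplicate reads (offset-0 full overlaps merge trivially)
  cand <- fingerprint_candidates(bases, params$f, max_offsets = 5L,
                                 index_stride = index_stride)
  ver <- cpp_verify_sub(bases, cand$i, cand$j, cand$offset,
                        params$l_iid, params$alpha)
  # both directions: a verified (i, j, offset>0) means j succeeds i;
  # offset 0 (duplicate-locus reads) merges j into i by convention i -> j
  keep <- ver$offset > 0L | (ver$offset == 0L & ver$i < ver$j)
  ver <- ver[keep, , drop = FALSE]
  o <- order(-ver$W, ver$i, ver$j)
  chain <- cpp_greedy_chain(n, ver$i[o], ver$j[o])
  # the accepted link (i, j) used the largest verified W for that pair
  wmap <- new.env()
  for (k in o) {
    key <- paste(ver$i[k], ver$j[k])
    if (is.null(get0(key, envir = wmap))) assign(key, ver$W[k], envir = wmap)
  }
  starts <- which(chain$pred == 0L)
  contigs <- vapply(starts, function(s) {
    out <- bases[s]
    v <- chain$succ[s]
    prev <- s
    while (v != 0L) {
      W <- get(paste(prev, v), envir = wmap)
      out <- paste0(out, substr(bases[v], W + 1L, nchar(bases[v])))
      prev <- v
      v <- chain$succ[v]
    }
    out
  }, character(1))
  circularised <- FALSE
  if (circular && length(contigs) == 1) {
    W <- cpp_ra_overlap(contigs, contigs, params$l_iid, params$alpha)
    if (W >= params$l_iid && W < nchar(contigs)) {
      contigs <- substr(contigs, 1L, nchar(contigs) - W)
      circularised <- TRUE
    }
  }
  structure(list(contigs = unname(contigs), circularised = circularised,
                 params = params),
            class = "xmb_assembly")
}
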