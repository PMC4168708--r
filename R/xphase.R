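#' Find X-nodes of a condensed assembly graph
#'
#' An X-node is a condensed node with in-degree >= 2 and out-degree >= 2; it
#' corresponds to a flanked repeat whose copies clustered together (the
#' polymorphism inside the repeat interior is too sparse for the RA-rule to
#' separate noisy K-mers). Only 2-in/2-out nodes are phased downstream.
#'
#' @param graph condensed `xmb_graph`.
#' @return data.frame with `node`, `ind`, `outd`.
#' @export
find_xnodes <- function(graph) {
  deg <- node_degrees(graph)
  x <- which(deg$ind >= 2L & deg$outd >= 2L)
  data.frame(node = x, ind = deg$ind[x], outd = deg$outd[x])
}

# map cluster id -> condensed node containing it
cluster_node_map <- function(graph) {
  lab <- graph$labels
  node_of <- integer(length(graph$reps))
  for (v in seq_along(lab)) node_of[lab[[v]]] <- v
  node_of
}

#' Align reads to an X-node
#'
#' Every read owning a K-mer slot in one of the X-node's clusters is placed
#' at its majority-vote offset in the node's spelled coordinates. Reads whose
#' slots also touch an incoming (outgoing) neighbour node carry that flank
#' identity, which later anchors the phasing.
#'
#' @param graph condensed `xmb_graph`.
#' @param xnode node id.
#' @param reads `xmb_reads` or character vector.
#' @return object of class `xmb_xalign`: per-read offsets (0-based column of
#'   read start in node coordinates), flank identities, and node metadata.
#' @export
align_reads_to_xnode <- function(graph, xnode, reads, prep = NULL) {
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (is.null(prep)) prep <- xphase_prep(graph)
  lab <- graph$labels[[xnode]]
  coords <- node_cluster_coords(graph, xnode)  # 0-based start per label pos
  slots <- prep$slots_by_node[[as.character(xnode)]]
  if (is.null(slots) || !length(slots)) {
    return(structure(list(reads_idx = integer(0)), class = "xmb_xalign"))
  }
  pos_in_node <- integer(length(graph$reps))
  pos_in_node[lab] <- coords + 1L  # 1-based
  off <- (pos_in_node[graph$assign[slots]] - 1L) - graph$slot_pos[slots]
  sr <- graph$slot_read[slots]
  # majority offset per read
  tab <- split(off, sr)
  reads_idx <- as.integer(names(tab))
  offset <- vapply(tab, function(o) {
    tt <- table(o)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  # flank identity: which neighbour node do this read's other slots touch
  e <- graph$edges
  in_nodes <- e$from[e$to == xnode]
  out_nodes <- e$to[e$from == xnode]
  flank_of <- function(nbrs) {
    vapply(as.character(reads_idx), function(r) {
      nd <- prep$nodes_by_read[[r]]
      hit <- nbrs[nbrs %in% nd]
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
  }
  structure(list(
    reads_idx = reads_idx, offset = unname(offset),
    in_flank = flank_of(in_nodes), out_flank = flank_of(out_nodes),
    in_nodes = sort(in_nodes), out_nodes = sort(out_nodes),
    node = xnode, node_len = max(coords) + graph$K,
    bases = bases[reads_idx]
  ), class = "xmb_xalign")
}

# shared slot/node indexes reused across the X-nodes of one assembly
xphase_prep <- function(graph) {
  node_of <- cluster_node_map(graph)
  valid <- graph$assign > 0L
  slot_node <- integer(length(graph$assign))
  slot_node[valid] <- node_of[graph$assign[valid]]
  idx <- which(valid)
  list(
    slots_by_node = split(idx, slot_node[idx]),
    nodes_by_read = lapply(split(slot_node[idx], graph$slot_read[idx]),
                           unique)
  )
}

# per-column base counts (4 x node_len) from an X-node alignment
xnode_base_counts <- function(al) {
  len <- al$node_len
  if (!length(al$reads_idx)) {
    return(matrix(0L, 4, len, dimnames = list(DNA_ALPHABET, NULL)))
  }
  ch <- strsplit(al$bases, "", fixed = TRUE)
  lens <- lengths(ch)
  cols <- unlist(lapply(seq_along(ch),
                        function(k) al$offset[k] + seq_len(lens[k])))
  code <- match(unlist(ch, use.names = FALSE), DNA_ALPHABET)
  keep <- cols >= 1 & cols <= len & !is.na(code)
  idx <- (cols[keep] - 1L) * 4L + code[keep]
  matrix(tabulate(idx, 4L * len), nrow = 4,
         dimnames = list(DNA_ALPHABET, NULL))
}

#' Consensus step: locate polymorphic sites within an X-node
#'
#' For each column i of the repeat, the aligned read bases are modelled as an
#' equiprobable mixture of the two copies' bases (x1(i), x2(i)) observed
#' through substitution noise of rate p. The unordered pair F maximising the
#' likelihood is computed by enumerating all 10 pairs; a column is called a
#' polymorphic site when the best heterogeneous pair beats the best
#' homogeneous pair by `log_factor` (a prior-odds guard against false sites).
#'
#' @param al `xmb_xalign` from [align_reads_to_xnode()].
#' @param p substitution noise rate (effective rate for indel data).
#' @param log_factor polymorphism call threshold in nats (default 2).
#' @param min_depth minimum column depth to call a site.
#' @return data.frame with `col` (1-based node column), `b1`, `b2`, `margin`.
#' @export
consensus_sites <- function(al, p, log_factor = 2, min_depth = 4L) {
  counts <- xnode_base_counts(al)
  pairs <- utils::combn(4, 2)  # heterogeneous pairs
  q <- function(c_, b_) ifelse(c_ == b_, 1 - p, p / 3)
  # log P(obs | F) per column: t(logP) %*% counts
  ll_for <- function(b1, b2) {
    pr <- (q(1:4, b1) + q(1:4, b2)) / 2
    colSums(counts * log(pr))
  }
  ll_hom <- sapply(1:4, function(b) ll_for(b, b))
  ll_het <- sapply(seq_len(ncol(pairs)),
                   function(k) ll_for(pairs[1, k], pairs[2, k]))
  best_hom <- apply(ll_hom, 1, max)
  best_het_idx <- apply(ll_het, 1, which.max)
  best_het <- ll_het[cbind(seq_len(nrow(ll_het)), best_het_idx)]
  depth <- colSums(counts)
  is_site <- (best_het - best_hom > log_factor) & depth >= min_depth
  cols <- which(is_site)
  if (!length(cols)) {
    return(data.frame(col = integer(0), b1 = character(0),
                      b2 = character(0), margin = numeric(0)))
  }
  kk <- best_het_idx[cols]
  data.frame(
    col = cols,
    b1 = DNA_ALPHABET[pairs[1, kk]],
    b2 = DNA_ALPHABET[pairs[2, kk]],
    margin = best_het[cols] - best_hom[cols]
  )
}

#' Count-to-extend phasing (majority vote over spanning reads)
#'
#' Anchors along the repeat are the incoming flank, the polymorphic sites in
#' order, and the outgoing flank. For each consecutive anchor pair, the reads
#' spanning both vote for a linking of the two base assignments; the strict
#' majority linking is composed across all links into a flank pairing. Any
#' tie or zero-vote link leaves the X-node unresolved (never guessed).
#'
#' @param al `xmb_xalign`.
#' @param sites data.frame from [consensus_sites()].
#' @return list with `resolved`, `pairing` (for copy 1: in-flank node and
#'   out-flank node), `links` (per-link vote summary).
#' @export
count_to_extend <- function(al, sites) {
  if (length(al$in_nodes) != 2L || length(al$out_nodes) != 2L) {
    return(list(resolved = FALSE, pairing = NULL, links = NULL))
  }
  W1 <- al$in_nodes[1]; W2 <- al$in_nodes[2]
  Y1 <- al$out_nodes[1]; Y2 <- al$out_nodes[2]
  n_sites <- nrow(sites)
  # anchor state per read: in-flank (1 = W1, 2 = W2), one column per site
  # (1 = allele b1, 2 = b2, NA = absent or neither), out-flank (1 = Y1)
  states <- matrix(NA_integer_, length(al$reads_idx), n_sites + 2L)
  states[, 1] <- ifelse(is.na(al$in_flank), NA_integer_,
                        ifelse(al$in_flank == W1, 1L, 2L))
  states[, n_sites + 2L] <- ifelse(is.na(al$out_flank), NA_integer_,
                                   ifelse(al$out_flank == Y1, 1L, 2L))
  lens <- nchar(al$bases)
  for (j in seq2(1L, n_sites)) {
    p <- sites$col[j] - al$offset
    b <- ifelse(p >= 1 & p <= lens, substring(al$bases, p, p), NA_character_)
    states[, j + 1L] <- ifelse(is.na(b), NA_integer_,
                               ifelse(b == sites$b1[j], 1L,
                                      ifelse(b == sites$b2[j], 2L,
                                             NA_integer_)))
  }
  n_links <- n_sites + 1L
  link_sign <- integer(n_links)  # +1 same-state linking, -1 crossed, 0 tie
  votes <- matrix(0L, n_links, 2, dimnames = list(NULL, c("same", "cross")))
  for (l in seq_len(n_links)) {
    a <- states[, l]; b <- states[, l + 1L]
    ok <- !is.na(a) & !is.na(b)
    same <- sum(a[ok] == b[ok])
    cross <- sum(a[ok] != b[ok])
    votes[l, ] <- c(same, cross)
    link_sign[l] <- if (same > cross) 1L else if (cross > same) -1L else 0L
  }
  if (any(link_sign == 0L)) {
    return(list(resolved = FALSE, pairing = NULL, assignment = NULL,
                links = data.frame(votes, sign = link_sign)))
  }
  cum <- cumprod(link_sign)
  total <- cum[n_links]  # +1: W1 pairs with Y1
  pairing <- if (total > 0) list(in1 = W1, out1 = Y1, in2 = W2, out2 = Y2)
             else list(in1 = W1, out1 = Y2, in2 = W2, out2 = Y1)
  # allele of the W1-anchored copy at site j follows the cumulative linking
  assignment <- if (n_sites > 0) ifelse(cum[seq_len(n_sites)] > 0, 1L, 2L)
                else integer(0)
  list(resolved = TRUE, pairing = pairing, assignment = assignment,
       links = data.frame(votes, sign = link_sign))
}

#' Exact MAP phasing over the configuration set
#'
#' Enumerates all 2^(n_sites + 1) configurations (which allele belongs to the
#' copy anchored at the first in-flank, and which out-flank it exits to) and
#' scores each by the likelihood of every aligned read under an equiprobable
#' two-copy mixture with independent per-base substitution noise. Falls back
#' to [count_to_extend()] when the enumeration cap is exceeded.
#'
#' @param al `xmb_xalign`.
#' @param sites data.frame from [consensus_sites()].
#' @param p substitution rate.
#' @param cap enumeration cap (default 2^20).
#' @return list with `resolved`, `pairing`, `margin` (log-posterior gap),
#'   and `assignment` (allele of copy 1 per site).
#' @export
map_phase <- function(al, sites, p, cap = 2^20) {
  n_sites <- nrow(sites)
  if (length(al$in_nodes) != 2L || length(al$out_nodes) != 2L) {
    return(list(resolved = FALSE, pairing = NULL, margin = 0))
  }
  if (2^(n_sites + 1) > cap) {
    warning("map_phase: configuration set too large; falling back to countAlg")
    return(count_to_extend(al, sites))
  }
  W1 <- al$in_nodes[1]; W2 <- al$in_nodes[2]
  Y1 <- al$out_nodes[1]; Y2 <- al$out_nodes[2]
  # read observations at anchors, coded as in count_to_extend
  obs <- matrix(NA_integer_, length(al$reads_idx), n_sites)
  lens <- nchar(al$bases)
  for (j in seq2(1L, n_sites)) {
    q <- sites$col[j] - al$offset
    b <- ifelse(q >= 1 & q <= lens, substring(al$bases, q, q), NA_character_)
    obs[, j] <- ifelse(is.na(b), NA_integer_,
                       ifelse(b == sites$b1[j], 1L,
                              ifelse(b == sites$b2[j], 2L, 0L)))
  }
  inf <- ifelse(is.na(al$in_flank), NA, ifelse(al$in_flank == W1, 1L, 2L))
  outf <- ifelse(is.na(al$out_flank), NA, ifelse(al$out_flank == Y1, 1L, 2L))
  lp_match <- log(1 - p); lp_mis <- log(p / 3)
  n_cfg <- 2^(n_sites + 1)
  scores <- numeric(n_cfg)
  for (cfg in seq_len(n_cfg) - 1L) {
    sigma <- as.integer(intToBits(cfg))[seq_len(n_sites + 1L)]
    copy1_allele <- sigma[seq2(1L, n_sites)] + 1L  # 1 or 2 per site
    out_for_copy1 <- sigma[n_sites + 1L] + 1L       # 1 = Y1, 2 = Y2
    ll <- 0
    for (k in seq_along(al$reads_idx)) {
      lk <- c(0, 0)  # log-lik under copy 1, copy 2
      for (j in seq2(1L, n_sites)) {
        o <- obs[k, j]
        if (is.na(o)) next
        a1 <- copy1_allele[j]; a2 <- 3L - a1
        lk[1] <- lk[1] + if (o == a1) lp_match else lp_mis
        lk[2] <- lk[2] + if (o == a2) lp_match else lp_mis
      }
      # flank consistency is treated as certain
      w <- c(TRUE, TRUE)
      if (!is.na(inf[k])) w <- c(inf[k] == 1L, inf[k] == 2L)
      if (!is.na(outf[k])) {
        o1 <- out_for_copy1; o2 <- 3L - o1
        w <- w & c(outf[k] == o1, outf[k] == o2)
      }
      if (!any(w)) { ll <- -Inf; break }
      mx <- max(lk[w])
      ll <- ll + mx + log(sum(exp(lk[w] - mx)) / 2)
    }
    scores[cfg + 1L] <- ll
  }
  best <- which.max(scores)
  margin <- scores[best] - max(scores[-best])
  if (!is.finite(margin) && is.finite(scores[best])) margin <- Inf
  sigma <- as.integer(intToBits(best - 1L))[seq_len(n_sites + 1L)]
  out_for_copy1 <- sigma[n_sites + 1L] + 1L
  pairing <- if (out_for_copy1 == 1L) list(in1 = W1, out1 = Y1, in2 = W2, out2 = Y2)
             else list(in1 = W1, out1 = Y2, in2 = W2, out2 = Y1)
  list(resolved = margin > 0, pairing = pairing, margin = margin,
       assignment = sigma[seq2(1L, n_sites)] + 1L)
}

#' Resolve an X-node by duplicating it along the phased pairing
#'
#' The X-node is split into two parallel nodes, each wired to its paired
#' in-flank and out-flank and carrying copy-specific bases at the polymorphic
#' sites; degrees drop to 1 and condensation merges straight through.
#'
#' @param graph condensed `xmb_graph`.
#' @param xnode node id.
#' @param pairing list from the phasing step.
#' @param sites data.frame from [consensus_sites()].
#' @param assignment optional per-site allele (1/2) of copy 1 (MAP result);
#'   by default copy 1 takes `b1` everywhere, which is the countAlg
#'   convention when link composition starts at b1.
#' @return the rewired `xmb_graph`.
#' @export
resolve_xnode <- function(graph, xnode, pairing, sites, assignment = NULL) {
  if (is.null(pairing)) return(graph)
  n <- n_nodes(graph)
  # new node = copy of xnode appended at the end
  dup <- n + 1L
  graph$labels[[dup]] <- graph$labels[[xnode]]
  graph$label_ov[[dup]] <- graph$label_ov[[xnode]]
  graph$node_support[dup] <- graph$node_support[xnode]
  graph$dropped[dup] <- FALSE
  if (nrow(sites)) {
    a1 <- if (is.null(assignment)) rep(1L, nrow(sites)) else assignment
    b1 <- ifelse(a1 == 1L, sites$b1, sites$b2)
    b2 <- ifelse(a1 == 1L, sites$b2, sites$b1)
    graph$site_overrides[[xnode]] <- list(cols = sites$col, bases = b1)
    graph$site_overrides[[dup]] <- list(cols = sites$col, bases = b2)
  } else {
    graph$site_overrides[dup] <- list(NULL)
  }
  e <- graph$edges
  move_in <- which(e$to == xnode & e$from == pairing$in2)
  move_out <- which(e$from == xnode & e$to == pairing$out2)
  e$to[move_in] <- dup
  e$from[move_out] <- dup
  graph$edges <- e
  graph
}

#' X-phased multibridging assembly
#'
#' Runs multibridging steps 1-7, then phases every 2-in/2-out X-node:
#' aligns the relevant reads, locates polymorphic sites by consensus, and
#' pairs the flanks by count-to-extend majority vote (default) or exact MAP
#' enumeration. Resolved X-nodes are duplicated into copy-specific paths;
#' step 8 (Euler spelling) then runs on the resolved graph. Unresolved
#' X-nodes are left intact: the assembly degrades gracefully to more contigs
#' rather than guessing.
#'
#' @inheritParams multibridge_assemble
#' @param phase_mode `"count"` or `"map"`.
#' @param p_consensus substitution rate used by the consensus model.
#' @param log_factor polymorphism call threshold (nats).
#' @return `xmb_assembly` with an extra `phasing` report (one row per X-node).
#' @export
xphase_assemble <- function(reads, params, K = NULL, flanked_crit = NULL,
                            noise = c("sub", "indel"), p_indel = 0.03,
                            phase_mode = c("count", "map"),
                            p_consensus = NULL, log_factor = 2,
                            circular = FALSE, index_stride = 1L,
                            min_xnode_labels = 16L) {
  noise <- match.arg(noise)
  phase_mode <- match.arg(phase_mode)
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (!length(bases)) stop("xphase_assemble: empty read set")
  L <- min(nchar(bases))
  if (is.null(K)) {
    K <- if (!is.null(flanked_crit)) min(flanked_crit + 2L * params$l_iid, L)
         else min(2L * params$l_iid + 100L, L)
  }
  if (is.null(p_consensus)) {
    p_consensus <- if (noise == "sub" && !is.na(params$p)) max(params$p, 1e-3)
                   else max(p_indel, 1e-3)
  }
  band <- 3L * as.integer(ceiling(p_indel * L)) + 8L
  cl <- cluster_kmers(reads, K, params, noise = noise,
                      index_stride = index_stride, band = band)
  g <- build_debruijn(cl)
  if (noise == "indel") {
    g <- repair_edge_directions(g)
    g <- pop_indel_artifacts(g)
  }
  g <- join_components(g, params)
  g <- condense(g)
  g <- clear_branches(g, params$l_iid)
  g <- condense(g)
  xn <- find_xnodes(g)
  prep <- if (nrow(xn)) xphase_prep(g) else NULL
  report <- list()
  resolutions <- list()
  for (r in seq_len(nrow(xn))) {
    v <- xn$node[r]
    if (xn$ind[r] != 2L || xn$outd[r] != 2L) {
      report[[r]] <- data.frame(node = v, n_sites = NA, resolved = FALSE,
                                reason = "degree > 2")
      next
    }
    if (length(g$labels[[v]]) < min_xnode_labels) {
      # a flanked repeat longer than K spans many cluster labels; nodes
      # barely longer than one K-window are local graph artifacts
      report[[r]] <- data.frame(node = v, n_sites = NA, resolved = FALSE,
                                reason = "below size floor")
      next
    }
    al <- align_reads_to_xnode(g, v, bases, prep = prep)
    if (!length(al$reads_idx)) {
      report[[r]] <- data.frame(node = v, n_sites = NA, resolved = FALSE,
                                reason = "no aligned reads")
      next
    }
    sites <- consensus_sites(al, p_consensus, log_factor = log_factor)
    ph <- if (phase_mode == "map") map_phase(al, sites, p_consensus)
          else count_to_extend(al, sites)
    report[[r]] <- data.frame(node = v, n_sites = nrow(sites),
                              resolved = isTRUE(ph$resolved),
                              reason = if (isTRUE(ph$resolved)) "" else "tie or no votes")
    if (isTRUE(ph$resolved)) {
      resolutions[[length(resolutions) + 1]] <-
        list(node = v, pairing = ph$pairing, sites = sites,
             assignment = ph$assignment)
    }
  }
  for (res in resolutions) {
    g <- resolve_xnode(g, res$node, res$pairing, res$sites, res$assignment)
  }
  g <- condense(g)
  contigs <- euler_spell(g, circular = circular,
                         fallback = if (noise == "indel") "walk" else "unitigs")
  structure(list(contigs = as.character(contigs),
                 ambiguous = isTRUE(attr(contigs, "ambiguous")),
                 graph = g, K = as.integer(K), params = params,
                 phasing = if (length(report)) do.call(rbind, report)
                           else data.frame()),
            class = "xmb_assembly")
}
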