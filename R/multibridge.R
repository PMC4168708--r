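#' Cluster K-mers of a read set under the RA-rule
#'
#' K-mers are grouped with a union-find structure: every verified
#' RA-overlapping read pair unions the K-mer slots at aligned offsets
#' (substitution mode), or the slots matched by a banded overlap alignment
#' (indel mode). This is the read-overlap approximation of all-pairs K-mer
#' clustering; `method = "oracle"` performs the direct all-pairs transitive
#' closure and is meant for small validation instances only.
#'
#' @param reads `xmb_reads` or character vector.
#' @param K K-mer length (2*l_iid <= K <= read length).
#' @param params `xmb_overlap_params`.
#' @param noise `"sub"` or `"indel"`.
#' @param method `"overlap"` (default) or `"oracle"`.
#' @param index_stride fingerprint index stride passed to candidate search.
#' @param band alignment band width for indel mode; default
#'   3 * ceiling((p_i + p_d) * L) + 8 is supplied by the assembler wrappers.
#' @return object of class `xmb_clusters`: slot-to-cluster assignment,
#'   cluster representatives and sizes, and the consecutive-slot edge list.
#' @export
cluster_kmers <- function(reads, K, params, noise = c("sub", "indel"),
                          method = c("overlap", "oracle"),
                          index_stride = 1L, band = 16L,
                          min_support = if (noise == "indel") 2L else 1L) {
  noise <- match.arg(noise)
  method <- match.arg(method)
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (K > max(nchar(bases))) stop("cluster_kmers: K exceeds read length")
  if (method == "oracle") {
    return(cluster_kmers_oracle(bases, K, params))
  }
  cand <- fingerprint_candidates(bases, params$f, max_offsets = 5L,
                                 index_stride = index_stride)
  if (noise == "sub") {
    ver <- cpp_verify_sub(bases, cand$i, cand$j, cand$offset,
                          params$l_iid, params$alpha)
    cl <- cpp_cluster_sub(bases, ver$i, ver$j, ver$offset, as.integer(K))
  } else {
    o <- order(-cand$votes)
    cl <- cpp_cluster_indel(bases, cand$i[o], cand$j[o], cand$offset[o],
                            as.integer(K), as.integer(band), params$alpha,
                            params$l_iid, min_run = 5L,
                            min_support = as.integer(min_support))
  }
  cl$K <- as.integer(K)
  cl$n_reads <- length(bases)
  cl$read_bases <- bases
  class(cl) <- "xmb_clusters"
  cl
}

# direct all-pairs K-mer RA-matching with transitive closure (oracle mode)
cluster_kmers_oracle <- function(bases, K, params) {
  lens <- nchar(bases)
  nslot <- pmax(0L, lens - K + 1L)
  slot_read <- rep.int(seq_along(bases), nslot)
  slot_pos <- unlist(lapply(nslot, function(m) seq2(0L, m - 1L)))
  kmers <- substring(bases[slot_read], slot_pos + 1L, slot_pos + K)
  n <- length(kmers)
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (a in seq2(1L, n - 1L)) {
    for (b in seq2(a + 1L, n)) {
      if (cpp_ra_match(kmers[a], kmers[b], params$l_iid, params$alpha)) {
        ra <- findp(a); rb <- findp(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  assign <- match(roots, unique(roots))
  edges <- NULL
  for (r in seq_along(bases)) {
    sl <- which(slot_read == r)
    if (length(sl) >= 2) {
      u <- assign[sl[-length(sl)]]; v <- assign[sl[-1]]
      keep <- u != v
      if (any(keep)) edges <- rbind(edges, data.frame(u = u[keep], v = v[keep]))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(u = integer(0), v = integer(0), n = integer(0))
  } else {
    edges <- stats::aggregate(list(n = rep(1L, nrow(edges))),
                              by = edges[c("u", "v")], FUN = sum)
  }
  structure(list(
    assign = assign, slot_read = slot_read, slot_pos = slot_pos,
    reps = kmers[!duplicated(assign)][order(unique(assign))],
    sizes = as.integer(table(factor(assign, levels = seq_len(max(assign))))),
    edges = edges, self_edges = 0L, K = as.integer(K),
    n_reads = length(bases), read_bases = bases
  ), class = "xmb_clusters")
}

#' Build the K-mer-cluster De Bruijn graph
#'
#' Nodes are K-mer clusters; a directed edge (u, v) exists iff some read
#' contains member K-mers of u and v at consecutive offsets. Every node
#' starts as its own single-cluster label; edges carry the implied overlap
#' K - 1 and their read support.
#'
#' @param clusters `xmb_clusters`.
#' @return object of class `xmb_graph`.
#' @export
build_debruijn <- function(clusters) {
  C <- length(clusters$reps)
  edges <- clusters$edges
  ne <- length(edges$u)
  edges <- data.frame(from = edges$u, to = edges$v,
                      ov = rep(clusters$K - 1L, ne),
                      n = edges$n, joined = rep(FALSE, ne))
  structure(list(
    K = clusters$K,
    reps = clusters$reps, sizes = clusters$sizes,
    cons_last = if (!is.null(clusters$cons_last)) clusters$cons_last
                else substr(clusters$reps, clusters$K, clusters$K),
    read_bases = clusters$read_bases,
    labels = as.list(seq_len(C)),
    label_ov = rep(list(integer(0)), C),
    node_support = clusters$sizes,
    dropped = logical(C),
    edges = edges,
    site_overrides = rep(list(NULL), C),
    assign = clusters$assign, slot_read = clusters$slot_read,
    slot_pos = clusters$slot_pos
  ), class = "xmb_graph")
}

n_nodes <- function(graph) length(graph$labels)

node_degrees <- function(graph) {
  n <- n_nodes(graph)
  list(outd = tabulate(graph$edges$from, n),
       ind = tabulate(graph$edges$to, n))
}

#' Join disconnected components of the De Bruijn graph
#'
#' Coverage gaps leave nodes without a predecessor or successor. For W from
#' K-1 down to l_iid, tail nodes are linked to the head node whose cluster
#' representative has the best RA-overlap W (ties: larger cluster, then
#' lower id); no node gains a second predecessor or successor in this step.
#' The link is recorded as an edge annotated with its overlap W.
#'
#' @param graph `xmb_graph` (uncondensed).
#' @param params `xmb_overlap_params`.
#' @return the graph with join edges added.
#' @export
join_components <- function(graph, params) {
  deg <- node_degrees(graph)
  alive <- if (is.null(graph$dropped)) rep(TRUE, n_nodes(graph))
           else !graph$dropped
  need_succ <- which(deg$outd == 0L & alive)
  need_pred <- which(deg$ind == 0L & alive)
  if (!length(need_succ) && !length(need_pred)) return(graph)
  reps_search <- graph$reps
  if (any(!alive)) reps_search[!alive] <- strrep("N", graph$K)
  links <- cpp_join_search(reps_search, graph$sizes,
                           as.integer(need_succ), as.integer(need_pred),
                           params$l_iid, params$alpha, params$f,
                           params$l_iid)
  if (nrow(links)) {
    graph$edges <- rbind(graph$edges, data.frame(
      from = links$u, to = links$v, ov = links$W, n = 0L, joined = TRUE))
  }
  graph
}

#' Condense unambiguous chains of the assembly graph
#'
#' Repeatedly merges u -> v whenever out-degree(u) = 1 and in-degree(v) = 1,
#' concatenating node labels (all such merges are performed in one pass over
#' the static chain decomposition). The spelled sequence is preserved: label
#' overlaps move into the merged node.
#'
#' @param graph `xmb_graph`.
#' @return condensed `xmb_graph`.
#' @export
condense <- function(graph) {
  n <- n_nodes(graph)
  if (n == 0) return(graph)
  e <- graph$edges
  deg <- node_degrees(graph)
  alive <- if (is.null(graph$dropped)) rep(TRUE, n) else !graph$dropped
  mergeable <- deg$outd[e$from] == 1L & deg$ind[e$to] == 1L & e$from != e$to
  nxt <- integer(n); nxt_ov <- integer(n)
  nxt[e$from[mergeable]] <- e$to[mergeable]
  nxt_ov[e$from[mergeable]] <- e$ov[mergeable]
  has_prev <- logical(n)
  has_prev[e$to[mergeable]] <- TRUE
  starts <- which(!has_prev & alive)
  chain_id <- integer(n)
  cid <- 0L
  order_in_chain <- integer(n)
  for (s in starts) {
    cid <- cid + 1L
    v <- s; k <- 0L
    while (v != 0L && chain_id[v] == 0L) {
      k <- k + 1L
      chain_id[v] <- cid
      order_in_chain[v] <- k
      v <- nxt[v]
    }
  }
  # pure cycles of mergeable edges: break each at its lowest node
  leftover <- which(chain_id == 0L & alive)
  while (length(leftover)) {
    s <- leftover[1]
    cid <- cid + 1L
    v <- s; k <- 0L
    while (chain_id[v] == 0L) {
      k <- k + 1L
      chain_id[v] <- cid
      order_in_chain[v] <- k
      v <- nxt[v]
    }
    leftover <- which(chain_id == 0L & alive)
  }
  n_new <- cid
  # build merged labels
  new_labels <- vector("list", n_new)
  new_ov <- vector("list", n_new)
  new_support <- numeric(n_new)
  new_overrides <- vector("list", n_new)
  ord <- order(chain_id, order_in_chain)
  ord <- ord[chain_id[ord] > 0L]
  members <- split(ord, chain_id[ord])
  K <- graph$K
  for (c in seq_len(n_new)) {
    mem <- members[[c]]
    lab <- unlist(graph$labels[mem], use.names = FALSE)
    ovs <- integer(0)
    merged_or <- NULL
    pos0 <- 0L  # 0-based column offset of the current member's spelling
    for (k in seq_along(mem)) {
      m <- mem[k]
      ovs <- c(ovs, graph$label_ov[[m]])
      or_m <- graph$site_overrides[[m]]
      if (!is.null(or_m) && length(or_m$cols)) {
        merged_or <- list(
          cols = c(merged_or$cols, or_m$cols + pos0),
          bases = c(merged_or$bases, or_m$bases))
      }
      spell_len <- K + sum(K - graph$label_ov[[m]])
      if (k < length(mem)) {
        ovs <- c(ovs, nxt_ov[m])
        pos0 <- pos0 + spell_len - nxt_ov[m]
      }
    }
    new_labels[[c]] <- lab
    new_ov[[c]] <- ovs
    new_support[c] <- sum(graph$node_support[mem])
    if (!is.null(merged_or)) new_overrides[[c]] <- merged_or
  }
  keep <- !mergeable
  e2 <- e[keep, , drop = FALSE]
  e2$from <- chain_id[e2$from]
  e2$to <- chain_id[e2$to]
  graph$labels <- new_labels
  graph$label_ov <- new_ov
  graph$node_support <- new_support
  graph$site_overrides <- new_overrides
  graph$dropped <- logical(n_new)
  graph$edges <- e2
  graph
}

#' Clear short parallel branches (noise bubbles)
#'
#' A bubble is a pair (or fan) of parallel single-node paths of equal label
#' length shorter than l_iid that leave one node and rejoin at another; such
#' structures arise from residual clustering errors near flanked-repeat
#' boundaries. The path with the highest total member support survives
#' (ties: lowest node id); the graph is then re-condensed.
#'
#' @param graph condensed `xmb_graph`.
#' @param l_iid anchor length bounding the bubble label length.
#' @return `xmb_graph` without bubbles.
#' @export
clear_branches <- function(graph, l_iid) {
  repeat {
    e <- graph$edges
    deg <- node_degrees(graph)
    lab_len <- lengths(graph$labels)
    # candidate bubble interiors: single nodes with in = out = 1
    interior <- which(deg$ind == 1L & deg$outd == 1L & lab_len < l_iid)
    if (!length(interior)) return(graph)
    pre <- e$to %in% interior
    suc <- e$from %in% interior
    u_of <- integer(n_nodes(graph)); v_of <- integer(n_nodes(graph))
    u_of[e$to[pre]] <- e$from[pre]
    v_of[e$from[suc]] <- e$to[suc]
    key <- paste(u_of[interior], v_of[interior], lab_len[interior])
    ok <- u_of[interior] != 0L & v_of[interior] != 0L &
      u_of[interior] != interior & v_of[interior] != interior
    groups <- split(interior[ok], key[ok])
    groups <- Filter(function(g) length(g) >= 2, groups)
    if (!length(groups)) return(graph)
    drop_nodes <- integer(0)
    for (g in groups) {
      best <- g[order(-graph$node_support[g], g)][1]
      drop_nodes <- c(drop_nodes, setdiff(g, best))
    }
    graph <- drop_graph_nodes(graph, drop_nodes)
    graph <- condense(graph)
  }
}

drop_graph_nodes <- function(graph, drop) {
  if (!length(drop)) return(graph)
  n <- n_nodes(graph)
  keep <- setdiff(seq_len(n), drop)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  e <- graph$edges
  e <- e[!(e$from %in% drop) & !(e$to %in% drop), , drop = FALSE]
  e$from <- remap[e$from]; e$to <- remap[e$to]
  graph$labels <- graph$labels[keep]
  graph$label_ov <- graph$label_ov[keep]
  graph$node_support <- graph$node_support[keep]
  graph$site_overrides <- graph$site_overrides[keep]
  if (!is.null(graph$dropped)) graph$dropped <- graph$dropped[keep]
  graph$edges <- e
  graph
}

# spell a single condensed node: full consensus K-mer for the first cluster,
# then one consensus base per subsequent cluster (representative bases fill
# the middle of pieces longer than one, i.e. across join-edge gaps)
spell_node <- function(graph, v) {
  lab <- graph$labels[[v]]
  ovs <- graph$label_ov[[v]]
  K <- graph$K
  first <- cluster_consensus_kmer(graph, lab[1])
  if (length(lab) == 1L) {
    s <- first
  } else {
    reps <- graph$reps[lab[-1]]
    mids <- substring(reps, ovs + 1L, K - 1L)
    pieces <- paste0(mids, graph$cons_last[lab[-1]])
    s <- paste0(first, paste(pieces, collapse = ""))
  }
  ov_r <- graph$site_overrides[[v]]
  if (!is.null(ov_r) && length(ov_r$cols)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    inb <- ov_r$cols >= 1 & ov_r$cols <= length(ch)
    ch[ov_r$cols[inb]] <- ov_r$bases[inb]
    s <- paste(ch, collapse = "")
  }
  s
}

# column-majority consensus K-mer over a cluster's member slots
cluster_consensus_kmer <- function(graph, cl) {
  if (is.null(graph$read_bases)) return(graph$reps[cl])
  slots <- which(graph$assign == cl)
  if (length(slots) <= 1) return(graph$reps[cl])
  K <- graph$K
  km <- substring(graph$read_bases[graph$slot_read[slots]],
                  graph$slot_pos[slots] + 1L,
                  graph$slot_pos[slots] + K)
  km <- km[nchar(km) == K]
  if (length(km) <= 1) return(graph$reps[cl])
  m <- matrix(match(unlist(strsplit(km, "", fixed = TRUE)), DNA_ALPHABET),
              nrow = K)
  cons <- apply(m, 1, function(col) {
    tt <- tabulate(col, 4)
    which.max(tt)
  })
  paste(DNA_ALPHABET[cons], collapse = "")
}

# 0-based start coordinate of each label cluster within the node spelling
node_cluster_coords <- function(graph, v) {
  ovs <- graph$label_ov[[v]]
  K <- graph$K
  cumsum(c(0L, K - ovs))
}

weak_components <- function(n, edges) {
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(edges))) {
    a <- findp(edges$from[k]); b <- findp(edges$to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  match(roots, unique(roots))
}

# number of Euler circuits of a connected balanced multigraph (BEST theorem);
# returns Inf for overflow-scale counts
count_euler_circuits <- function(nodes, edges) {
  n <- length(nodes)
  idx <- seq_len(n)
  remap <- setNames(idx, nodes)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    a <- remap[as.character(edges$from[k])]
    b <- remap[as.character(edges$to[k])]
    A[a, b] <- A[a, b] + 1
  }
  outd <- rowSums(A)
  L <- diag(outd) - A
  t_w <- if (n == 1) 1 else round(det(L[-1, -1, drop = FALSE]))
  t_w * prod(factorial(pmax(outd - 1, 0)))
}

#' Spell the genome from the condensed assembly graph
#'
#' Each weakly connected component is checked for an Euler path (or cycle);
#' when the Euler traversal is unique (counted exactly with the BEST
#' theorem), the node labels along it are concatenated and mapped back
#' through the cluster representatives with the recorded overlaps. Components
#' that are non-Eulerian or admit several Euler traversals are spelled as
#' one contig per condensed node (unitigs) with a warning: guessing among
#' multiple Euler paths would silently misassemble interleaved repeats.
#'
#' @param graph condensed `xmb_graph`.
#' @param circular treat a balanced component as an Euler cycle.
#' @param fallback what to emit for a component that is non-Eulerian or has
#'   several Euler traversals: `"unitigs"` (one contig per condensed node;
#'   conservative, never misassembles) or `"walk"` (greedy support-ordered
#'   edge walks; longer draft contigs whose local order may be imperfect,
#'   appropriate when the downstream criterion tolerates a few percent
#'   mismatch, as with indel-noise data).
#' @return character vector of contigs (attribute `ambiguous` marks the
#'   components that could not be uniquely spelled).
#' @export
euler_spell <- function(graph, circular = FALSE,
                        fallback = c("unitigs", "walk")) {
  fallback <- match.arg(fallback)
  n <- n_nodes(graph)
  if (n == 0) return(character(0))
  comp <- weak_components(n, graph$edges)
  contigs <- character(0)
  ambiguous <- FALSE
  spell_fallback <- function(nodes, e) {
    if (fallback == "unitigs" || nrow(e) == 0) {
      vapply(nodes, function(v) spell_node(graph, v), character(1))
    } else {
      walk_spell(graph, nodes, e)
    }
  }
  for (c in unique(comp)) {
    nodes <- which(comp == c)
    e <- graph$edges[graph$edges$from %in% nodes, , drop = FALSE]
    if (nrow(e) == 0) {
      contigs <- c(contigs, vapply(nodes, function(v) spell_node(graph, v),
                                   character(1)))
      next
    }
    outd <- tabulate(e$from, n)[nodes]
    ind <- tabulate(e$to, n)[nodes]
    diffd <- outd - ind
    start_cand <- nodes[diffd == 1L]
    end_cand <- nodes[diffd == -1L]
    balanced <- all(diffd == 0L)
    is_path <- length(start_cand) == 1 && length(end_cand) == 1 &&
      sum(abs(diffd)) == 2
    if (!balanced && !is_path) {
      warning("euler_spell: non-Eulerian component; using ", fallback,
              " fallback")
      contigs <- c(contigs, spell_fallback(nodes, e))
      ambiguous <- TRUE
      next
    }
    e2 <- e
    start <- NULL
    if (is_path) {
      start <- start_cand
      e2 <- rbind(e2, data.frame(from = end_cand, to = start_cand, ov = 0L,
                                 n = 0L, joined = FALSE))
    } else {
      start <- min(nodes)
    }
    n_circ <- count_euler_circuits(nodes, e2)
    if (!isTRUE(all.equal(n_circ, 1))) {
      warning("euler_spell: ", format(n_circ), " Euler traversals; using ",
              fallback, " fallback")
      contigs <- c(contigs, spell_fallback(nodes, e))
      ambiguous <- TRUE
      next
    }
    path <- hierholzer_path(nodes, e, start)
    if (is.null(path)) {
      warning("euler_spell: disconnected Eulerian component; using ",
              fallback, " fallback")
      contigs <- c(contigs, spell_fallback(nodes, e))
      ambiguous <- TRUE
      next
    }
    if (balanced) {
      # Euler cycle: the node sequence starts and ends at `start`; spell one
      # trimmed piece per edge so each base appears exactly once (the result
      # is a rotation of the circular genome)
      pieces <- vapply(seq2(2L, length(path$nodes)), function(k) {
        piece <- spell_node(graph, path$nodes[k])
        substr(piece, path$ovs[k - 1] + 1L, nchar(piece))
      }, character(1))
      s <- paste(pieces, collapse = "")
    } else {
      s <- spell_node(graph, path$nodes[1])
      for (k in seq2(2L, length(path$nodes))) {
        piece <- spell_node(graph, path$nodes[k])
        s <- paste0(s, substr(piece, path$ovs[k - 1] + 1L, nchar(piece)))
      }
    }
    contigs <- c(contigs, s)
  }
  attr(contigs, "ambiguous") <- ambiguous
  contigs
}

# Hierholzer with lowest-target-first edge choice; returns node sequence and
# the overlap of each traversed edge, or NULL if edges remain untraversed
hierholzer_path <- function(nodes, e, start) {
  if (nrow(e) == 0) return(list(nodes = start, ovs = integer(0)))
  e <- e[order(e$from, e$to), , drop = FALSE]
  adj <- split(seq_len(nrow(e)), e$from)
  ptr <- new.env()
  for (v in names(adj)) assign(v, 1L, envir = ptr)
  used <- logical(nrow(e))
  # iterative Hierholzer
  stack_v <- c(start)
  stack_e <- c(NA_integer_)  # edge used to reach each stacked node
  out_nodes <- integer(0)
  out_edges <- integer(0)
  while (length(stack_v)) {
    v <- stack_v[length(stack_v)]
    key <- as.character(v)
    lst <- adj[[key]]
    p <- if (!is.null(lst)) get0(key, envir = ptr, ifnotfound = 1L) else 1L
    while (!is.null(lst) && p <= length(lst) && used[lst[p]]) p <- p + 1L
    if (!is.null(lst)) assign(key, p, envir = ptr)
    if (!is.null(lst) && p <= length(lst)) {
      ed <- lst[p]
      used[ed] <- TRUE
      assign(key, p + 1L, envir = ptr)
      stack_v <- c(stack_v, e$to[ed])
      stack_e <- c(stack_e, ed)
    } else {
      out_nodes <- c(out_nodes, v)
      out_edges <- c(out_edges, stack_e[length(stack_e)])
      stack_v <- stack_v[-length(stack_v)]
      stack_e <- stack_e[-length(stack_e)]
    }
  }
  if (!all(used)) return(NULL)
  out_nodes <- rev(out_nodes)
  out_edges <- rev(out_edges)  # edge arriving INTO each node (first is NA)
  list(nodes = out_nodes, ovs = e$ov[out_edges[-1]])
}

# Greedy support-ordered edge walks over one component: repeatedly start at
# the node with the largest out-minus-in excess among sources of unused
# edges and follow the highest-support unused edge. Every edge is traversed
# exactly once across all walks.
walk_spell <- function(graph, nodes, e) {
  e <- e[order(e$from, -e$n, e$to), , drop = FALSE]
  used <- logical(nrow(e))
  n <- n_nodes(graph)
  outd <- tabulate(e$from, n)
  ind <- tabulate(e$to, n)
  adj <- split(seq_len(nrow(e)), e$from)
  contigs <- character(0)
  remaining <- nrow(e)
  while (remaining > 0) {
    srcs <- unique(e$from[!used])
    start <- srcs[which.max((outd - ind)[srcs])]
    s <- spell_node(graph, start)
    v <- start
    repeat {
      lst <- adj[[as.character(v)]]
      k <- if (is.null(lst)) NA_integer_ else lst[!used[lst]][1]
      if (is.na(k)) break
      used[k] <- TRUE
      remaining <- remaining - 1L
      piece <- spell_node(graph, e$to[k])
      s <- paste0(s, substr(piece, e$ov[k] + 1L, nchar(piece)))
      v <- e$to[k]
    }
    contigs <- c(contigs, s)
  }
  contigs
}

#' Remove indel-drift artifacts from the uncondensed De Bruijn graph
#'
#' A deletion in a read makes its consecutive K-mers jump over one genome
#' window, adding a "skip" edge u -> w parallel to the well-supported
#' two-step path u -> v -> w; coinciding insertions occasionally create a
#' spurious interstitial cluster on a two-step path parallel to a
#' well-supported direct edge. Both are resolved by support dominance: the
#' minority variant is removed when the alternative carries at least
#' `ratio` times its read support.
#'
#' @param graph `xmb_graph` (uncondensed).
#' @param ratio dominance factor (default 2).
#' @return cleaned graph with attributes `n_skip_dropped`, `n_interstitial`.
#' @export
pop_indel_artifacts <- function(graph, ratio = 2) {
  e <- graph$edges
  if (!nrow(e)) return(graph)
  # two-step paths u -> v -> w with their bottleneck support
  m <- merge(data.frame(u = e$from, v = e$to, n1 = e$n),
             data.frame(v = e$from, w = e$to, n2 = e$n), by = "v")
  m <- m[m$u != m$w, , drop = FALSE]
  m$bottleneck <- pmin(m$n1, m$n2)
  # (1) skip edges dominated by a two-step path
  key_path <- paste(m$u, m$w)
  best_path <- tapply(m$bottleneck, key_path, max)
  key_edge <- paste(e$from, e$to)
  dom <- best_path[key_edge]
  drop_edge <- !is.na(dom) & dom >= ratio * pmax(e$n, 1) & !e$joined
  n_skip <- sum(drop_edge)
  # (2) interstitial nodes: v with a single in (u) and single out (w),
  # dominated by a direct edge u -> w
  deg <- node_degrees(graph)
  cand_v <- which(deg$ind == 1L & deg$outd == 1L)
  if (length(cand_v)) {
    vin <- e$from[match(cand_v, e$to)]
    vout <- e$to[match(cand_v, e$from)]
    n_in <- e$n[match(cand_v, e$to)]
    n_out <- e$n[match(cand_v, e$from)]
    direct <- e$n[match(paste(vin, vout), key_edge)]
    kill <- !is.na(direct) & direct >= ratio * pmax(pmin(n_in, n_out), 1)
    kill_v <- cand_v[kill]
  } else {
    kill_v <- integer(0)
  }
  e <- e[!drop_edge, , drop = FALSE]
  if (length(kill_v)) {
    e <- e[!(e$from %in% kill_v) & !(e$to %in% kill_v), , drop = FALSE]
    if (is.null(graph$dropped)) graph$dropped <- logical(n_nodes(graph))
    graph$dropped[kill_v] <- TRUE
  }
  graph$edges <- e
  attr(graph, "n_skip_dropped") <- n_skip
  attr(graph, "n_interstitial") <- length(kill_v)
  graph
}

#' Repair inverted edges of an indel-mode De Bruijn graph
#'
#' Alignment drift under indel noise can make a cluster adjacency appear in
#' both orientations across different reads. When both (u, v) and (v, u)
#' are present and one orientation dominates (at least `ratio` times the
#' read support of the other), the minority edge is an artifact and is
#' removed. Near-balanced bidirectional pairs are kept: they are genuine
#' two-visit cycles through a cluster that spans two nearby loci, which the
#' Euler traversal resolves.
#'
#' @param graph `xmb_graph` (uncondensed).
#' @param ratio dominance factor (default 3).
#' @return the repaired graph, with attribute `n_repaired`.
#' @export
repair_edge_directions <- function(graph, ratio = 3) {
  e <- graph$edges
  if (!nrow(e)) return(graph)
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  key <- paste(a, b)
  dupkey <- key[duplicated(key)]
  n_rep <- 0L
  drop <- logical(nrow(e))
  for (kk in unique(dupkey)) {
    idx <- which(key == kk)
    if (length(unique(paste(e$from[idx], e$to[idx]))) < 2) next
    fwd <- idx[e$from[idx] <= e$to[idx]]
    rev_ <- idx[e$from[idx] > e$to[idx]]
    nf <- sum(e$n[fwd]); nr <- sum(e$n[rev_])
    if (nf >= ratio * max(nr, 1)) {
      drop[rev_] <- TRUE
      n_rep <- n_rep + 1L
    } else if (nr >= ratio * max(nf, 1)) {
      drop[fwd] <- TRUE
      n_rep <- n_rep + 1L
    }
  }
  graph$edges <- e[!drop, , drop = FALSE]
  attr(graph, "n_repaired") <- n_rep
  graph
}

#' Pairwise overlap alignment of indel-noisy reads
#'
#' Banded edit-distance overlap alignments for fingerprint candidate pairs,
#' with the RA-style acceptance test (edit density below alpha over the
#' whole overlap and over both l_iid end windows of the alignment).
#'
#' @param reads `xmb_reads` or character vector.
#' @param params `xmb_overlap_params`.
#' @param band alignment band width.
#' @param index_stride fingerprint index stride.
#' @return data.frame with `i`, `j`, `offset`, `dist`, `W`, `accepted`.
#' @export
pairwise_overlap_align <- function(reads, params, band = 16L,
                                   index_stride = 1L) {
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  cand <- fingerprint_candidates(bases, params$f, max_offsets = 5L,
                                 index_stride = index_stride)
  cpp_overlap_align_stats(bases, cand$i, cand$j, cand$offset,
                          as.integer(band), params$alpha, params$l_iid)
}

#' Multibridging assembly (De Bruijn graph over K-mer clusters)
#'
#' Runs the eight-step pipeline: K-mer extraction and RA-rule clustering,
#' De Bruijn graph construction, component joining, condensation, branch
#' clearing, re-condensation and Euler spelling. K defaults to
#' flanked_crit + 2 l_iid (capped at L) when a critical flanked repeat
#' length estimate is supplied, else 2 l_iid + 100.
#'
#' @param reads `xmb_reads` or character vector.
#' @param params `xmb_overlap_params`.
#' @param K K-mer length override.
#' @param flanked_crit critical flanked repeat length estimate used to set K.
#' @param noise `"sub"` or `"indel"`.
#' @param p_indel p_i + p_d, used for the indel alignment band.
#' @param circular spell an Euler cycle for circular genomes.
#' @param index_stride fingerprint index stride.
#' @return object of class `xmb_assembly`: `contigs`, `graph`, `K`, `params`.
#' @export
multibridge_assemble <- function(reads, params, K = NULL,
                                 flanked_crit = NULL,
                                 noise = c("sub", "indel"), p_indel = 0.03,
                                 circular = FALSE, index_stride = 1L) {
  noise <- match.arg(noise)
  bases <- if (inherits(reads, "xmb_reads")) reads$bases else reads
  if (!length(bases)) stop("multibridge_assemble: empty read set")
  L <- min(nchar(bases))
  if (is.null(K)) {
    K <- if (!is.null(flanked_crit)) min(flanked_crit + 2L * params$l_iid, L)
         else min(2L * params$l_iid + 100L, L)
  }
  if (K < 2L * params$l_iid) {
    stop("multibridge_assemble: K must be at least 2*l_iid so both RA anchors fit")
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
  contigs <- euler_spell(g, circular = circular,
                         fallback = if (noise == "indel") "walk" else "unitigs")
  structure(list(contigs = as.character(contigs),
                 ambiguous = isTRUE(attr(contigs, "ambiguous")),
                 graph = g, K = as.integer(K), params = params),
            class = "xmb_assembly")
}

#' @export
print.xmb_assembly <- function(x, ...) {
  cat("xmb assembly: ", length(x$contigs), " contig(s), total ",
      sum(nchar(x$contigs)), " bases (K = ", x$K, ")\n", sep = "")
  invisible(x)
}
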