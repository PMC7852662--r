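# Median-joining haplotype networks (Bandelt-Forster-Rohl style):
# epsilon-relaxed minimum spanning network over the variable sites,
# iterative insertion of quasi-median (Steiner) vectors from linked
# triplets that minimise connection cost, and pruning of obsolete median
# vectors.

# Hamming distance matrix between rows of a character matrix.
.hamming <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      block <- mat[(i + 1L):n, , drop = FALSE] != matrix(mat[i, ], n - i,
                                                         ncol(mat), byrow = TRUE)
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- as.integer(rowSums(block))
    }
  }
  d
}

# Connection level delta(u,v): smallest weight w such that u and v are in
# the same component using only links of weight <= w. Union-find sweep.
.connection_levels <- function(d) {
  n <- nrow(d)
  delta <- matrix(Inf, n, n)
  diag(delta) <- 0
  comp <- seq_len(n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (d[i, j] == w && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
    newly <- outer(comp, comp, "==") & !is.finite(delta)
    delta[newly] <- w
  }
  delta
}

# Epsilon-relaxed minimum spanning network: links {u,v} with
# d(u,v) <= delta(u,v) + eps.
.msn_edges <- function(d, eps) {
  delta <- .connection_levels(d)
  sel <- which(upper.tri(d) & d <= delta + eps, arr.ind = TRUE)
  data.frame(i = sel[, 1L], j = sel[, 2L], w = d[sel])
}

# Quasi-medians of a triplet of character vectors: majority state per
# site; sites where all three states differ expand combinatorially
# (capped; triplets with more than `max_free` such sites are skipped).
.quasi_medians <- function(u, v, w, max_free = 3L) {
  L <- length(u)
  med <- character(L)
  free <- integer(0)
  for (s in seq_len(L)) {
    if (u[s] == v[s] || u[s] == w[s]) med[s] <- u[s]
    else if (v[s] == w[s]) med[s] <- v[s]
    else free <- c(free, s)
  }
  if (length(free) > max_free) return(NULL)
  if (!length(free)) return(matrix(med, 1L, L, byrow = TRUE))
  opts <- lapply(free, function(s) c(u[s], v[s], w[s]))
  grid <- as.matrix(expand.grid(opts, stringsAsFactors = FALSE))
  out <- matrix(rep(med, nrow(grid)), nrow(grid), L, byrow = TRUE)
  out[, free] <- grid
  out
}

#' Build a median-joining haplotype network
#'
#' Constructs the MJ network of a haplotype set over its variable
#' alignment columns: an epsilon-relaxed minimum spanning network is
#' computed, quasi-median vectors of triplets with at least two network
#' links are generated, and the candidates with minimal connection cost
#' (`d(u,m)+d(v,m)+d(w,m)`, within `epsilon`) are inserted; the cycle
#' repeats to fixation. Obsolete median vectors (unsampled nodes of degree
#' <= 2, or not on any minimal path between observed haplotypes) are
#' pruned at the end. Deterministic: haplotypes are processed in
#' lexicographic order of their variable-site strings.
#'
#' @param h a `haplotype_set` with `H >= 2` (see [collapse_haplotypes()]).
#' @param epsilon non-negative integer relaxation parameter (default 0,
#'   the usual strict behaviour).
#' @param groups optional metadata data.frame (`sample_id`, `group`) used
#'   to annotate nodes.
#' @param max_iter safety cap on median-insertion rounds.
#' @return object of class `haplotype_network`: `graph` (igraph, vertex
#'   attributes `name`, `seq`, `observed`, `multiplicity`, `group`; edge
#'   attributes `weight`, `sites` = original differing column indices),
#'   `nodes`, `edges` data.frames, `epsilon`, `var_sites`, and attribute
#'   `cost_trace` (total MSN cost after each insertion round).
#' @export
build_mj_network <- function(h, epsilon = 0L, groups = NULL, max_iter = 100L) {
  stopifnot(inherits(h, "haplotype_set"))
  if (h$H < 2L)
    stop("degenerate output: all sequences identical (H = 1); no network to build")
  if (epsilon < 0 || epsilon != round(epsilon))
    stop("epsilon must be a non-negative integer")
  var_sites <- which(apply(h$seqs, 2L, function(col) length(unique(col)) >= 2L))
  vmat <- h$seqs[, var_sites, drop = FALSE]
  keys <- apply(vmat, 1L, paste0, collapse = "")
  ord <- order(keys) # lexicographic tie-break
  vmat <- vmat[ord, , drop = FALSE]
  obs_label <- h$ids[ord]
  obs_mult <- h$multiplicity[ord]
  obs_members <- h$members[ord]

  U <- vmat                       # node matrix, observed first
  observed <- rep(TRUE, nrow(U))
  cost_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d <- .hamming(U)
    E <- .msn_edges(d, epsilon)
    cost_trace <- c(cost_trace, sum(E$w))
    linked <- matrix(FALSE, nrow(U), nrow(U))
    linked[cbind(E$i, E$j)] <- TRUE
    linked <- linked | t(linked)
    cand_seq <- character(0)
    cand_cost <- numeric(0)
    nn <- nrow(U)
    if (nn >= 3L) {
      trips <- utils::combn(nn, 3L)
      existing <- apply(U, 1L, paste0, collapse = "")
      for (tcol in seq_len(ncol(trips))) {
        a <- trips[1L, tcol]; b <- trips[2L, tcol]; cc <- trips[3L, tcol]
        nlinks <- linked[a, b] + linked[a, cc] + linked[b, cc]
        if (nlinks < 2L) next
        meds <- .quasi_medians(U[a, ], U[b, ], U[cc, ])
        if (is.null(meds)) next
        for (mrow in seq_len(nrow(meds))) {
          m <- meds[mrow, ]
          key <- paste0(m, collapse = "")
          if (key %in% existing || key %in% cand_seq) next
          lam <- sum(m != U[a, ]) + sum(m != U[b, ]) + sum(m != U[cc, ])
          cand_seq <- c(cand_seq, key)
          cand_cost <- c(cand_cost, lam)
        }
      }
    }
    if (!length(cand_seq)) break
    keep <- cand_cost <= min(cand_cost) + epsilon
    newkeys <- sort(cand_seq[keep]) # lexicographic, deterministic
    newmat <- matrix(unlist(strsplit(newkeys, "", fixed = TRUE)),
                     nrow = length(newkeys), byrow = TRUE)
    U <- rbind(U, newmat)
    observed <- c(observed, rep(FALSE, length(newkeys)))
  }

  # pruning: iteratively drop obsolete median vectors
  repeat {
    d <- .hamming(U)
    E <- .msn_edges(d, epsilon)
    deg <- tabulate(c(E$i, E$j), nbins = nrow(U))
    drop <- which(!observed & deg <= 2L)
    if (!length(drop) && any(!observed)) {
      g0 <- igraph::graph_from_data_frame(
        data.frame(from = E$i, to = E$j, weight = E$w),
        directed = FALSE, vertices = data.frame(name = seq_len(nrow(U))))
      dg <- igraph::distances(g0, weights = igraph::E(g0)$weight)
      obs_idx <- which(observed)
      onpath <- vapply(which(!observed), function(m) {
        any(outer(dg[obs_idx, m], dg[m, obs_idx], "+") ==
              dg[obs_idx, obs_idx] + 0)
      }, logical(1))
      drop <- which(!observed)[!onpath]
    }
    if (!length(drop)) break
    U <- U[-drop, , drop = FALSE]
    observed <- observed[-drop]
  }

  d <- .hamming(U)
  E <- .msn_edges(d, epsilon)
  nmed <- sum(!observed)
  name <- character(nrow(U))
  name[observed] <- obs_label
  if (nmed) name[!observed] <- paste0("MV", seq_len(nmed))
  mult <- integer(nrow(U)); mult[observed] <- obs_mult
  grp <- rep(NA_character_, nrow(U))
  if (!is.null(groups)) {
    gmap <- stats::setNames(groups$group, groups$sample_id)
    grp[observed] <- vapply(obs_members, function(mm)
      paste(sort(unique(stats::na.omit(gmap[mm]))), collapse = ","),
      character(1))
  }
  site_list <- vapply(seq_len(nrow(E)), function(r) {
    diffs <- which(U[E$i[r], ] != U[E$j[r], ])
    paste(var_sites[diffs], collapse = ",")
  }, character(1))
  nodes <- data.frame(name = name,
                      seq = apply(U, 1L, paste0, collapse = ""),
                      observed = observed, multiplicity = mult,
                      group = grp, stringsAsFactors = FALSE)
  edges <- data.frame(from = name[E$i], to = name[E$j], weight = E$w,
                      sites = site_list, stringsAsFactors = FALSE)
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  out <- structure(list(graph = graph, nodes = nodes, edges = edges,
                        epsilon = as.integer(epsilon),
                        var_sites = var_sites),
                   class = "haplotype_network")
  attr(out, "cost_trace") <- cost_trace
  out
}

#' @export
print.haplotype_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("haplotype_network: %d nodes (%d observed, %d median), %d edges, epsilon=%d\n",
              s$n_nodes, s$n_observed, s$n_median, s$n_edges, x$epsilon))
  cat(sprintf("  star-likeness %.3f, reticulations %d, max degree %d\n",
              s$star_likeness, s$reticulations, s$max_degree))
  invisible(x)
}

#' Summarise a haplotype network
#'
#' Node/edge/median counts, maximum degree, reticulation count
#' (`edges - nodes + components`), the modal (highest-multiplicity)
#' observed haplotype, and a star-likeness score in `[0, 1]`: the fraction
#' of observed haplotypes, other than the central node itself, that sit
#' one edge step from the network's central node. The centre is the
#' maximum-degree node (ties resolved observed-first, then by multiplicity,
#' then lexicographically); under a recent expansion the ancestral central
#' haplotype is typically unsampled and appears as a reconstructed median
#' hub, which is why centrality rather than multiplicity defines the
#' centre. A perfect star scores 1.
#'
#' @param net a `haplotype_network`.
#' @return list of summary statistics.
#' @export
network_summary <- function(net) {
  g <- net$graph
  nd <- net$nodes
  deg <- igraph::degree(g)
  obs <- which(nd$observed)
  modal <- obs[order(-nd$multiplicity[obs], nd$seq[obs])][1L]
  hub <- order(-deg, !nd$observed, -nd$multiplicity, nd$seq)[1L]
  others <- setdiff(obs, hub)
  star <- if (length(others)) {
    dg <- igraph::distances(g, v = hub, weights = NA)
    mean(dg[1L, others] == 1)
  } else NA_real_
  list(n_nodes = nrow(nd),
       n_observed = sum(nd$observed),
       n_median = sum(!nd$observed),
       n_edges = nrow(net$edges),
       max_degree = max(deg),
       modal_haplotype = nd$name[modal],
       central_node = nd$name[hub],
       star_likeness = star,
       reticulations = nrow(net$edges) - nrow(nd) +
         igraph::components(g)$no)
}

#' Export a haplotype network
#'
#' GraphML via igraph; a NEXUS `Network` block (vertices with observed
#' flag, multiplicity and group; edges with mutation counts); or a plain
#' TSV edge list.
#'
#' @param net a `haplotype_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_nexus <- function(net, path) {
  nd <- net$nodes
  ed <- net$edges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN NETWORK;", con)
  writeLines(sprintf("  DIMENSIONS NVERTICES=%d NEDGES=%d;", nrow(nd), nrow(ed)), con)
  writeLines("  VERTICES", con)
  for (i in seq_len(nrow(nd)))
    writeLines(sprintf("    %d %s observed=%s multiplicity=%d group=%s,",
                       i, nd$name[i], tolower(nd$observed[i]),
                       nd$multiplicity[i],
                       ifelse(is.na(nd$group[i]), "NA", nd$group[i])), con)
  writeLines("  ;", con)
  writeLines("  EDGES", con)
  idx <- stats::setNames(seq_len(nrow(nd)), nd$name)
  for (i in seq_len(nrow(ed)))
    writeLines(sprintf("    %d %d mutations=%d,",
                       idx[[ed$from[i]]], idx[[ed$to[i]]], ed$weight[i]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
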