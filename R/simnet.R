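# Pocket (or protein) similarity network and its community decomposition.
#
# Edges connect node pairs whose alignment P-value is below alpha (strict).
# Communities come from greedy agglomerative modularity maximization
# (CNM-style): repeatedly merge the connected community pair with the largest
# modularity gain, ties broken by the lexicographically smallest label pair,
# and stop when no merge has a strictly positive gain. Unweighted modularity
# is used because edges encode binary significance; igraph serves only for
# exports and as an independent cross-check in the tests.

#' Build a similarity network from alignment results
#'
#' @param results an `AllVsAll` object (or its `table` data frame with
#'   columns `pocket_a`, `pocket_b`, `q`).
#' @param model a `CalibrationModel` (or [evd_params()]).
#' @param alpha significance threshold (default 0.05); an edge is added iff
#'   `p < alpha` strictly.
#' @return A `SimilarityNetwork`: `nodes` (all ids, including isolated
#'   nodes), `edges` data frame (node_a, node_b, q, p).
#' @export
build_network <- function(results, model, alpha = 0.05) {
  tab <- if (inherits(results, "AllVsAll")) results$table else results
  nodes <- sort(unique(c(tab$pocket_a, tab$pocket_b)))
  p <- p_value(tab$q, model)
  keep <- p < alpha
  edges <- data.frame(node_a = tab$pocket_a[keep], node_b = tab$pocket_b[keep],
                      q = tab$q[keep], p = p[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "SimilarityNetwork")
}

#' @export
print.SimilarityNetwork <- function(x, ...) {
  cat(sprintf("SimilarityNetwork: %d nodes, %d edges (alpha = %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Construct a similarity network directly from nodes and edges
#'
#' Used by the synthetic planted-partition generator and tests.
#'
#' @param nodes node ids.
#' @param edges data frame with columns `node_a`, `node_b` (optionally `q`,
#'   `p`).
#' @export
new_network <- function(nodes, edges) {
  if (is.null(edges$q)) edges$q <- NA_real_
  if (is.null(edges$p)) edges$p <- NA_real_
  structure(list(nodes = sort(as.character(nodes)), edges = edges,
                 alpha = NA_real_), class = "SimilarityNetwork")
}

# node degrees within the network
.degrees <- function(net) {
  d <- setNames(rep(0L, length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    t1 <- table(net$edges$node_a); t2 <- table(net$edges$node_b)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Newman--Girvan modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` over communities, with `e_cc` the fraction of
#' edges inside community c and `a_c` the fraction of edge ends attached to
#' it; unweighted edges.
#'
#' @param net a `SimilarityNetwork`.
#' @param membership named vector mapping every node to a community label.
#' @export
modularity_score <- function(net, membership) {
  if (!all(net$nodes %in% names(membership)))
    stop("partition does not cover all nodes")
  m <- nrow(net$edges)
  if (m == 0) stop("modularity undefined for an edgeless network")
  ca <- membership[net$edges$node_a]
  cb <- membership[net$edges$node_b]
  labs <- unique(membership[net$nodes])
  ein <- vapply(labs, function(l) sum(ca == l & cb == l), numeric(1)) / m
  deg <- .degrees(net)
  a <- vapply(labs, function(l)
    sum(deg[net$nodes[membership[net$nodes] == l]]), numeric(1)) / (2 * m)
  sum(ein - a^2)
}

#' Greedy modularity community detection
#'
#' Agglomerative merging: starting from singleton communities, repeatedly
#' merge the pair of connected communities with the largest modularity gain
#' (ties: lexicographically smallest label pair) while the best gain is
#' strictly positive. Isolated nodes end as singleton communities. The result
#' is deterministic and invariant to node input order.
#'
#' @param net a `SimilarityNetwork`.
#' @return A `Partition`: `membership` (named integer vector, labels 1..K in
#'   order of each community's smallest node id) and `modularity` (0 for an
#'   edgeless network).
#' @export
detect_communities <- function(net) {
  nodes <- sort(net$nodes)
  if (nrow(net$edges) == 0) {
    memb <- setNames(seq_along(nodes), nodes)
    return(structure(list(membership = memb, modularity = 0),
                     class = "Partition"))
  }
  m <- nrow(net$edges)
  # community state: labels are the (current) smallest member node id
  comm <- setNames(nodes, nodes)
  dc <- .degrees(net)[nodes]            # total degree per community
  # inter-community edge counts, keyed "small|large"
  ekey <- function(a, b) ifelse(a < b, paste(a, b, sep = "\r"),
                                paste(b, a, sep = "\r"))
  ec <- new.env(hash = TRUE)
  for (i in seq_len(m)) {
    a <- comm[net$edges$node_a[i]]; b <- comm[net$edges$node_b[i]]
    if (a == b) next
    k <- ekey(a, b)
    ec[[k]] <- (if (is.null(ec[[k]])) 0 else ec[[k]]) + 1
  }
  repeat {
    keys <- ls(ec)
    if (length(keys) == 0) break
    parts <- strsplit(keys, "\r", fixed = TRUE)
    la <- vapply(parts, `[`, character(1), 1)
    lb <- vapply(parts, `[`, character(1), 2)
    lab <- vapply(keys, function(k) ec[[k]], numeric(1))
    gain <- lab / m - dc[la] * dc[lb] / (2 * m^2)
    best <- max(gain)
    if (best <= 1e-12) break
    cand <- which(gain >= best - 1e-12)
    # lexicographically smallest label pair among the tied best
    cand <- cand[order(la[cand], lb[cand])][1]
    a <- la[cand]; b <- lb[cand]       # a < b; merged community keeps label a
    # merge b into a
    comm[comm == b] <- a
    dc[a] <- dc[a] + dc[b]; dc <- dc[names(dc) != b]
    rm(list = ekey(a, b), envir = ec)
    for (k in ls(ec)) {
      pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
      if (b %in% pr) {
        other <- setdiff(pr, b)
        v <- ec[[k]]
        rm(list = k, envir = ec)
        if (other == a) next
        k2 <- ekey(a, other)
        ec[[k2]] <- (if (is.null(ec[[k2]])) 0 else ec[[k2]]) + v
      }
    }
  }
  # canonical integer labels: communities numbered by smallest member id
  labs <- sort(unique(comm))
  memb <- setNames(match(comm, labs), names(comm))
  q <- modularity_score(net, memb)
  structure(list(membership = memb, modularity = q), class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities over %d nodes, modularity %.4f\n",
              length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Extract pocket groups from a partition
#'
#' Groups are sorted by size (descending), ties by smallest member id, and
#' numbered 1..n in that order. A group is major when its size reaches
#' `min_size`; the representative is the member of maximal within-network
#' degree (ties: lexicographically smallest id).
#'
#' @param part a `Partition`.
#' @param net the `SimilarityNetwork` the partition was computed on.
#' @param min_size minimum size of a major group (default 5).
#' @return List of `PocketGroup`: `group_id`, `members`, `representative`,
#'   `is_major`.
#' @export
extract_groups <- function(part, net, min_size = 5) {
  memb <- part$membership
  if (length(memb) == 0) return(list())
  deg <- .degrees(net)
  labs <- unique(memb)
  blocks <- lapply(labs, function(l) sort(names(memb)[memb == l]))
  sizes <- vapply(blocks, length, integer(1))
  firsts <- vapply(blocks, `[`, character(1), 1)
  ord <- order(-sizes, firsts)
  blocks <- blocks[ord]
  out <- lapply(seq_along(blocks), function(g) {
    mem <- blocks[[g]]
    d <- deg[mem]
    rep_id <- sort(mem[d == max(d)])[1]
    structure(list(group_id = g, members = mem, representative = rep_id,
                   is_major = length(mem) >= min_size),
              class = "PocketGroup")
  })
  out
}

#' @export
print.PocketGroup <- function(x, ...) {
  cat(sprintf("PocketGroup %d%s: %d members, representative %s\n",
              x$group_id, if (x$is_major) " (major)" else "",
              length(x$members), x$representative))
  invisible(x)
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = net$nodes))
}

#' Export a similarity network
#'
#' Writes the edge list as TSV (`node_a`, `node_b`, `q`, `p`), and optionally
#' GraphML and SIF companions for external viewers.
#'
#' @param net a `SimilarityNetwork`.
#' @param path output TSV path.
#' @param graphml,sif optional output paths.
#' @export
write_network <- function(net, path, graphml = NULL, sif = NULL) {
  .write_tsv(net$edges, path)
  if (!is.null(graphml))
    igraph::write_graph(.as_igraph(net), graphml, format = "graphml")
  if (!is.null(sif)) {
    lines <- sprintf("%s sim %s", net$edges$node_a, net$edges$node_b)
    iso <- setdiff(net$nodes, c(net$edges$node_a, net$edges$node_b))
    writeLines(c(lines, iso), sif)
  }
  invisible(path)
}

#' Write pocket groups as TSV
#'
#' Columns `pocket_id`, `group_id`, `is_representative`; members of non-major
#' groups are reported with `group_id` 0 (unassigned / "grey" nodes).
#'
#' @param groups list of `PocketGroup` from [extract_groups()].
#' @param path output TSV.
#' @export
write_groups <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    data.frame(pocket_id = g$members,
               group_id = if (g$is_major) g$group_id else 0L,
               is_representative = g$members == g$representative,
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}
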