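make_q_for_p <- function(p_target, params) {
  # invert the survival function numerically (independent of .qgev)
  stats::uniroot(function(x) p_value(x, params) - p_target,
                 c(params$mu - 20 * params$sigma,
                   params$mu + 20 * params$sigma), tol = 1e-14)$root
}

test_that("network edges require p strictly below alpha", {
  params <- evd_params(k = 0.1, mu = 0.3, sigma = 0.05)
  model <- structure(list(params = params), class = "CalibrationModel")
  qs <- vapply(c(0.01, 0.2, 0.03), make_q_for_p, numeric(1), params = params)
  tab <- data.frame(pocket_a = c("a", "a", "b"), pocket_b = c("b", "c", "c"),
                    q = qs, stringsAsFactors = FALSE)
  net <- build_network(tab, model, alpha = 0.05)
  expect_equal(nrow(net$edges), 2)
  deg <- sort(unname(pocketmotif:::.degrees(net)), decreasing = TRUE)
  expect_equal(deg, c(2, 1, 1))

  # all pairs insignificant: edgeless but nodes retained
  tab$q <- rep(make_q_for_p(0.5, params), 3)
  net0 <- build_network(tab, model, alpha = 0.05)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(net0$nodes, c("a", "b", "c"))

  # boundary: p exactly equal to alpha adds no edge
  q05 <- make_q_for_p(0.05, params)
  tab1 <- tab[1, ]; tab1$q <- q05
  p_exact <- p_value(q05, params)
  expect_equal(nrow(build_network(tab1, model, alpha = p_exact)$edges), 0)

  # edge set shrinks monotonically as alpha decreases
  tab$q <- qs
  for (alpha in c(0.05, 0.02, 0.005)) {
    e1 <- build_network(tab, model, alpha = alpha)$edges
    e2 <- build_network(tab, model, alpha = alpha / 2)$edges
    expect_true(all(paste(e2$node_a, e2$node_b) %in%
                      paste(e1$node_a, e1$node_b)))
  }
})

test_that("modularity matches hand-computed values", {
  tri <- new_network(c(paste0("x", 1:3), paste0("y", 1:3)),
                     rbind(clique_edges(paste0("x", 1:3)),
                           clique_edges(paste0("y", 1:3))))
  memb <- setNames(c(1, 1, 1, 2, 2, 2), tri$nodes)
  expect_equal(modularity_score(tri, memb), 0.5)

  # one community on any graph gives 0
  expect_equal(modularity_score(tri, setNames(rep(1, 6), tri$nodes)), 0)

  expect_error(modularity_score(tri, memb[1:5]), "cover")
  empty <- new_network(c("a", "b"), edge_df(character(0), character(0))[0, ])
  expect_error(modularity_score(empty, setNames(1:2, c("a", "b"))),
               "edgeless")

  # cross-check against igraph on random graphs
  set.seed(17)
  for (i in 1:5) {
    g <- igraph::sample_gnp(10, 0.35)
    igraph::V(g)$name <- sprintf("v%02d", 1:10)
    ed <- igraph::as_data_frame(g)
    net <- new_network(sprintf("v%02d", 1:10),
                       edge_df(ed$from, ed$to))
    memb <- setNames(sample(1:3, 10, replace = TRUE), net$nodes)
    expect_equal(modularity_score(net, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
})

test_that("greedy community detection recovers canonical structures", {
  # two 4-cliques joined by a single edge
  net <- new_network(c(paste0("a", 1:4), paste0("b", 1:4)),
                     rbind(clique_edges(paste0("a", 1:4)),
                           clique_edges(paste0("b", 1:4)),
                           edge_df("a1", "b1")))
  part <- detect_communities(net)
  blocks <- split(names(part$membership), part$membership)
  expect_equal(length(blocks), 2)
  expect_true(all(sort(blocks[[1]]) == paste0("a", 1:4)))
  expect_true(all(sort(blocks[[2]]) == paste0("b", 1:4)))

  # edgeless network: singletons, modularity reported as 0
  iso <- new_network(c("u", "v"), edge_df(character(0), character(0))[0, ])
  p0 <- detect_communities(iso)
  expect_equal(unname(p0$membership), c(1, 2))
  expect_equal(p0$modularity, 0)

  # isolated nodes stay singletons next to real communities
  net2 <- new_network(c(net$nodes, "z9"), net$edges)
  part2 <- detect_communities(net2)
  expect_equal(sum(table(part2$membership) == 1), 1)
})

test_that("community detection is invariant to node input order", {
  set.seed(23)
  for (i in 1:5) {
    net <- make_planted_partition(3, 5, 0.8, 0.1, seed = 40 + i)
    shuf <- net
    ord <- sample(nrow(shuf$edges))
    shuf$edges <- shuf$edges[ord, ]
    flip <- runif(nrow(shuf$edges)) < 0.5
    tmp <- shuf$edges$node_a[flip]
    shuf$edges$node_a[flip] <- shuf$edges$node_b[flip]
    shuf$edges$node_b[flip] <- tmp
    shuf$nodes <- sample(shuf$nodes)
    expect_identical(detect_communities(shuf)$membership[net$nodes],
                     detect_communities(net)$membership[net$nodes])
  }
})

test_that("greedy modularity is near the igraph CNM reference", {
  set.seed(29)
  for (i in 1:5) {
    g <- igraph::sample_gnp(14, 0.25)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("v%02d", 1:14)
    ed <- igraph::as_data_frame(g)
    net <- new_network(sprintf("v%02d", 1:14), edge_df(ed$from, ed$to))
    mine <- detect_communities(net)$modularity
    ref <- max(igraph::cluster_fast_greedy(g)$modularity)
    expect_gte(mine, ref - 0.05)
  }
})

test_that("groups are ordered, sized and represented deterministically", {
  nodes <- c(sprintf("g1_%d", 1:7), sprintf("g2_%d", 1:6), "h1", "h2", "solo")
  edges <- rbind(clique_edges(sprintf("g1_%d", 1:7)),
                 clique_edges(sprintf("g2_%d", 1:6)),
                 edge_df("h1", "h2"))
  net <- new_network(nodes, edges)
  part <- detect_communities(net)
  groups <- extract_groups(part, net, min_size = 5)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  expect_equal(sizes, c(7L, 6L, 2L, 1L))
  expect_equal(vapply(groups, function(g) g$group_id, integer(1)), 1:4)
  expect_equal(vapply(groups, function(g) g$is_major, logical(1)),
               c(TRUE, TRUE, FALSE, FALSE))
  # clique members all tie on degree: lexicographically smallest id wins
  expect_equal(groups[[1]]$representative, "g1_1")

  # blocks partition the node set
  all_members <- unlist(lapply(groups, function(g) g$members))
  expect_setequal(all_members, nodes)
  expect_equal(anyDuplicated(all_members), 0L)

  expect_equal(extract_groups(structure(list(membership = setNames(
    integer(0), character(0)), modularity = 0), class = "Partition"),
    net), list())
})

test_that("network and group exports are written", {
  net <- new_network(c("a", "b", "c"), edge_df(c("a", "b"), c("b", "c")))
  net$edges$q <- c(0.9, 0.8); net$edges$p <- c(0.001, 0.002)
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  write_network(net, tsv, graphml = gml, sif = sif)
  expect_equal(nrow(read.table(tsv, header = TRUE)), 2)
  expect_true(file.size(gml) > 0)
  expect_equal(length(readLines(sif)), 2)

  part <- detect_communities(net)
  gr <- extract_groups(part, net, min_size = 2)
  gpath <- tempfile(fileext = ".tsv")
  write_groups(gr, gpath)
  tab <- read.table(gpath, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_true(any(tab$is_representative))
})
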