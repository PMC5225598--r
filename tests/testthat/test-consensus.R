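identity_pa <- function(M, n) {
  ids <- sprintf("p%d", seq_len(M))
  sizes <- setNames(rep(as.integer(n), M), ids)
  maps <- list()
  for (pr in combn(ids, 2, simplify = FALSE))
    maps[[paste(pr[1], pr[2], sep = "|")]] <-
      cbind(seq_len(n), seq_len(n))
  new_pairwise_set(ids, sizes, maps)
}

test_that("objective counts consensus-consistent aligned pairs", {
  pa <- identity_pa(3, 4)
  cons <- build_consensus(pa$ids, pa)
  expect_equal(cons$objective, 12L)  # C(3,2) pairs x 4 columns
  expect_equal(objective_score(cons, pa), 12L)

  # empty assignment scores zero
  empty <- structure(list(assign = lapply(pa$sizes, function(n)
    rep(NA_integer_, n)), n_columns = 4L, objective = 0L),
    class = "ConsensusAlignment")
  expect_equal(objective_score(empty, pa), 0L)

  # violated one-to-one constraint is rejected
  bad <- empty
  bad$assign[[1]] <- c(1L, 1L, 2L, 3L)
  expect_error(objective_score(bad, pa), "one-to-one")
})

test_that("M = 2 and M = 1 consensus follow the pairwise definition", {
  ids <- c("a", "b")
  maps <- list("a|b" = cbind(c(1L, 3L, 4L), c(2L, 1L, 4L)))
  pa <- new_pairwise_set(ids, setNames(c(4L, 4L), ids), maps)
  cons <- build_consensus(ids, pa)
  expect_equal(cons$n_columns, 3L)
  expect_equal(cons$objective, 3L)
  # columns where both residues are delta-aligned
  expect_equal(cons$assign[[1]][c(1, 3, 4)], cons$assign[[2]][c(2, 1, 4)])

  one <- new_pairwise_set("solo", c(solo = 5L), list())
  c1 <- build_consensus("solo", one)
  expect_equal(c1$n_columns, 5L)
  expect_equal(c1$objective, 0L)
})

test_that("find_seed picks the triple with most cyclically consistent triples", {
  # pockets 1-3 share 5 consistent triples; pocket 4 is nearly unrelated
  ids <- sprintf("p%d", 1:4)
  sizes <- setNames(rep(6L, 4), ids)
  idm <- cbind(1:5, 1:5)
  weak <- cbind(1:2, c(6L, 5L))
  maps <- list("p1|p2" = idm, "p1|p3" = idm, "p2|p3" = idm,
               "p1|p4" = weak, "p2|p4" = weak, "p3|p4" = weak)
  pa <- new_pairwise_set(ids, sizes, maps)
  seed <- find_seed(pa)
  expect_equal(seed$triple, 1:3)
  expect_equal(seed$cons$n_columns, 5L)

  # all-empty delta: 0 columns, empty consensus downstream
  none <- new_pairwise_set(ids[1:3], sizes[1:3],
                           setNames(lapply(1:3, function(i)
                             matrix(integer(0), 0, 2)),
                             c("p1|p2", "p1|p3", "p2|p3")))
  s0 <- find_seed(none)
  expect_equal(s0$cons$n_columns, 0L)
  expect_equal(build_consensus(ids[1:3], none)$n_columns, 0L)

  # M = 3 has exactly one triple
  expect_equal(find_seed(identity_pa(3, 4))$triple, 1:3)
  expect_error(find_seed(identity_pa(2, 4)), "at least 3")
})

test_that("max weight matching solves small instances exactly", {
  W <- diag(c(5, 4, 3)) + 0.1
  m <- max_weight_matching(W)
  expect_equal(m[, 1], 1:3)
  expect_equal(m[, 2], 1:3)

  expect_equal(nrow(max_weight_matching(matrix(0, 3, 4))), 0)
  expect_error(max_weight_matching(matrix(c(1, -1, 2, 3), 2)),
               "non-negative")

  set.seed(37)
  for (i in 1:30) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    W <- matrix(sample(0:9, nr * nc, replace = TRUE), nr, nc)
    m <- max_weight_matching(W)
    got <- sum(W[m, drop = FALSE])
    expect_equal(got, brute_mwm_weight(W))
    expect_equal(anyDuplicated(m[, 1]), 0L)
    expect_equal(anyDuplicated(m[, 2]), 0L)
    expect_true(all(W[m] > 0))
  }
})

test_that("adding pockets grows the objective as expected", {
  pa <- identity_pa(4, 4)
  seed <- find_seed(pa)
  cons3 <- seed$cons
  expect_equal(cons3$objective, 12L)
  cons4 <- add_pocket(cons3, 4L, pa)
  # the added identical pocket matches all 4 columns against 3 pockets
  expect_equal(cons4$objective, 12L + 3L * 4L)

  # pocket with empty delta rows contributes nothing
  ids <- sprintf("p%d", 1:4)
  maps <- pa$maps
  maps[["p1|p4"]] <- matrix(integer(0), 0, 2)
  maps[["p2|p4"]] <- matrix(integer(0), 0, 2)
  maps[["p3|p4"]] <- matrix(integer(0), 0, 2)
  pa2 <- new_pairwise_set(ids, pa$sizes, maps)
  cons4b <- add_pocket(find_seed(pa2)$cons, 4L, pa2)
  expect_equal(cons4b$objective, 12L)

  expect_error(add_pocket(pocketmotif:::.empty_cons(pa), 4L, pa),
               "empty consensus")
  expect_error(add_pocket(cons4, 4L, pa), "already assigned")
})

test_that("refinement never decreases the objective and fixes points", {
  pa <- identity_pa(4, 4)
  cons <- build_consensus(pa$ids, pa)
  expect_equal(refine(cons, pa)$objective, cons$objective)

  set.seed(41)
  for (i in 1:10) {
    pa <- random_pa(4, 4, seed = 500 + i)
    seed <- find_seed(pa)
    cons <- seed$cons
    for (j in setdiff(1:4, seed$triple)) cons <- add_pocket(cons, j, pa)
    ref <- refine(cons, pa)
    expect_gte(ref$objective, cons$objective)
    expect_silent(pocketmotif:::.check_cons(ref))
  }
})

test_that("greedy consensus never beats the exhaustive optimum", {
  for (i in 1:8) {
    pa <- random_pa(4, 3, seed = 900 + i, p_keep = 0.8)
    greedy <- build_consensus(pa$ids, pa)
    expect_lte(greedy$objective, brute_consensus_opt(pa))
  }
  # mutually consistent family: greedy attains the optimum C(M,2) * N
  pa <- identity_pa(4, 3)
  expect_equal(build_consensus(pa$ids, pa)$objective, 6L * 3L)
})

test_that("consensus is invariant to pocket relabeling", {
  set.seed(55)
  pa <- random_pa(4, 4, seed = 321)
  base <- build_consensus(pa$ids, pa)
  # relabel p1..p4 -> q4..q1 (reverses lexicographic order)
  relabel <- setNames(sprintf("q%d", 4:1), pa$ids)
  ids2 <- unname(relabel[pa$ids])
  maps2 <- list()
  for (key in names(pa$maps)) {
    pr <- strsplit(key, "|", fixed = TRUE)[[1]]
    a2 <- relabel[pr[1]]; b2 <- relabel[pr[2]]
    m <- pa$maps[[key]]
    if (a2 > b2) { tmp <- a2; a2 <- b2; b2 <- tmp; m <- m[, 2:1, drop = FALSE] }
    maps2[[paste(a2, b2, sep = "|")]] <- m
  }
  pa2 <- new_pairwise_set(ids2, setNames(unname(pa$sizes), ids2), maps2)
  rel <- build_consensus(ids2, pa2)
  expect_equal(rel$objective, base$objective)
})

test_that("consensus of an aligned noisy family spans full columns", {
  tmpl <- make_template_pocket(8, seed = 77, pocket_id = "T:1:A")
  fam <- make_family(tmpl, 6, noise_sigma = 0.2, permute = TRUE, seed = 78,
                     id_prefix = "C")
  ava <- all_vs_all(fam)
  pa <- pairwise_set(ava, sort(vapply(fam, function(p) p$pocket_id,
                                      character(1))))
  cons <- build_consensus(pa$ids, pa)
  expect_equal(cons$n_columns, 8L)
  # every column is occupied by every pocket (full columns = template size)
  occupied <- vapply(cons$assign, function(x) sum(!is.na(x)), integer(1))
  expect_true(all(occupied == 8L))
  expect_equal(cons$objective, choose(6, 2) * 8L)

  # writing the consensus table works
  pockets <- setNames(fam, vapply(fam, function(p) p$pocket_id, character(1)))
  path <- tempfile(fileext = ".tsv")
  write_consensus(cons, pa, pockets, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(dim(tab), c(6L, 9L))
})
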