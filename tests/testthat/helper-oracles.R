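# Independent brute-force oracles used to validate the optimizers. These are
# deliberately naive (full enumeration) and share no code with the package
# internals they check.

# all permutations of 1..n (n <= 7)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exhaustive gated assignment between equal-size point sets: over all
# permutations, the matched set is the allowed (<= dmax) subset; maximize
# size, then minimize total squared distance. Returns best size, cost, the
# optimal mapping and whether the optimum is unique.
brute_assign <- function(A, B, dmax) {
  n <- nrow(A)
  d2 <- as.matrix(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
  allowed <- d2 <= dmax^2
  P <- perms(n)
  best_size <- -1L; best_cost <- Inf; best_map <- NULL; n_opt <- 0L
  for (r in seq_len(nrow(P))) {
    p <- P[r, ]
    ok <- allowed[cbind(seq_len(n), p)]
    size <- sum(ok)
    cost <- sum(d2[cbind(seq_len(n), p)][ok])
    if (size > best_size || (size == best_size && cost < best_cost - 1e-12)) {
      best_size <- size; best_cost <- cost
      best_map <- cbind(which(ok), p[ok])
      n_opt <- 1L
    } else if (size == best_size && abs(cost - best_cost) <= 1e-12) {
      cand <- cbind(which(ok), p[ok])
      if (!identical(cand, best_map)) n_opt <- n_opt + 1L
    }
  }
  list(size = best_size, cost = best_cost, mapping = best_map,
       unique = n_opt == 1L)
}

# exhaustive maximum-weight matching on a rectangular non-negative matrix
brute_mwm_weight <- function(W) {
  nr <- nrow(W); nc <- ncol(W); n <- max(nr, nc)
  Wp <- matrix(0, n, n)
  Wp[seq_len(nr), seq_len(nc)] <- W
  P <- perms(n)
  max(vapply(seq_len(nrow(P)), function(r)
    sum(Wp[cbind(seq_len(n), P[r, ])]), numeric(1)))
}

# all set partitions of n items as restricted-growth strings
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, m) {
    k <- length(s)
    if (k == n) { out[[length(out) + 1]] <<- s; return(invisible()) }
    for (v in seq_len(m + 1)) rec(c(s, v), max(m, v))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximal modularity over all partitions of the network's nodes
brute_modularity_max <- function(net) {
  nodes <- sort(net$nodes)
  best <- -Inf
  for (s in set_partitions(length(nodes))) {
    memb <- setNames(s, nodes)
    q <- modularity_score(net, memb)
    if (q > best) best <- q
  }
  best
}

# exhaustive consensus optimum for M pockets of n residues over N = n
# columns. Full per-pocket bijections suffice: the objective is monotone
# under extending a partial assignment (delta counts are non-negative), so
# some full assignment attains the optimum.
brute_consensus_opt <- function(pa) {
  M <- length(pa$ids)
  n <- unname(pa$sizes[1])
  stopifnot(all(pa$sizes == n))
  P <- perms(n)
  idx <- rep(1L, M)
  best <- -1L
  total <- nrow(P)^M
  for (code in 0:(total - 1)) {
    c0 <- code
    assign <- vector("list", M)
    for (i in seq_len(M)) {
      assign[[i]] <- as.integer(P[c0 %% nrow(P) + 1, ])
      c0 <- c0 %/% nrow(P)
    }
    cons <- structure(list(assign = assign, n_columns = n, objective = 0L),
                      class = "ConsensusAlignment")
    sc <- objective_score(cons, pa)
    if (sc > best) best <- sc
  }
  best
}

# random pairwise alignment set: for every pocket pair an independent random
# partial one-to-one residue mapping
random_pa <- function(M, n, seed, p_keep = 0.7) {
  set.seed(seed)
  ids <- sprintf("p%d", seq_len(M))
  sizes <- setNames(rep(as.integer(n), M), ids)
  maps <- list()
  for (pr in combn(ids, 2, simplify = FALSE)) {
    keep <- which(runif(n) < p_keep)
    m <- cbind(keep, sample(n)[seq_along(keep)])
    maps[[paste(pr[1], pr[2], sep = "|")]] <-
      matrix(as.integer(m), ncol = 2)
  }
  new_pairwise_set(ids, sizes, maps)
}

# numeric minimization oracle for the 3-point superposition: minimize the
# residual over an Euler-angle rotation parameterization with multi-start
brute_kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sum((Ac - Bc %*% t(rotmat(ang)))^2)
  best <- Inf
  set.seed(99)
  for (s in 1:40) {
    r <- optim(runif(3, -pi, pi), f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    if (r$value < best) best <- r$value
  }
  sqrt(best / nrow(A))
}
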