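test_that("kabsch superposition recovers rigid transforms", {
  set.seed(10)
  A <- matrix(runif(30, -5, 5), ncol = 3)

  id <- kabsch_superpose(A, A)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(as.numeric(id$translation), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)   # 90 deg about z
  B <- sweep(A %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(A, B)
  back <- sweep(B %*% t(fit$rotation), 2, as.numeric(fit$translation), "+")
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(back, A, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(A, A[1:5, ]), "equal length")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("kabsch rmsd matches a numeric minimization oracle", {
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  B <- A; B[3, ] <- c(0, 1.2, 0)
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$rmsd, brute_kabsch_rmsd(A, B), tolerance = 1e-6)

  set.seed(4)
  for (i in 1:5) {
    A2 <- matrix(runif(12, -3, 3), ncol = 3)
    B2 <- A2 + matrix(rnorm(12, sd = 0.3), ncol = 3)
    expect_equal(kabsch_superpose(A2, B2)$rmsd, brute_kabsch_rmsd(A2, B2),
                 tolerance = 1e-5)
  }
})

test_that("gated assignment recovers permutations and respects the gate", {
  set.seed(21)
  A <- matrix(runif(18, -6, 6), ncol = 3)
  perm <- sample(6)
  m <- assign_correspondence(A, A[perm, ], d_max = 5)
  expect_equal(nrow(m), 6)
  expect_equal(m[, 2], order(perm)[m[, 1]])

  far <- sweep(A, 2, c(1000, 0, 0), "+")
  expect_equal(nrow(assign_correspondence(A, far, d_max = 5)), 0)
})

test_that("gated assignment agrees with exhaustive enumeration", {
  set.seed(31)
  for (i in 1:20) {
    A <- matrix(runif(18, -4, 4), ncol = 3)
    B <- matrix(runif(18, -4, 4), ncol = 3)
    m <- assign_correspondence(A, B, d_max = 4)
    oracle <- brute_assign(A, B, dmax = 4)
    expect_equal(nrow(m), oracle$size)
    cost <- sum(rowSums((A[m[, 1], , drop = FALSE] -
                           B[m[, 2], , drop = FALSE])^2))
    expect_equal(cost, oracle$cost, tolerance = 1e-9)
    if (oracle$unique && oracle$size > 0)
      expect_equal(unname(cbind(m[, 1], m[, 2])),
                   unname(oracle$mapping[order(oracle$mapping[, 1]), ,
                                         drop = FALSE]))
  }
})

test_that("q_score evaluates the formula and is monotone", {
  expect_identical(q_score(5, 0, 5, 5, 3.0), 1.0)
  expect_identical(q_score(5, 3.0, 5, 5, 3.0), 0.5)
  expect_identical(q_score(4, 1.5, 5, 8, 3.0), 16 / (1.25 * 40))

  # decreasing in rmsd, increasing in n_align
  r <- seq(0, 6, by = 0.5)
  expect_true(all(diff(q_score(5, r, 8, 8)) < 0))
  expect_true(all(diff(vapply(1:8, q_score, numeric(1),
                              rmsd = 1, n1 = 8, n2 = 8)) > 0))
  expect_error(q_score(6, 1, 5, 5), "n_align")
  expect_error(q_score(3, -1, 5, 5), "rmsd")
  expect_error(q_score(3, 1, 0, 5), "n1")
})

test_that("self-alignment under permutation and rigid motion is exact", {
  for (s in 1:5) {
    p <- make_template_pocket(10, seed = 100 + s, pocket_id = "a:1:A")
    cp <- rigid_copy(p, seed = 200 + s, id = "b:1:A")
    res <- align_pockets(p, cp)
    expect_equal(res$n_align, 10)
    expect_lt(res$rmsd, 1e-6)
    expect_lt(abs(res$q - 1), 1e-9)
    # mapping composes with the generating permutation to the identity
    perm <- attr(cp, "perm")
    expect_equal(res$mapping[, 1], perm[res$mapping[, 2]])
  }
})

test_that("alignment is symmetric and rigid-motion invariant", {
  p1 <- make_template_pocket(10, seed = 51, pocket_id = "x:1:A")
  p2 <- make_template_pocket(10, seed = 52, pocket_id = "y:1:A")
  r12 <- align_pockets(p1, p2)
  r21 <- align_pockets(p2, p1)
  expect_identical(r12$q, r21$q)
  expect_identical(r12$n_align, r21$n_align)

  moved <- rigid_copy(p2, seed = 60, id = "y:1:A", permute = FALSE)
  rmoved <- align_pockets(p1, moved)
  expect_lt(abs(rmoved$q - r12$q), 1e-6)
  expect_equal(rmoved$n_align, r12$n_align)
})

test_that("noisy rigid copies align at the noise floor, unrelated pairs lower", {
  p <- make_template_pocket(10, seed = 71, pocket_id = "t:1:A")
  sigma <- 0.2
  rmsds <- numeric(30); q_noisy <- numeric(30); q_rand <- numeric(30)
  for (i in 1:30) {
    cp <- rigid_copy(p, seed = 300 + i, id = "u:1:A", sigma = sigma)
    res <- align_pockets(p, cp)
    expect_equal(res$n_align, 10)
    rmsds[i] <- res$rmsd
    q_noisy[i] <- res$q
    q_rand[i] <- align_pockets(random_cloud_pocket(10, 400 + i, id = "v:1:A"),
                               random_cloud_pocket(10, 500 + i, id = "w:1:A"))$q
  }
  # expected pair RMSD ~ sigma * sqrt(3) (two noisy point sets after fitting)
  expect_true(all(rmsds > 0.5 * sigma * sqrt(3)))
  expect_true(all(rmsds < 1.5 * sigma * sqrt(3)))
  expect_true(mean(q_rand < min(q_noisy)) >= 0.95)
})

test_that("all_vs_all covers each unordered pair once, canonically", {
  pockets <- lapply(1:4, function(i)
    make_template_pocket(8, seed = 600 + i, pocket_id = sprintf("p%d:1:A", i)))
  ava <- all_vs_all(pockets)
  expect_equal(nrow(ava$table), 6)
  expect_true(all(ava$table$pocket_a < ava$table$pocket_b))

  # input order must not matter
  ava2 <- all_vs_all(rev(pockets))
  expect_equal(ava2$table, ava$table)

  dup <- c(pockets, pockets[1])
  expect_error(all_vs_all(dup), "duplicate pocket_id")

  # identical pockets: q all ~ 1
  same <- lapply(1:3, function(i) {
    p <- make_template_pocket(8, seed = 700, pocket_id = sprintf("q%d:1:A", i))
    p
  })
  ava3 <- all_vs_all(same)
  expect_true(all(abs(ava3$table$q - 1) < 1e-9))
})
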