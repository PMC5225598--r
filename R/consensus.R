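# Consensus multiple structure alignment of a pocket group.
#
# Given the pairwise non-sequential alignments (the indicator delta_ijkl = 1
# when residue k of pocket i is aligned to residue l of pocket j), the
# consensus assigns residues to shared columns x_ikc maximizing the number of
# pairwise-aligned residue pairs that agree with the consensus,
#   max sum_{i<j} sum_{k,l,c} delta_ijkl x_ikc x_jlc,
# under one-to-one constraints between every pocket and the columns. It is
# solved greedily: a seed of three pockets with maximal cyclically consistent
# residue triples, greedy insertion of the remaining pockets by maximum
# weight matching, then iterative single-pocket re-insertion.

#' Pairwise alignment set for a pocket group
#'
#' Collects the pairwise residue correspondences (the delta indicators) for
#' an ordered set of pockets from an all-vs-all run.
#'
#' @param ava an `AllVsAll` object covering at least `ids`.
#' @param ids ordered pocket ids of the group.
#' @param sizes optional named residue counts (taken from `ava` otherwise).
#' @return A `PairwiseAlignmentSet`: `ids`, `sizes`, and `maps`, a list keyed
#'   `"a|b"` (lexicographic id order) of 2-column residue-index matrices.
#' @export
pairwise_set <- function(ava, ids, sizes = NULL) {
  stopifnot(inherits(ava, "AllVsAll"))
  if (anyDuplicated(ids)) stop("duplicate ids in group")
  maps <- list()
  if (is.null(sizes)) sizes <- setNames(rep(NA_integer_, length(ids)), ids)
  if (length(ids) >= 2) {
    for (pr in combn(sort(ids), 2, simplify = FALSE)) {
      key <- paste(pr[1], pr[2], sep = "|")
      res <- ava$results[[key]]
      if (is.null(res))
        stop("missing pairwise alignment for ", key)
      maps[[key]] <- res$mapping
      sizes[pr[1]] <- res$n1
      sizes[pr[2]] <- res$n2
    }
  }
  structure(list(ids = ids, sizes = sizes[ids], maps = maps),
            class = "PairwiseAlignmentSet")
}

#' Build a pairwise alignment set directly from mappings
#'
#' Constructor for tests and small instances: `maps` is keyed `"a|b"` with
#' ids in lexicographic order and residue index pairs (k in a, l in b).
#'
#' @param ids ordered pocket ids.
#' @param sizes named residue counts.
#' @param maps named list of 2-column integer matrices.
#' @export
new_pairwise_set <- function(ids, sizes, maps) {
  structure(list(ids = ids, sizes = sizes[ids], maps = maps),
            class = "PairwiseAlignmentSet")
}

# residue map between pockets nr. i and j (indices into pa$ids), as the
# function l = f[k] (NA where unaligned)
.pa_fun <- function(pa, i, j) {
  a <- pa$ids[i]; b <- pa$ids[j]
  key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  m <- pa$maps[[key]]
  f <- rep(NA_integer_, pa$sizes[i])
  if (is.null(m) || nrow(m) == 0) return(f)
  if (a < b) f[m[, 1]] <- m[, 2] else f[m[, 2]] <- m[, 1]
  f
}

.check_cons <- function(cons) {
  for (x in cons$assign) {
    v <- x[!is.na(x)]
    if (anyDuplicated(v)) stop("consensus violates one-to-one constraints")
    if (any(v < 1 | v > cons$n_columns))
      stop("consensus column index out of range")
  }
  invisible(TRUE)
}

#' Consensus objective
#'
#' Number of pairwise-aligned residue pairs consistent with the consensus:
#' over unordered pocket pairs i < j and columns c, counts cases where both
#' pockets assign delta-aligned residues to the same column.
#'
#' @param cons a `ConsensusAlignment`.
#' @param pa the `PairwiseAlignmentSet`.
#' @export
objective_score <- function(cons, pa) {
  .check_cons(cons)
  M <- length(pa$ids)
  if (M < 2) return(0L)
  total <- 0L
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    f <- .pa_fun(pa, i, j)
    ci <- cons$assign[[i]]
    cj <- cons$assign[[j]]
    k <- which(!is.na(f) & !is.na(ci))
    if (length(k) == 0) next
    total <- total + sum(cj[f[k]] == ci[k], na.rm = TRUE)
  }
  as.integer(total)
}

.empty_cons <- function(pa, n_columns = 0L) {
  structure(list(assign = lapply(pa$sizes, function(n)
    rep(NA_integer_, n)),
    n_columns = as.integer(n_columns), objective = 0L,
    assigned = integer(0)),
    class = "ConsensusAlignment")
}

#' Seed triple of a pocket group
#'
#' Enumerates all pocket triples and counts cyclically consistent residue
#' triples (k, l, m) with `delta_ijkl = delta_ipkm = delta_jplm = 1`; the
#' winning triple's consistent triples become the first consensus columns.
#' Ties are broken by lexicographic triple order. For M <= 2 the consensus is
#' the pairwise mapping (M = 2) or the pocket itself (M = 1) and no seed is
#' needed.
#'
#' @param pa a `PairwiseAlignmentSet` with M >= 3 pockets.
#' @return List with `triple` (pocket indices) and `cons`, the seeded
#'   `ConsensusAlignment`.
#' @export
find_seed <- function(pa) {
  M <- length(pa$ids)
  if (M < 3) stop("find_seed needs at least 3 pockets; smaller groups are ",
                  "handled by build_consensus directly")
  best <- NULL; best_n <- -1L
  for (tri in combn(M, 3, simplify = FALSE)) {
    i <- tri[1]; j <- tri[2]; p <- tri[3]
    fij <- .pa_fun(pa, i, j); fip <- .pa_fun(pa, i, p); fjp <- .pa_fun(pa, j, p)
    k <- which(!is.na(fij) & !is.na(fip))
    cyc <- k[!is.na(fjp[fij[k]]) & fjp[fij[k]] == fip[k]]
    if (length(cyc) > best_n) {
      best_n <- length(cyc)
      best <- list(triple = tri, k = cyc, l = fij[cyc], m = fip[cyc])
    }
  }
  cons <- .empty_cons(pa, n_columns = best_n)
  if (best_n > 0) {
    ord <- order(best$k)
    cons$assign[[best$triple[1]]][best$k[ord]] <- seq_len(best_n)
    cons$assign[[best$triple[2]]][best$l[ord]] <- seq_len(best_n)
    cons$assign[[best$triple[3]]][best$m[ord]] <- seq_len(best_n)
  }
  cons$assigned <- best$triple
  cons$objective <- objective_score(cons, pa)
  list(triple = best$triple, cons = cons)
}

#' Maximum-weight one-to-one matching
#'
#' Matches rows to columns of a non-negative weight matrix maximizing the
#' total weight; zero-weight pairs are excluded. Ties among maximal-weight
#' matchings are broken deterministically toward low (row, column) indices
#' (exactly the lexicographically smallest pair set for integer weights).
#'
#' @param weights non-negative numeric matrix.
#' @return Two-column integer matrix of (row, col) pairs.
#' @export
max_weight_matching <- function(weights) {
  weights <- as.matrix(weights)
  if (length(weights) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  m <- .cpp_mwm(weights)
  colnames(m) <- c("row", "col")
  m[order(m[, 1]), , drop = FALSE]
}

# delta-support weight matrix of pocket i against the assigned pockets
.add_weights <- function(cons, pa, i, assigned) {
  ni <- pa$sizes[i]
  W <- matrix(0, ni, max(cons$n_columns, 1L))
  if (cons$n_columns == 0) return(W[, 0, drop = FALSE])
  W <- matrix(0, ni, cons$n_columns)
  for (j in assigned) {
    f <- .pa_fun(pa, i, j)
    cj <- cons$assign[[j]]
    k <- which(!is.na(f))
    cc <- cj[f[k]]
    ok <- !is.na(cc)
    if (any(ok)) {
      idx <- cbind(k[ok], cc[ok])
      W[idx] <- W[idx] + 1
    }
  }
  W
}

#' Greedily add a pocket to a consensus
#'
#' Weights each (residue, column) pair by its delta support among already
#' assigned pockets, assigns by [max_weight_matching()], and opens new
#' columns (up to the maximum pocket size in the group) for unmatched
#' residues.
#'
#' @param cons current `ConsensusAlignment` (must contain at least one
#'   assigned pocket).
#' @param i index of the pocket to add (currently unassigned).
#' @param pa the `PairwiseAlignmentSet`.
#' @export
add_pocket <- function(cons, i, pa) {
  assigned <- cons$assigned
  if (length(assigned) == 0)
    stop("cannot add to an empty consensus: build a seed first")
  if (i %in% assigned) stop("pocket ", pa$ids[i], " is already assigned")
  ni <- pa$sizes[i]
  W <- .add_weights(cons, pa, i, assigned)
  x <- rep(NA_integer_, ni)
  if (ncol(W) > 0 && any(W > 0)) {
    mt <- max_weight_matching(W)
    x[mt[, 1]] <- mt[, 2]
  }
  n_max <- max(pa$sizes)
  for (k in which(is.na(x))) {
    if (cons$n_columns >= n_max) break
    cons$n_columns <- cons$n_columns + 1L
    x[k] <- cons$n_columns
  }
  cons$assign[[i]] <- x
  cons$assigned <- sort(c(assigned, i))
  cons$objective <- objective_score(cons, pa)
  cons
}

# remove pocket i, dropping columns that become empty (renumbering preserves
# column order)
.remove_pocket <- function(cons, i, pa) {
  cons$assign[[i]] <- rep(NA_integer_, pa$sizes[i])
  cons$assigned <- setdiff(cons$assigned, i)
  used <- sort(unique(unlist(lapply(cons$assign, function(x) x[!is.na(x)]))))
  remap <- integer(cons$n_columns)
  remap[used] <- seq_along(used)
  cons$assign <- lapply(cons$assign, function(x) {
    x[!is.na(x)] <- remap[x[!is.na(x)]]
    x
  })
  cons$n_columns <- length(used)
  cons
}

#' Iterative refinement of a consensus
#'
#' Repeatedly removes one pocket at a time (in input order) and re-adds it
#' via [add_pocket()], keeping the re-assignment iff the objective does not
#' decrease. Stops when a full round brings no improvement or after
#' `max_rounds`. The objective is monotonically non-decreasing.
#'
#' @param cons a `ConsensusAlignment` with all pockets assigned.
#' @param pa the `PairwiseAlignmentSet`.
#' @param max_rounds maximum full passes (default 10).
#' @export
refine <- function(cons, pa, max_rounds = 10) {
  M <- length(pa$ids)
  if (M < 2) return(cons)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (i in seq_len(M)) {
      trial <- .remove_pocket(cons, i, pa)
      if (length(trial$assigned) == 0) next
      trial <- add_pocket(trial, i, pa)
      if (trial$objective >= cons$objective) {
        if (trial$objective > cons$objective) improved <- TRUE
        cons <- trial
      }
    }
    if (!improved) break
  }
  cons
}

#' Build the consensus alignment of a pocket group
#'
#' For M >= 3: seed triple ([find_seed()]), greedy insertion of the remaining
#' pockets in descending order of total delta overlap with the already
#' assigned set (ties: lexicographic id), then [refine()]. For M = 2 the
#' consensus columns are the pairwise mapping; for M = 1 every residue is its
#' own column. Deterministic throughout.
#'
#' @param ids pocket ids of the group (or a `PocketGroup`).
#' @param pa a `PairwiseAlignmentSet` covering the group (ignored ids
#'   outside `ids` are not allowed).
#' @param max_rounds refinement rounds.
#' @return A `ConsensusAlignment`: per-pocket column assignments `assign`,
#'   `n_columns`, and the `objective`.
#' @export
build_consensus <- function(ids, pa = NULL, max_rounds = 10) {
  if (inherits(ids, "PocketGroup")) ids <- ids$members
  stopifnot(inherits(pa, "PairwiseAlignmentSet"),
            identical(sort(ids), sort(pa$ids)))
  M <- length(pa$ids)
  if (M == 1) {
    cons <- .empty_cons(pa, n_columns = pa$sizes[1])
    cons$assign[[1]] <- seq_len(pa$sizes[1])
    cons$assigned <- 1L
    cons$objective <- 0L
    return(cons)
  }
  if (M == 2) {
    f <- .pa_fun(pa, 1, 2)
    k <- which(!is.na(f))
    cons <- .empty_cons(pa, n_columns = length(k))
    cons$assign[[1]][k] <- seq_along(k)
    cons$assign[[2]][f[k]] <- seq_along(k)
    cons$assigned <- 1:2
    cons$objective <- objective_score(cons, pa)
    return(cons)
  }
  if (all(vapply(pa$maps, nrow, integer(1)) == 0)) return(.empty_cons(pa))
  seed <- find_seed(pa)
  cons <- seed$cons
  remaining <- setdiff(seq_len(M), seed$triple)
  while (length(remaining) > 0) {
    assigned <- setdiff(seq_len(M), remaining)
    overlap <- vapply(remaining, function(i)
      sum(vapply(assigned, function(j) sum(!is.na(.pa_fun(pa, i, j))),
                 numeric(1))), numeric(1))
    pick <- remaining[order(-overlap, pa$ids[remaining])][1]
    cons <- add_pocket(cons, pick, pa)
    remaining <- setdiff(remaining, pick)
  }
  refine(cons, pa, max_rounds = max_rounds)
}

#' @export
print.ConsensusAlignment <- function(x, ...) {
  cat(sprintf("ConsensusAlignment: %d pockets, %d columns, objective %d\n",
              length(x$assign), x$n_columns, x$objective))
  invisible(x)
}

#' Write a consensus alignment as TSV
#'
#' Rows are pockets, columns are consensus positions, cells hold the residue
#' key (`chain/seqnum/icode`) or `-`.
#'
#' @param cons a `ConsensusAlignment`.
#' @param pa the matching `PairwiseAlignmentSet`.
#' @param pockets named list of `PocketStructure` for residue keys.
#' @param path output TSV.
#' @export
write_consensus <- function(cons, pa, pockets, path) {
  N <- cons$n_columns
  rows <- lapply(seq_along(pa$ids), function(i) {
    p <- pockets[[pa$ids[i]]]
    cells <- rep("-", N)
    x <- cons$assign[[i]]
    k <- which(!is.na(x))
    cells[x[k]] <- sprintf("%s/%d%s", p$keys$chain_id[k], p$keys$seq_num[k],
                           p$keys$icode[k])
    as.data.frame(c(list(pocket_id = pa$ids[i]), as.list(cells)),
                  col.names = c("pocket_id", paste0("col", seq_len(N))),
                  stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}
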