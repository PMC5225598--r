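# Non-sequential-order rigid-body alignment of residue pockets.
#
# The aligner alternates two steps that realize the two stated objectives of
# multi-objective structure alignment: (1) an optimal one-to-one residue
# assignment (minimum-cost linear assignment on squared distances, pairs
# beyond d_max forbidden — maximal correspondence size first, then minimal
# squared distance) and (2) a least-squares Kabsch superposition of the
# currently mapped residues. The alternation runs from a deterministic set of
# initial orientations (four proper principal-axis frames plus quasi-uniform
# quaternion seeds from a Halton sequence) and returns the converged result
# of maximal Q-score.

#' Alignment parameters
#'
#' @param r0 Q-score normalizing factor in Angstrom (default 3.0).
#' @param d_max assignment distance gate in Angstrom (default 5.0): residue
#'   pairs farther apart are never matched.
#' @param n_rotation_seeds number of quasi-uniform rotation seeds in addition
#'   to the four principal-axis frames (default 24).
#' @param max_iter maximum assign/superpose iterations per seed (default 50).
#' @param tol convergence tolerance on the RMSD change (default 1e-6).
#' @export
alignment_params <- function(r0 = 3.0, d_max = 5.0, n_rotation_seeds = 24,
                             max_iter = 50, tol = 1e-6) {
  stopifnot(r0 > 0, d_max > 0, n_rotation_seeds > 0, max_iter > 0, tol > 0)
  structure(list(r0 = r0, d_max = d_max,
                 n_rotation_seeds = as.integer(n_rotation_seeds),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "AlignmentParams")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' `sum(|R b_i + t - a_i|^2)`.
#'
#' @param points_a,points_b n x 3 coordinate matrices, equal n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(points_a, points_b) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  if (nrow(points_a) != nrow(points_b))
    stop("point sets must have equal length")
  if (nrow(points_a) < 3) stop("superposition needs at least 3 points")
  .cpp_kabsch(points_a, points_b)
}

#' Optimal gated residue correspondence
#'
#' One-to-one mapping between two coordinate sets after applying a
#' superposition to the second: among mappings in which every matched pair is
#' within `d_max`, the correspondence of maximal size and, within that, of
#' minimal total squared distance.
#'
#' @param coords_a,coords_b coordinate matrices (n1 x 3, n2 x 3).
#' @param sup superposition applied to `coords_b` (list with `rotation`,
#'   `translation`), or `NULL` for none.
#' @param d_max distance gate in Angstrom.
#' @return Two-column integer matrix of (a_index, b_index) pairs; possibly
#'   zero rows.
#' @export
assign_correspondence <- function(coords_a, coords_b, sup = NULL, d_max = 5.0) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(nrow(coords_a) > 0, nrow(coords_b) > 0)
  if (!is.null(sup)) {
    coords_b <- coords_b %*% t(sup$rotation)
    coords_b <- sweep(coords_b, 2, as.numeric(sup$translation), "+")
  }
  m <- .cpp_assign(coords_a, coords_b, d_max)
  colnames(m) <- c("a_index", "b_index")
  m
}

#' Q-score of an alignment
#'
#' `Q = N_align^2 / ((1 + (RMSD/R0)^2) * N1 * N2)`, in \[0, 1\]: large
#' correspondences with low RMSD relative to the normalizing factor R0 score
#' high, and the product N1*N2 penalizes aligning only fragments of either
#' structure.
#'
#' @param n_align number of aligned residue pairs.
#' @param rmsd RMSD of the aligned pairs (Angstrom).
#' @param n1,n2 residue counts of the two structures.
#' @param r0 normalizing factor (default 3.0).
#' @export
q_score <- function(n_align, rmsd, n1, n2, r0 = 3.0) {
  if (any(n1 < 1) || any(n2 < 1)) stop("n1 and n2 must be >= 1")
  if (any(n_align < 0) || any(n_align > pmin(n1, n2)))
    stop("n_align must lie in [0, min(n1, n2)]")
  if (any(!is.finite(rmsd)) || any(rmsd < 0))
    stop("rmsd must be finite and >= 0")
  n_align^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
}

.align_xyz <- function(xyz_a, xyz_b, params, pa_only = FALSE) {
  .cpp_align(xyz_a, xyz_b, params$r0, params$d_max, params$n_rotation_seeds,
             params$max_iter, params$tol, pa_only)
}

.as_alignment_result <- function(raw, id_a, id_b, n1, n2, swapped = FALSE) {
  mapping <- raw$mapping
  if (swapped && nrow(mapping) > 0) mapping <- mapping[, c(2, 1), drop = FALSE]
  if (nrow(mapping) > 0) {
    mapping <- mapping[order(mapping[, 1]), , drop = FALSE]
    colnames(mapping) <- c("a_index", "b_index")
  }
  structure(list(id_a = id_a, id_b = id_b, n1 = n1, n2 = n2,
                 n_align = raw$n_align, rmsd = raw$rmsd, q = raw$q,
                 mapping = mapping,
                 superposition = list(rotation = raw$rotation,
                                      translation = as.numeric(raw$translation)),
                 swapped = swapped),
            class = "AlignmentResult")
}

#' Align two pockets non-sequentially
#'
#' Runs the alternating assignment/superposition scheme from every initial
#' orientation seed and returns the converged result of maximal Q-score.
#' Internally the pocket pair is put in canonical (lexicographic id) order so
#' that `align_pockets(a, b)` and `align_pockets(b, a)` give exactly equal
#' Q-scores; the returned mapping and superposition are always expressed in
#' the argument order (superposition maps `b` onto `a`).
#'
#' @param a,b `PocketStructure` objects with >= 3 residues.
#' @param params an [alignment_params()] object.
#' @return An `AlignmentResult`: `mapping` (a_index, b_index), `n_align`,
#'   `rmsd`, `q`, `n1`, `n2` and the rigid `superposition`.
#' @export
align_pockets <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(a, "PocketStructure"), inherits(b, "PocketStructure"))
  if (nrow(a$xyz) < 3 || nrow(b$xyz) < 3)
    stop("alignment needs pockets with at least 3 residues")
  swap <- is.character(a$pocket_id) && is.character(b$pocket_id) &&
    a$pocket_id > b$pocket_id
  if (swap) {
    raw <- .align_xyz(b$xyz, a$xyz, params)
    res <- .as_alignment_result(raw, a$pocket_id, b$pocket_id,
                                nrow(a$xyz), nrow(b$xyz), swapped = TRUE)
    # re-express the transform as b -> a (inverse of the canonical a -> b fit)
    R <- t(raw$rotation)
    res$superposition <- list(rotation = R,
                              translation = as.numeric(-R %*% as.numeric(raw$translation)))
    res
  } else {
    raw <- .align_xyz(a$xyz, b$xyz, params)
    .as_alignment_result(raw, a$pocket_id, b$pocket_id,
                         nrow(a$xyz), nrow(b$xyz))
  }
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf(
    "AlignmentResult %s vs %s: n_align %d/%d,%d  rmsd %.3f A  Q %.4f\n",
    x$id_a, x$id_b, x$n_align, x$n1, x$n2, x$rmsd, x$q))
  invisible(x)
}

#' All-against-all pocket alignment
#'
#' Aligns every unordered pocket pair once, in canonical (lexicographic id)
#' order, and returns the results as a data frame plus the detailed
#' per-pair results.
#'
#' @param pockets list of `PocketStructure` with unique ids, length >= 2.
#' @param params an [alignment_params()] object.
#' @param progress log progress every this many pairs (0 = silent).
#' @return An `AllVsAll` object: `table` data frame (pocket_a, pocket_b, n1,
#'   n2, n_align, rmsd, q) over all unordered pairs with pocket_a < pocket_b,
#'   and `results` named list (`"a|b"`) of `AlignmentResult`.
#' @export
all_vs_all <- function(pockets, params = alignment_params(), progress = 0) {
  ids <- vapply(pockets, function(p) p$pocket_id, character(1))
  if (length(pockets) < 2) stop("need at least 2 pockets")
  if (anyDuplicated(ids))
    stop("duplicate pocket_id: ", ids[duplicated(ids)][1])
  ord <- order(ids)
  pockets <- pockets[ord]; ids <- ids[ord]
  n <- length(pockets)
  pairs <- combn(n, 2)
  m <- ncol(pairs)
  rows <- vector("list", m)
  results <- vector("list", m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- tryCatch(align_pockets(pockets[[i]], pockets[[j]], params),
                    error = function(e)
                      stop("alignment failed for pair ", ids[i], " vs ",
                           ids[j], ": ", conditionMessage(e), call. = FALSE))
    rows[[k]] <- data.frame(pocket_a = ids[i], pocket_b = ids[j],
                            n1 = res$n1, n2 = res$n2, n_align = res$n_align,
                            rmsd = res$rmsd, q = res$q,
                            stringsAsFactors = FALSE)
    results[[k]] <- res
    if (progress > 0 && k %% progress == 0)
      message(sprintf("[align] %d / %d pairs", k, m))
  }
  names(results) <- vapply(rows, function(r)
    paste(r$pocket_a, r$pocket_b, sep = "|"), character(1))
  structure(list(table = do.call(rbind, rows), results = results,
                 node_ids = ids), class = "AllVsAll")
}

#' Write an all-vs-all alignment table
#'
#' @param ava an `AllVsAll` object.
#' @param path output TSV.
#' @export
write_alignment_table <- function(ava, path) .write_tsv(ava$table, path)
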