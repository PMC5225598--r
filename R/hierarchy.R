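# Protein-level similarity and the pocket <-> protein group correspondence.
#
# Whole chains are aligned with the same non-sequential engine as pockets but
# from principal-axis seeds only: exhaustive rotational seeding is wasteful
# at ~200 residues (each extra seed costs a full alternation at O(n^3)
# assignment cost), and chain-scale clouds are anisotropic enough for the
# four proper principal-axis frames to bracket the basin. Protein-level
# significance must be calibrated on its own background of random chain
# pairs (score distributions shift with size); the pocket EVD is never
# reused.

#' Align two protein chains non-sequentially
#'
#' Same engine and Q-score as [align_pockets()] with N1, N2 the chain
#' lengths; initial orientations restricted to the principal-axis frames.
#'
#' @param a,b `ChainStructure` objects with >= 3 CA residues, or
#'   `PocketStructure`-like coordinate carriers.
#' @param params an [alignment_params()] object.
#' @return An `AlignmentResult`.
#' @export
align_chains <- function(a, b, params = alignment_params()) {
  pa <- .chain_as_pocket(a); pb <- .chain_as_pocket(b)
  if (nrow(pa$xyz) < 3 || nrow(pb$xyz) < 3)
    stop("chain alignment needs at least 3 CA residues")
  swap <- pa$pocket_id > pb$pocket_id
  if (swap) {
    raw <- .align_xyz(pb$xyz, pa$xyz, params, pa_only = TRUE)
    res <- .as_alignment_result(raw, pa$pocket_id, pb$pocket_id,
                                nrow(pa$xyz), nrow(pb$xyz), swapped = TRUE)
    R <- t(raw$rotation)
    res$superposition <- list(rotation = R,
                              translation = as.numeric(-R %*% as.numeric(raw$translation)))
    res
  } else {
    raw <- .align_xyz(pa$xyz, pb$xyz, params, pa_only = TRUE)
    .as_alignment_result(raw, pa$pocket_id, pb$pocket_id,
                         nrow(pa$xyz), nrow(pb$xyz))
  }
}

.chain_as_pocket <- function(x) {
  if (inherits(x, "PocketStructure")) return(x)
  stopifnot(inherits(x, "ChainStructure"))
  r <- x$residues[x$residues$polymer_class == "protein" &
                    !is.na(x$residues$ca_x), , drop = FALSE]
  new_pocket(paste(x$structure_id, x$chain_id, sep = ":"),
             as.matrix(r[, c("ca_x", "ca_y", "ca_z")]),
             ifelse(is.na(r$aa1), "X", r$aa1),
             keys = data.frame(chain_id = r$chain_id, seq_num = r$seq_num,
                               icode = r$icode, stringsAsFactors = FALSE))
}

#' Pocket <-> protein group correspondence
#'
#' Joins the pocket grouping with the grouping of the parent proteins and
#' reports, per protein group, the multiset of pocket-group labels, plus the
#' consistency statistic: the fraction of multi-pocket proteins whose
#' pockets span more than one pocket group.
#'
#' @param pocket_groups list of `PocketGroup` for pockets.
#' @param protein_groups list of `PocketGroup` for proteins.
#' @param pocket_parents named character vector mapping pocket id to parent
#'   protein id; must cover every grouped pocket.
#' @return A `CorrespondenceTable`: `table` data frame (protein_id,
#'   protein_group, pocket_id, pocket_group), `summary` (per protein group,
#'   table of pocket-group labels), `spanning_fraction`.
#' @export
build_correspondence <- function(pocket_groups, protein_groups,
                                 pocket_parents) {
  glab <- function(groups) {
    out <- list()
    for (g in groups)
      for (m in g$members)
        out[[m]] <- if (g$is_major) g$group_id else 0L
    out
  }
  pg <- glab(pocket_groups)
  rg <- glab(protein_groups)
  pockets <- names(pg)
  orphan <- setdiff(pockets, names(pocket_parents))
  if (length(orphan) > 0)
    stop("orphan pockets without a parent protein: ",
         paste(orphan, collapse = ", "))
  tab <- data.frame(
    protein_id = unname(pocket_parents[pockets]),
    protein_group = vapply(pockets, function(p) {
      v <- rg[[pocket_parents[[p]]]]
      if (is.null(v)) NA_integer_ else v
    }, integer(1)),
    pocket_id = pockets,
    pocket_group = vapply(pockets, function(p) pg[[p]], integer(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$protein_id, tab$pocket_id), , drop = FALSE]
  rownames(tab) <- NULL
  summary <- lapply(split(tab$pocket_group, tab$protein_group),
                    table)
  per_protein <- split(tab$pocket_group, tab$protein_id)
  multi <- per_protein[vapply(per_protein, length, integer(1)) > 1]
  spanning <- if (length(multi) == 0) 0 else
    mean(vapply(multi, function(x) length(unique(x)) > 1, logical(1)))
  structure(list(table = tab, summary = summary,
                 spanning_fraction = spanning),
            class = "CorrespondenceTable")
}

#' @export
print.CorrespondenceTable <- function(x, ...) {
  cat(sprintf(
    "CorrespondenceTable: %d pockets, %d proteins, spanning fraction %.3f\n",
    nrow(x$table), length(unique(x$table$protein_id)), x$spanning_fraction))
  invisible(x)
}

#' Write a correspondence table as TSV
#'
#' @param corr a `CorrespondenceTable`.
#' @param path output TSV.
#' @export
write_correspondence <- function(corr, path) .write_tsv(corr$table, path)
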