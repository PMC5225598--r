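# RNA-binding residue detection and pocket labeling / size filtering.
#
# Interface residues are defined by a single atomic distance criterion: a
# protein residue is RNA-binding when any of its in-scope atoms lies within
# `cutoff` (inclusive) of any RNA atom. This distance union stands in for
# typed interaction classification (hydrogen bond / electrostatic /
# hydrophobic / van der Waals) and is the standard operational definition of
# an interface; the cutoff is configurable.

#' Contact detection parameters
#'
#' @param cutoff contact distance in Angstrom (default 5.0, inclusive).
#' @param atom_scope `"heavy"` (ignore hydrogens; deposited structures rarely
#'   contain them) or `"all"`.
#' @export
contact_params <- function(cutoff = 5.0, atom_scope = c("heavy", "all")) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  structure(list(cutoff = cutoff, atom_scope = match.arg(atom_scope)),
            class = "ContactParams")
}

.scope_atoms <- function(chain, scope) {
  at <- chain$atoms
  if (scope == "heavy") {
    elem <- toupper(trimws(at$elesy))
    noelem <- is.na(elem) | elem == ""
    if (any(noelem)) {
      # fall back to the first letter of the atom name
      nm <- gsub("[0-9' ]", "", at$elety[noelem])
      elem[noelem] <- toupper(substr(nm, 1, 1))
    }
    at <- at[elem != "H" & elem != "D", , drop = FALSE]
  }
  at
}

#' Detect RNA-binding residues of a protein chain
#'
#' @param protein a `ChainStructure` of polymer class protein.
#' @param rna list of `ChainStructure` objects (may be empty).
#' @param params a [contact_params()] object.
#' @return Data frame of residue keys (`chain_id`, `seq_num`, `icode`) of the
#'   protein residues with at least one in-scope atom within `cutoff` of any
#'   RNA atom. Empty RNA input yields an empty set.
#' @export
detect_binding_residues <- function(protein, rna, params = contact_params()) {
  stopifnot(inherits(protein, "ChainStructure"))
  if (inherits(rna, "ChainStructure")) rna <- list(rna)
  empty <- data.frame(chain_id = character(), seq_num = integer(),
                      icode = character(), stringsAsFactors = FALSE)
  if (length(rna) == 0) return(empty)
  pat <- .scope_atoms(protein, params$atom_scope)
  if (nrow(pat) == 0) return(empty)
  rxyz <- do.call(rbind, lapply(rna, function(ch) {
    at <- .scope_atoms(ch, params$atom_scope)
    keep <- .classify_residue(at$resid) == "rna"
    as.matrix(at[keep, c("x", "y", "z")])
  }))
  if (is.null(rxyz) || nrow(rxyz) == 0) return(empty)
  pxyz <- as.matrix(pat[, c("x", "y", "z")])
  # squared-distance scan, chunked over protein atoms to bound memory
  cut2 <- params$cutoff^2
  hit <- logical(nrow(pxyz))
  step <- 2000L
  for (s in seq(1L, nrow(pxyz), by = step)) {
    e <- min(s + step - 1L, nrow(pxyz))
    blk <- pxyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(rxyz^2), "+") -
      2 * tcrossprod(blk, rxyz)
    hit[s:e] <- apply(d2 <= cut2 + 1e-9, 1, any)
  }
  keys <- unique(data.frame(chain_id = pat$chain[hit],
                            seq_num = pat$resno[hit],
                            icode = pat$insert[hit],
                            stringsAsFactors = FALSE))
  rownames(keys) <- NULL
  keys[order(keys$chain_id, keys$seq_num, keys$icode), , drop = FALSE]
}

.key_strings <- function(keys) {
  paste(keys$chain_id, keys$seq_num, keys$icode, sep = "\r")
}

#' Label pockets with RNA-binding flags
#'
#' Sets the per-residue `binding` flag from a set of binding residue keys and
#' marks a pocket as RNA-binding when it contains at least one flagged
#' residue.
#'
#' @param pockets list of `PocketStructure`.
#' @param binding data frame of residue keys as returned by
#'   [detect_binding_residues()].
#' @return The pockets, with `binding` flags set and an `is_rna_binding`
#'   attribute on each.
#' @export
label_pockets <- function(pockets, binding) {
  bset <- if (nrow(binding) > 0) .key_strings(binding) else character()
  lapply(pockets, function(p) {
    p$binding <- .key_strings(p$keys) %in% bset
    attr(p, "is_rna_binding") <- any(p$binding)
    p
  })
}

#' Filter pockets by RNA-binding status and size
#'
#' Retains pockets that are RNA-binding (at least one flagged residue) and
#' contain at least `min_residues` residues; very tiny pockets with fewer
#' residues are removed.
#'
#' @param pockets labeled pockets (see [label_pockets()]).
#' @param min_residues minimum residue count (default 4).
#' @export
filter_pockets <- function(pockets, min_residues = 4) {
  keep <- vapply(pockets, function(p) {
    isTRUE(attr(p, "is_rna_binding")) && nrow(p$xyz) >= min_residues
  }, logical(1))
  pockets[keep]
}

#' Write a pocket summary table
#'
#' TSV with one row per pocket: id, residue counts and RNA-binding status.
#'
#' @param pockets labeled pockets.
#' @param path output file.
#' @export
write_pocket_table <- function(pockets, path) {
  df <- do.call(rbind, lapply(pockets, function(p) {
    data.frame(pocket_id = p$pocket_id, n_residues = nrow(p$xyz),
               n_binding = sum(p$binding),
               is_rna_binding = isTRUE(attr(p, "is_rna_binding")),
               stringsAsFactors = FALSE)
  }))
  .write_tsv(df, path)
}
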