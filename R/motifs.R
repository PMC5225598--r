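# Motif summaries of a pocket group: per-column residue frequencies,
# occupancy and RNA-binding ratios from the consensus alignment, plus
# hypergeometric / EASE term enrichment of the parent proteins.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a motif profile from a consensus alignment
#'
#' Per consensus column: relative amino-acid frequencies over the assigned
#' residues (unknown residues `X` excluded from frequencies), the occupancy
#' (fraction of pockets with a residue assigned) and the binding ratio
#' (fraction of assigned residues flagged RNA-binding).
#'
#' @param cons a `ConsensusAlignment`.
#' @param pockets named list of the group's `PocketStructure` objects, in
#'   the order of the consensus' pairwise set ids.
#' @param ids pocket ids matching `cons$assign`.
#' @return A `MotifProfile`: `n_columns`, `frequencies` (n_columns x 20
#'   matrix), `occupancy`, `binding_ratio` (NA for columns with no assigned
#'   residues).
#' @export
build_profile <- function(cons, pockets, ids = names(pockets)) {
  N <- cons$n_columns
  M <- length(ids)
  freq <- matrix(0, N, 20, dimnames = list(NULL, .AA20))
  occ <- numeric(N)
  bind_n <- numeric(N); bind_tot <- numeric(N)
  if (N == 0)
    return(structure(list(n_columns = 0L, frequencies = freq,
                          occupancy = occ, binding_ratio = numeric(0)),
                     class = "MotifProfile"))
  for (i in seq_len(M)) {
    p <- pockets[[ids[i]]]
    x <- cons$assign[[i]]
    k <- which(!is.na(x))
    for (kk in k) {
      cc <- x[kk]
      occ[cc] <- occ[cc] + 1
      bind_tot[cc] <- bind_tot[cc] + 1
      if (p$binding[kk]) bind_n[cc] <- bind_n[cc] + 1
      if (p$aa[kk] %in% .AA20) freq[cc, p$aa[kk]] <- freq[cc, p$aa[kk]] + 1
    }
  }
  tot <- rowSums(freq)
  freq <- sweep(freq, 1, pmax(tot, 1), "/")
  structure(list(n_columns = N, frequencies = freq, occupancy = occ / M,
                 binding_ratio = ifelse(bind_tot > 0, bind_n / bind_tot,
                                        NA_real_)),
            class = "MotifProfile")
}

#' @export
print.MotifProfile <- function(x, ...) {
  top <- if (x$n_columns > 0)
    apply(x$frequencies, 1, function(f)
      if (all(f == 0)) "-" else names(which.max(f)))
  else character(0)
  cat(sprintf("MotifProfile: %d columns, consensus %s\n", x$n_columns,
              paste(top, collapse = "")))
  invisible(x)
}

#' Column-ordered pocket sequences
#'
#' One record per pocket: its residues in consensus column order, `-` for
#' unassigned columns, each letter annotated with the original residue
#' position in the parent chain.
#'
#' @inheritParams build_profile
#' @return Data frame with `pocket_id`, `sequence` (gapped string), and
#'   `positions` (comma-separated `chain/seqnum/icode`, `-` for gaps).
#' @export
concatenated_sequences <- function(cons, pockets, ids = names(pockets)) {
  N <- cons$n_columns
  rows <- lapply(seq_along(ids), function(i) {
    p <- pockets[[ids[i]]]
    x <- cons$assign[[i]]
    letters <- rep("-", N)
    poss <- rep("-", N)
    k <- which(!is.na(x))
    letters[x[k]] <- p$aa[k]
    poss[x[k]] <- sprintf("%s/%d%s", p$keys$chain_id[k], p$keys$seq_num[k],
                          p$keys$icode[k])
    data.frame(pocket_id = ids[i], sequence = paste(letters, collapse = ""),
               positions = paste(poss, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Term enrichment of a protein group
#'
#' One-tailed upper hypergeometric probability of observing at least `count`
#' annotated proteins in the group, per term. The `ease` mode subtracts one
#' success before taking the tail (the conservative convention of DAVID's
#' EASE score). No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param group_proteins ids of the group's proteins (subset of
#'   `population`).
#' @param population ids of the background protein set.
#' @param annotations data frame with columns `protein_id`, `term` (optional
#'   `description`); proteins absent from it count as unannotated.
#' @param mode `"hypergeometric"` or `"ease"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame (term, count, list_total, pop_hits, pop_total, p),
#'   sorted by p ascending.
#' @export
enrich_terms <- function(group_proteins, population, annotations,
                         mode = c("hypergeometric", "ease"),
                         adjust = c("none", "BH")) {
  mode <- match.arg(mode); adjust <- match.arg(adjust)
  if (length(group_proteins) == 0) stop("empty group")
  if (!all(group_proteins %in% population))
    stop("group must be a subset of the population")
  ann <- annotations[annotations$protein_id %in% population, , drop = FALSE]
  ann <- unique(ann[, c("protein_id", "term")])
  terms <- unique(ann$term)
  n_pop <- length(unique(population))
  n_list <- length(unique(group_proteins))
  rows <- lapply(terms, function(tm) {
    hits <- unique(ann$protein_id[ann$term == tm])
    count <- sum(group_proteins %in% hits)
    if (count == 0) return(NULL)
    k <- if (mode == "ease") count - 1L else count
    # P(X >= k) for X ~ Hypergeom(pop_hits, pop_total - pop_hits, list_total)
    p <- if (k <= 0) 1.0 else
      phyper(k - 1, length(hits), n_pop - length(hits), n_list,
             lower.tail = FALSE)
    data.frame(term = tm, count = count, list_total = n_list,
               pop_hits = length(hits), pop_total = n_pop, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), count = integer(),
                      list_total = integer(), pop_hits = integer(),
                      pop_total = integer(), p = numeric()))
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write column-ordered pocket sequences as FASTA
#'
#' FASTA-like export of the gapped, column-ordered one-letter sequences from
#' [concatenated_sequences()]; the usual input format for logo tools.
#'
#' @param recs data frame from [concatenated_sequences()].
#' @param path output file.
#' @export
write_sequences_fasta <- function(recs, path) {
  writeLines(as.vector(rbind(paste0(">", recs$pocket_id), recs$sequence)),
             path)
  invisible(path)
}

#' Write a motif profile as TSV
#'
#' Columns: `column`, `occupancy`, `binding_ratio`, then the 20 amino-acid
#' frequencies.
#'
#' @param profile a `MotifProfile`.
#' @param path output TSV.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(column = seq_len(profile$n_columns),
                   occupancy = profile$occupancy,
                   binding_ratio = profile$binding_ratio)
  df <- cbind(df, as.data.frame(profile$frequencies))
  .write_tsv(df, path)
}
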