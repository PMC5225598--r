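# Fixtures built in code: tiny PDB texts, point-cloud pockets, graphs.

# fixed-column PDB ATOM line
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     record = "ATOM", elem = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resid, chain, resno, x, y, z, 1.0, 0.0, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 3-residue protein chain
mini_protein_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_mini_pdb(c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.5, 0.0, 0.0),
    pdb_line(3, " CA ", "GLY", "A", 2, 4.2, 1.0, 0.5),
    pdb_line(4, " CA ", "LEU", "A", 3, 7.0, 2.0, 1.5)
  ), path)
}

# random point-cloud pocket (no separation constraint; for aligner stress)
random_cloud_pocket <- function(n, seed, id = sprintf("R%d:1:A", seed),
                                scale = 6) {
  set.seed(seed)
  new_pocket(id, matrix(runif(3 * n, -scale, scale), ncol = 3),
             sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                    replace = TRUE))
}

rigid_copy <- function(pocket, seed, id = paste0(pocket$pocket_id, "c"),
                       sigma = 0, permute = TRUE) {
  set.seed(seed)
  n <- nrow(pocket$xyz)
  idx <- if (permute) sample(n) else seq_len(n)
  R <- pocketmotif:::.rand_rotation()
  xyz <- (pocket$xyz[idx, , drop = FALSE] +
            matrix(rnorm(3 * n, sd = sigma), ncol = 3)) %*% t(R)
  xyz <- sweep(xyz, 2, runif(3, -30, 30), "+")
  p <- new_pocket(id, xyz, pocket$aa[idx])
  attr(p, "perm") <- idx
  p
}

edge_df <- function(a, b) data.frame(node_a = a, node_b = b,
                                     q = rep(NA_real_, length(a)),
                                     p = rep(NA_real_, length(a)),
                                     stringsAsFactors = FALSE)

clique_edges <- function(v) {
  do.call(rbind, combn(v, 2, function(x) edge_df(x[1], x[2]),
                       simplify = FALSE))
}

# self-avoiding random walk "fold": consecutive CA step 3.8 A, any pair
# >= 3.5 A, by rejection
random_walk_chain <- function(n, seed, id = sprintf("W%d:A", seed)) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- 0
  for (i in 2:n) {
    for (try in 1:200) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pts[i - 1, ] + 3.8 * u
      prev <- pts[seq_len(i - 1), , drop = FALSE]
      if (all(colSums((t(prev) - cand)^2) >= 3.5^2)) {
        pts[i, ] <- cand
        break
      }
    }
    if (any(is.na(pts[i, ]))) return(random_walk_chain(n, seed + 1000, id))
  }
  new_pocket(id, pts, rep("A", n))
}
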