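# Synthetic fixtures with ground truth: pocket families (noisy rigid copies
# of templates with permuted residue order — exactly what a non-sequential
# aligner must undo), background pockets, toy protein-RNA complexes with
# planted contacts, and planted-partition graphs. All generators are pure
# functions of their seeds.

.rand_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

#' Family generation specification
#'
#' Default values define the reference synthetic study conditions: pockets of
#' about 10 residues (the typical surface-pocket size), six structural
#' families of 15 members each under 0.3 Angstrom coordinate noise with
#' permuted residue order, plus 30 unrelated background pockets.
#'
#' @param n_templates number of template pockets (families).
#' @param members_per_template noisy copies per template.
#' @param n_residues residues per pocket (>= 4).
#' @param noise_sigma iid Gaussian coordinate noise, Angstrom.
#' @param permute randomly permute residue order of each member.
#' @param n_background unrelated background pockets mixed into the set.
#' @param deletion_rate per-residue deletion probability in members
#'   (default 0; exercises partial alignments).
#' @param seed RNG seed.
#' @export
family_spec <- function(n_templates = 6, members_per_template = 15,
                        n_residues = 10, noise_sigma = 0.3, permute = TRUE,
                        n_background = 30, deletion_rate = 0, seed = 1) {
  stopifnot(n_templates >= 0, members_per_template >= 0, n_residues >= 4,
            noise_sigma >= 0, deletion_rate >= 0, deletion_rate < 1)
  structure(list(n_templates = n_templates,
                 members_per_template = members_per_template,
                 n_residues = n_residues, noise_sigma = noise_sigma,
                 permute = permute, n_background = n_background,
                 deletion_rate = deletion_rate, seed = seed),
            class = "FamilySpec")
}

#' Generate a template pocket
#'
#' Residue points are rejection-sampled uniformly in a sphere under a
#' minimum pairwise separation of 3.5 Angstrom (the CA-CA packing limit);
#' amino-acid letters are uniform random. Deterministic per seed.
#'
#' @param n_residues number of residues (>= 4).
#' @param seed RNG seed.
#' @param pocket_id id of the generated pocket.
#' @export
make_template_pocket <- function(n_residues, seed,
                                 pocket_id = sprintf("T%d:1:A", seed)) {
  if (n_residues < 4) stop("a pocket needs at least 4 residues")
  set.seed(seed)
  radius <- 3.5 * max(1.9, n_residues^(1/3))
  min_sep2 <- 3.5^2
  for (attempt in 1:50) {
    pts <- matrix(NA_real_, n_residues, 3)
    ok <- TRUE
    for (i in seq_len(n_residues)) {
      placed <- FALSE
      for (try in 1:500) {
        p <- runif(3, -radius, radius)
        if (sum(p^2) > radius^2) next
        if (i == 1 || all(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) -
                                     p)^2) >= min_sep2)) {
          pts[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      aa <- sample(.AA20, n_residues, replace = TRUE)
      return(new_pocket(pocket_id, pts, aa))
    }
  }
  stop("could not satisfy the 3.5 A separation constraint; ",
       "reduce n_residues")
}

#' Generate a family of noisy rigid copies of a template
#'
#' Each member is the template plus iid Gaussian coordinate noise, a uniform
#' random rotation and translation, optional residue deletions, and (when
#' `permute`) a random residue-order permutation. The ground-truth
#' correspondence is kept as `attr(member, "template_index")`: entry i gives
#' the template residue that member residue i came from.
#'
#' @param template a `PocketStructure`.
#' @param n_members number of members.
#' @param noise_sigma Gaussian noise sd per coordinate, Angstrom.
#' @param permute permute residue order.
#' @param seed RNG seed.
#' @param deletion_rate per-residue deletion probability.
#' @param id_prefix member ids become `<id_prefix>:<k>:A`.
#' @export
make_family <- function(template, n_members, noise_sigma, permute, seed,
                        deletion_rate = 0, id_prefix = "F") {
  set.seed(seed)
  n <- nrow(template$xyz)
  lapply(seq_len(n_members), function(k) {
    keep <- if (deletion_rate > 0)
      which(runif(n) >= deletion_rate) else seq_len(n)
    if (length(keep) < 4) keep <- sort(sample.int(n, 4))
    idx <- if (permute) sample(keep) else keep
    xyz <- template$xyz[idx, , drop = FALSE] +
      matrix(rnorm(3 * length(idx), sd = noise_sigma), ncol = 3)
    R <- .rand_rotation()
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, runif(3, -50, 50), "+")
    p <- new_pocket(sprintf("%s:%d:A", id_prefix, k), xyz, template$aa[idx])
    attr(p, "template_index") <- idx
    attr(p, "template_id") <- template$pocket_id
    p
  })
}

#' Generate unrelated background pockets
#'
#' Independent template draws; used as the calibration background and as
#' noise pockets in end-to-end runs.
#'
#' @param n number of pockets.
#' @param n_residues residues per pocket.
#' @param seed RNG seed.
#' @param id_prefix pocket ids become `<id_prefix><k>:1:A`.
#' @export
make_background <- function(n, n_residues = 10, seed = 1, id_prefix = "BG") {
  lapply(seq_len(n), function(k)
    make_template_pocket(n_residues, seed = seed * 100003L + k,
                         pocket_id = sprintf("%s%03d:1:A", id_prefix, k)))
}

#' Generate the full synthetic pocket study set
#'
#' Templates, their families, and background pockets per a [family_spec()];
#' returns pockets together with the ground-truth family labels (background
#' pockets are labeled 0).
#'
#' Templates are drawn under a mutual-dissimilarity constraint: a candidate
#' is rejected (and redrawn deterministically) when its non-sequential
#' alignment Q-score against any accepted template exceeds
#' `max_template_q`. Without this the planted labels are not ground truth:
#' two independently drawn templates can be near-identical up to rotation
#' and residue relabeling, in which case their families form one structural
#' group, not two.
#'
#' @param spec a [family_spec()].
#' @param max_template_q maximum allowed pairwise template Q-score. The
#'   default 0.6 sits at the typical (median) background Q of unrelated
#'   10-residue pockets under the default alignment parameters — i.e.
#'   planted families are mutually no more similar than unrelated pockets —
#'   and far below the within-family similarity of about 0.95 at the default
#'   noise level. (The alpha = 0.05 significance cutoff of the calibrated
#'   null lies near 0.69, so templates merely below that boundary would
#'   still leak cross-family edges.)
#' @return List with `pockets` (named list of `PocketStructure`), `labels`
#'   (named integer vector, 0 = background), and `templates`.
#' @export
make_family_set <- function(spec = family_spec(), max_template_q = 0.6) {
  pockets <- list(); labels <- integer(0); templates <- list()
  apar <- alignment_params()
  for (t in seq_len(spec$n_templates)) {
    tmpl <- NULL
    for (attempt in 0:50) {
      cand <- make_template_pocket(
        spec$n_residues,
        seed = spec$seed * 1000L + t + 100000L * attempt,
        pocket_id = sprintf("TPL%d:1:A", t))
      distinct <- all(vapply(templates, function(prev)
        .align_xyz(prev$xyz, cand$xyz, apar)$q <= max_template_q,
        logical(1)))
      if (distinct) { tmpl <- cand; break }
    }
    if (is.null(tmpl))
      stop("could not draw ", spec$n_templates, " mutually dissimilar ",
           "templates; lower n_templates or raise max_template_q")
    templates[[t]] <- tmpl
    fam <- make_family(tmpl, spec$members_per_template, spec$noise_sigma,
                       spec$permute, seed = spec$seed * 1000L + 500L + t,
                       deletion_rate = spec$deletion_rate,
                       id_prefix = sprintf("FAM%d", t))
    for (p in fam) {
      pockets[[p$pocket_id]] <- p
      labels[p$pocket_id] <- t
    }
  }
  bg <- make_background(spec$n_background, spec$n_residues,
                        seed = spec$seed + 777L)
  for (p in bg) {
    pockets[[p$pocket_id]] <- p
    labels[p$pocket_id] <- 0L
  }
  list(pockets = pockets, labels = labels, templates = templates)
}

#' Generate a toy protein-RNA complex with planted contacts
#'
#' Protein CA atoms sit on a widely spaced grid; each planted contact gets
#' one RNA phosphate at distance `cutoff - gap` from its CA, and all other
#' protein-RNA atom distances exceed `cutoff + gap` by construction. The
#' complex is written as a two-chain PDB file and read back through
#' [read_structure()], so the returned chains exercise the full IO path.
#'
#' @param n_protein_res protein residues.
#' @param n_rna_res RNA residues (>= planted_contacts).
#' @param planted_contacts number of protein residues with a planted
#'   contact.
#' @param cutoff contact cutoff the complex is built around (default 5.0).
#' @param gap margin in Angstrom separating planted from non-planted
#'   distances.
#' @param seed RNG seed (chooses which residues are planted).
#' @param path PDB output path (default: a temp file).
#' @return List with `protein` / `rna` (`ChainStructure`), `truth` (keys of
#'   the planted residues), `path`.
#' @export
make_complex <- function(n_protein_res, n_rna_res, planted_contacts,
                         cutoff = 5.0, gap = 1.0, seed = 1,
                         path = tempfile(fileext = ".pdb")) {
  stopifnot(planted_contacts <= n_protein_res, planted_contacts <= n_rna_res,
            gap > 0, gap < cutoff)
  set.seed(seed)
  spacing <- 4 * (cutoff + gap)
  prot_xyz <- cbind(spacing * seq_len(n_protein_res), 0, 0)
  planted <- sort(sample.int(n_protein_res, planted_contacts))
  rna_xyz <- matrix(NA_real_, n_rna_res, 3)
  if (planted_contacts > 0)
    rna_xyz[seq_len(planted_contacts), ] <-
      prot_xyz[planted, , drop = FALSE] +
      matrix(rep(c(0, 0, cutoff - gap), each = planted_contacts), ncol = 3)
  if (n_rna_res > planted_contacts) {
    far <- (planted_contacts + 1):n_rna_res
    rna_xyz[far, ] <- cbind(spacing * far, 0, 1000)
  }
  aa3 <- sample(.STD_AA3, n_protein_res, replace = TRUE)
  nt <- sample(c("A", "C", "G", "U"), n_rna_res, replace = TRUE)
  xyz <- rbind(prot_xyz, rna_xyz)
  n_all <- n_protein_res + n_rna_res
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(xyz)),
    type = rep("ATOM", n_all),
    resno = c(seq_len(n_protein_res), seq_len(n_rna_res)),
    resid = c(aa3, nt),
    eleno = seq_len(n_all),
    elety = c(rep("CA", n_protein_res), rep("P", n_rna_res)),
    chain = c(rep("A", n_protein_res), rep("B", n_rna_res)),
    o = rep(1, n_all), b = rep(0, n_all),
    elesy = c(rep("C", n_protein_res), rep("P", n_rna_res)))
  chains <- read_structure(path, format = "pdb")
  truth <- data.frame(chain_id = rep("A", length(planted)),
                      seq_num = planted,
                      icode = rep("", length(planted)),
                      stringsAsFactors = FALSE)
  list(protein = chains[["A"]], rna = chains[["B"]], truth = truth,
       path = path)
}

#' Write a pocket as a CA-only PDB file
#'
#' Lets synthetic pockets flow through the same file-based path as real
#' ones.
#'
#' @param pocket a `PocketStructure`.
#' @param path output PDB.
#' @export
write_pocket_pdb <- function(pocket, path) {
  n <- nrow(pocket$xyz)
  inv <- setNames(.STD_AA3, .aa_one(.STD_AA3))
  aa3 <- unname(inv[pocket$aa])
  aa3[is.na(aa3)] <- "UNK"
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(pocket$xyz)),
    type = rep("ATOM", n), resno = pocket$keys$seq_num, resid = aa3,
    eleno = seq_len(n), elety = rep("CA", n),
    chain = pocket$keys$chain_id, o = rep(1, n), b = rep(0, n),
    elesy = rep("C", n))
  invisible(path)
}

#' Generate a planted-partition similarity network
#'
#' Independent edges with within-group probability `p_in` and between-group
#' probability `p_out`; ground-truth labels kept as `attr(, "labels")`.
#'
#' @param k_groups number of groups.
#' @param group_size nodes per group.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @export
make_planted_partition <- function(k_groups, group_size, p_in, p_out, seed) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  set.seed(seed)
  n <- k_groups * group_size
  nodes <- sprintf("n%03d", seq_len(n))
  labels <- setNames(rep(seq_len(k_groups), each = group_size), nodes)
  pairs <- combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  keep <- runif(ncol(pairs)) < prob
  edges <- data.frame(node_a = nodes[pairs[1, keep]],
                      node_b = nodes[pairs[2, keep]],
                      q = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  net <- new_network(nodes, edges)
  attr(net, "labels") <- labels
  net
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical, ~0 = random.
#'
#' @param a,b label vectors over the same items (matched by name when both
#'   are named).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
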