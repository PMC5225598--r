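# Full-pipeline orchestration: extract -> align -> calibrate -> network ->
# cluster -> consensus -> motif, writing every intermediate table plus a
# machine-readable manifest. Every stochastic step draws its seed from the
# config; there is no hidden global randomness.

#' Pipeline configuration
#'
#' Flat key-value configuration with the package defaults; unknown keys are
#' rejected.
#'
#' @param ... overrides for: `cutoff` (contact distance, A), `min_residues`
#'   (pocket size filter), `r0`, `d_max`, `n_rotation_seeds`, `max_iter`,
#'   `tol` (alignment), `n_pairs` (calibration background pairs), `alpha`
#'   (significance threshold), `min_size` (major-group size), `max_rounds`
#'   (consensus refinement), `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(cutoff = 5.0, min_residues = 4L, r0 = 3.0, d_max = 5.0,
              n_rotation_seeds = 24L, max_iter = 50L, tol = 1e-6,
              n_pairs = 20000L, alpha = 0.05, min_size = 5L,
              max_rounds = 10L, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Extract labeled RNA-binding pockets from a complex
#'
#' Convenience wrapper for the file-based path: parse the structure, detect
#' binding residues against all RNA chains, resolve the pocket definitions,
#' label and filter.
#'
#' @param pdb_path coordinate file.
#' @param pockets_path pocket definition file (TSV dialect).
#' @param config a [pipeline_config()].
#' @return Named list of labeled, filtered `PocketStructure`.
#' @export
extract_pockets <- function(pdb_path, pockets_path,
                            config = pipeline_config()) {
  chains <- read_structure(pdb_path)
  defs <- read_pocket_definitions(pockets_path, dialect = "tsv")
  classes <- vapply(chains, function(c) c$polymer_class, character(1))
  rna <- chains[classes == "rna"]
  prot <- chains[classes %in% c("protein", "mixed")]
  binding <- do.call(rbind, lapply(prot, detect_binding_residues, rna = rna,
                                   params = contact_params(config$cutoff)))
  if (is.null(binding))
    binding <- data.frame(chain_id = character(), seq_num = integer(),
                          icode = character())
  pockets <- lapply(defs, resolve_pocket, chains = chains)
  pockets <- label_pockets(pockets, binding)
  filter_pockets(pockets, config$min_residues)
}

#' Run the full classification pipeline
#'
#' Executes align -> calibrate -> network -> cluster -> consensus -> motif
#' on a set of labeled pockets, writing every intermediate table into
#' `out_dir` together with a manifest (package version, resolved config,
#' file checksums). A stage error aborts with the stage name; partial
#' outputs are retained.
#'
#' @param pockets named list of labeled `PocketStructure` (the analysis
#'   set).
#' @param background list of `PocketStructure` used to calibrate the null;
#'   required.
#' @param out_dir run directory (created).
#' @param config a [pipeline_config()].
#' @param progress alignment progress logging interval (0 = silent).
#' @return Invisibly, a list with the run artifacts (`ava`, `model`, `net`,
#'   `partition`, `groups`, `consensus`, `profiles`, `out_dir`).
#' @export
run_pipeline <- function(pockets, background, out_dir,
                         config = pipeline_config(), progress = 0) {
  if (missing(background) || is.null(background))
    stop("no calibration background: supply 'background' ",
         "(a list of pockets; see make_background())")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  apar <- alignment_params(r0 = config$r0, d_max = config$d_max,
                           n_rotation_seeds = config$n_rotation_seeds,
                           max_iter = config$max_iter, tol = config$tol)

  .stage("extract", write_pocket_table(pockets,
                                       file.path(out_dir, "pockets.tsv")))

  ava <- .stage("align", all_vs_all(pockets, apar, progress = progress))
  write_alignment_table(ava, file.path(out_dir, "align.tsv"))

  model <- .stage("calibrate",
                  calibrate_background(background, n_pairs = config$n_pairs,
                                       seed = config$seed, params = apar,
                                       progress = progress))
  write_calibration(model, file.path(out_dir, "evd.json"))

  net <- .stage("network", build_network(ava, model, alpha = config$alpha))
  write_network(net, file.path(out_dir, "network.tsv"),
                sif = file.path(out_dir, "network.sif"))

  part <- .stage("cluster", detect_communities(net))
  groups <- extract_groups(part, net, min_size = config$min_size)
  write_groups(groups, file.path(out_dir, "groups.tsv"))

  consensus <- list(); profiles <- list()
  for (g in groups) {
    if (!g$is_major) next
    pa <- .stage("consensus", pairwise_set(ava, g$members))
    cons <- .stage("consensus",
                   build_consensus(g$members, pa,
                                   max_rounds = config$max_rounds))
    consensus[[as.character(g$group_id)]] <- cons
    write_consensus(cons, pa, pockets,
                    file.path(out_dir,
                              sprintf("consensus_group%d.tsv", g$group_id)))
    prof <- .stage("motif", build_profile(cons, pockets, ids = pa$ids))
    profiles[[as.character(g$group_id)]] <- prof
    write_profile(prof,
                  file.path(out_dir, sprintf("profile_group%d.tsv",
                                             g$group_id)))
    recs <- concatenated_sequences(cons, pockets, ids = pa$ids)
    .write_tsv(recs, file.path(out_dir, sprintf("sequences_group%d.tsv",
                                                g$group_id)))
    write_sequences_fasta(recs,
                          file.path(out_dir,
                                    sprintf("sequences_group%d.fasta",
                                            g$group_id)))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "pocketmotif",
    version = as.character(utils::packageVersion("pocketmotif")),
    config = unclass(config),
    n_pockets = length(pockets), n_background = length(background),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(ava = ava, model = model, net = net, partition = part,
                 groups = groups, consensus = consensus,
                 profiles = profiles, out_dir = out_dir))
}
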