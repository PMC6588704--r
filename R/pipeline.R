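# End-to-end orchestration: scan -> null test -> (optional ancestral codons,
# energy sweeps), with a JSON run manifest. A single global seed fans out to
# per-stage seeds by fixed offsets so stages are reproducible independently.

#' Run the convergence pipeline on a set of gene alignments
#'
#' Stages run in order: per-site scan over all genes, neutral-expectation
#' confirmation of candidate genes, optional focal-codon ancestral
#' reconstruction, optional kinetic-model sweeps. Each stage writes a TSV
#' into `out_dir` (`candidates.tsv`, `confirmed.tsv`, `calls.tsv`,
#' `sweep.tsv`) plus a JSON `manifest.json` recording the seed, parameters
#' and per-stage counts. Re-running with the same inputs reproduces all
#' outputs.
#'
#' @param alignments Named list of `labeled_alignment` objects (or a
#'   directory of FASTA files, read with `labels`).
#' @param tree Rooted `ape::phylo` or Newick path.
#' @param labels `species_groups` table or TSV path.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param scan List of [scan_genes()] settings (`min_shared`, `alpha`).
#' @param nulltest List of [confirm_candidates()] settings (`alpha`,
#'   `gamma_shape`, `n_cat`, `model`, `optimize_scale`).
#' @param ancestral Optional list: `gene_atgl`, `start_atgl`, `gene_acot7`,
#'   `start_acot7`, `model` (nucleotide `subst_model`) for a
#'   [robustness_report()] on the supplied tree.
#' @param energy Optional list of [sweep_activity()] settings: `params`,
#'   `name`, `grid`, `criterion`.
#' @return List with elements `candidates`, `confirmed`, `calls`, `sweep`,
#'   `manifest` (also written to disk).
#' @export
run_pipeline <- function(alignments, tree, labels, out_dir,
                         seed = 1L,
                         scan = list(), nulltest = list(),
                         ancestral = NULL, energy = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(labels)) labels <- read_group_labels(labels)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(alignments)) {
    paths <- list.files(alignments, pattern = "\\.(fa|fasta|fna|faa)$",
                        full.names = TRUE)
    alignments <- lapply(paths, read_alignment, labels = labels)
    names(alignments) <- vapply(alignments, `[[`, character(1), "gene_id")
  }
  if (length(alignments) == 0) {
    abort("scan stage: no alignments supplied", class = "convflight_stage_error")
  }
  scan_args <- modifyList(list(min_shared = 7L, alpha = 1e-3), scan)
  null_args <- modifyList(list(alpha = 0.01, gamma_shape = 1, n_cat = 4L,
                               model = NULL, optimize_scale = FALSE), nulltest)
  set.seed(seed + 1L)
  candidates <- scan_genes(alignments, min_shared = scan_args$min_shared,
                           alpha = scan_args$alpha)
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  confirmed_tbl <- tibble(gene_id = character(), observed = integer(),
                          expected = numeric(), p_poisson = numeric(),
                          pairs = integer(), retained = logical())
  if (nrow(candidates) > 0) {
    set.seed(seed + 2L)
    conf <- confirm_candidates(candidates, alignments, tree,
                               model = null_args$model,
                               alpha = null_args$alpha,
                               gamma_shape = null_args$gamma_shape,
                               n_cat = null_args$n_cat,
                               optimize_scale = null_args$optimize_scale)
    confirmed_tbl <- tidy(conf)
  }
  utils::write.table(confirmed_tbl, file.path(out_dir, "confirmed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  calls_tbl <- NULL
  if (!is.null(ancestral)) {
    set.seed(seed + 3L)
    rep <- robustness_report(
      alignments[[ancestral$gene_atgl]], ancestral$start_atgl,
      alignments[[ancestral$gene_acot7]], ancestral$start_acot7,
      trees = list(tree), model = ancestral$model)
    calls_tbl <- tidy(rep)
    utils::write.table(calls_tbl, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sweep_tbl <- NULL
  if (!is.null(energy)) {
    sw <- sweep_activity(energy$params, name = energy$name,
                         grid = energy$grid,
                         criterion = energy$criterion %||% "energy")
    sweep_tbl <- as_tibble(sw)
    sweep_tbl$threshold <- attr(sw, "threshold")
    utils::write.table(sweep_tbl, file.path(out_dir, "sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "convflight",
    version = as.character(utils::packageVersion("convflight")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameters = list(scan = scan_args,
                      nulltest = null_args[c("alpha", "gamma_shape", "n_cat")]),
    counts = list(genes = length(alignments),
                  candidates = nrow(candidates),
                  candidate_genes = length(unique(candidates$gene_id)),
                  confirmed = sum(confirmed_tbl$retained)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(candidates = candidates, confirmed = confirmed_tbl,
       calls = calls_tbl, sweep = sweep_tbl, manifest = manifest)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML mirrors [run_pipeline()]'s arguments with file paths:
#' `aln_dir`, `tree`, `labels`, `out_dir`, `seed`, and optional `scan` /
#' `nulltest` blocks.
#'
#' @param path YAML configuration file.
#' @return See [run_pipeline()].
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in c("aln_dir", "tree", "labels")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      abort(paste0("config path missing or nonexistent: ", p))
    }
  }
  run_pipeline(cfg$aln_dir, cfg$tree, cfg$labels,
               out_dir = cfg$out_dir %||% "pipeline_out",
               seed = cfg$seed %||% 1L,
               scan = cfg$scan %||% list(),
               nulltest = cfg$nulltest %||% list())
}
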