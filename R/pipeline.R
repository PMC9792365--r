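#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's options.  Exactly one data source must be given:
#' either a [synthetic_config()] or paths to an abundance TSV plus an
#' annotation TSV.  Enrichment runs only when a GMT source is supplied; a
#' missing GMT file fails here, before any computation.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param abundance_path,annotation_path TSV inputs (see [read_abundance()]),
#'   or `NULL` when simulating.
#' @param gmt Path to a GMT file or a `gene_set_collection`; `NULL` disables
#'   enrichment.
#' @param zscore_by Z-score axis for [log2_zscore()].
#' @param protect_group Protect the case/control contrast in [combat_adjust()].
#' @param sam Named list of overrides for [sam()] (`s0`, `n_permutations`,
#'   `q_threshold`, `var_equal`).
#' @param bootauc Named list of overrides for [diff_auc()] (`B`,
#'   `n_permutations`, `q_threshold`, `stratified`).
#' @param ora_method Enrichment p-value variant, `"fisher"` or `"ease"`.
#' @param seed Global seed; every stochastic stage derives its stream from it.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, abundance_path = NULL,
                       annotation_path = NULL, gmt = NULL,
                       zscore_by = "sample", protect_group = FALSE,
                       sam = list(), bootauc = list(),
                       ora_method = "fisher", seed = 1L) {
  has_files <- !is.null(abundance_path) || !is.null(annotation_path)
  if (is.null(synthetic) == !has_files) {
    tmt_error("tmtdiff_config_error",
              "Exactly one of a synthetic config or input file paths must be given.")
  }
  if (has_files) {
    for (p in c(abundance_path, annotation_path)) {
      if (is.null(p) || !file.exists(p)) {
        tmt_error("tmtdiff_config_error",
                  sprintf("Input file not found: %s", p %||% "<missing path>"))
      }
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  if (is.character(gmt) && !file.exists(gmt)) {
    tmt_error("tmtdiff_config_error", sprintf("GMT file not found: %s", gmt))
  }
  sam_cfg <- utils::modifyList(
    list(s0 = 0.1, n_permutations = 250, q_threshold = 0.05, var_equal = TRUE), sam)
  boot_cfg <- utils::modifyList(
    list(B = 1000, n_permutations = 20, q_threshold = 0.05, stratified = TRUE), bootauc)
  structure(list(synthetic = synthetic, abundance_path = abundance_path,
                 annotation_path = annotation_path, gmt = gmt,
                 zscore_by = zscore_by, protect_group = protect_group,
                 sam = sam_cfg, bootauc = boot_cfg, ora_method = ora_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Proteins called differential by both selection methods
#'
#' Intersects the SAM and bootstrap-AUC significant sets over a shared
#' protein universe and annotates each common protein's direction (up/down in
#' cases by the sign of the SAM mean difference).  Set sizes are attached as
#' `attr(., "counts")`.
#'
#' @param sam_rows A `sam_result` from [sam()].
#' @param bootauc_rows A `bootauc_result` after [bootauc_q()].
#' @return Tibble: `protein`, `mean_diff`, `direction`, `q_sam`, `q_auc`.
#' @export
intersect_selections <- function(sam_rows, bootauc_rows) {
  if (!setequal(sam_rows$protein, bootauc_rows$protein)) {
    tmt_error("tmtdiff_input_error",
              "The two result tables cover different protein universes.")
  }
  common <- intersect(sam_rows$protein[sam_rows$significant],
                      bootauc_rows$protein[bootauc_rows$significant])
  s <- sam_rows[match(common, sam_rows$protein), ]
  b <- bootauc_rows[match(common, bootauc_rows$protein), ]
  out <- tibble(protein = common, mean_diff = s$mean_diff,
                direction = ifelse(s$mean_diff >= 0, "up", "down"),
                q_sam = s$q, q_auc = b$q)
  attr(out, "counts") <- list(n_sam = sum(sam_rows$significant),
                              n_auc = sum(bootauc_rows$significant),
                              n_common = nrow(out))
  out
}

#' Run the full differential-expression pipeline
#'
#' Executes, in order: data generation or loading; reference-channel
#' normalization, median centring, log2 z-scoring, missing-value filtering and
#' empirical-Bayes batch correction (with PCA batch diagnostics before and
#' after); SAM permutation testing; bootstrap-AUC testing with permutation
#' q-values; intersection of the two significant sets; and, when gene sets
#' are configured, over-representation analysis of the intersection against
#' the tested universe.  Every stochastic stage draws its seed
#' deterministically from the global seed, so a config reproduces its bundle
#' exactly.
#'
#' @param config A [run_config()].
#' @return A `tmt_run` list: `config`, `annotation`, `truth` (synthetic runs),
#'   `normalized`, `fold_changes`, `sam`, `bootauc`, `intersection`,
#'   `enrichment` (or `NULL`), `pca` (before/after), and `counts`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    tmt_error("tmtdiff_config_error", "`config` must come from run_config().")
  }
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- derive_seed(config$seed, "generate")
    ds <- generate_dataset(cfg)
    abundance <- ds$abundance; annotation <- ds$annotation; truth <- ds$truth
  } else {
    abundance <- read_abundance(config$abundance_path)
    annotation <- read_annotation(config$annotation_path)
    truth <- NULL
  }
  sets <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt

  centred <- abundance |>
    reference_normalize(annotation) |>
    median_center()
  fc <- fold_change(centred)
  complete <- centred |>
    log2_zscore(by = config$zscore_by) |>
    drop_missing()
  pca_before <- batch_pca(complete)
  corrected <- combat_adjust(complete, protect_group = config$protect_group)
  pca_after <- batch_pca(corrected)

  sam_rows <- sam(corrected, s0 = config$sam$s0,
                  n_permutations = config$sam$n_permutations,
                  seed = derive_seed(config$seed, "sam"),
                  q_threshold = config$sam$q_threshold,
                  var_equal = config$sam$var_equal, fold_changes = fc)
  auc_rows <- diff_auc(corrected, B = config$bootauc$B,
                       n_permutations = config$bootauc$n_permutations,
                       seed = derive_seed(config$seed, "boot"),
                       stratified = config$bootauc$stratified,
                       q_threshold = config$bootauc$q_threshold)
  common <- intersect_selections(sam_rows, auc_rows)
  enrich <- if (!is.null(sets)) {
    ora(common$protein, corrected$protein, sets, method = config$ora_method)
  }
  structure(list(
    config = config, annotation = annotation, truth = truth,
    normalized = corrected, fold_changes = fc, sam = sam_rows,
    bootauc = auc_rows, intersection = common, enrichment = enrich,
    pca = list(before = pca_before, after = pca_after),
    counts = list(proteins_input = nrow(abundance),
                  proteins_tested = nrow(corrected),
                  n_sam = sum(sam_rows$significant),
                  n_auc = sum(auc_rows$significant),
                  n_common = nrow(common),
                  silhouette_before = pca_before$silhouette,
                  silhouette_after = pca_after$silhouette)
  ), class = "tmt_run")
}

#' @export
print.tmt_run <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0(
    "<tmt_run> %d proteins in, %d tested\n",
    "  SAM significant: %d; bootstrap-AUC significant: %d; common: %d\n",
    "  batch silhouette: %.3f -> %.3f\n"),
    ct$proteins_input, ct$proteins_tested, ct$n_sam, ct$n_auc, ct$n_common,
    ct$silhouette_before, ct$silhouette_after))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Writes the normalized matrix, SAM rows, bootstrap-AUC rows, intersection
#' and enrichment as TSV files plus a JSON manifest (config echo, seed,
#' package version, per-stage counts).  The output is a pure function of the
#' bundle: re-writing produces byte-identical files.
#'
#' @param run A `tmt_run` from [run_pipeline()].
#' @param outdir Output directory; created if needed.
#' @return Named character vector of files written, invisibly.
#' @export
write_results <- function(run, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    tmt_error("tmtdiff_io_error", sprintf("Cannot create output directory '%s'.", outdir))
  }
  files <- c(normalized = "normalized_matrix.tsv", sam = "sam_results.tsv",
             bootauc = "bootauc_results.tsv", intersection = "intersection.tsv",
             enrichment = "enrichment.tsv")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  write_tsv_plain(run$normalized, paths["normalized"])
  write_tsv_plain(run$sam, paths["sam"])
  write_tsv_plain(run$bootauc, paths["bootauc"])
  write_tsv_plain(run$intersection, paths["intersection"])
  if (!is.null(run$enrichment)) {
    write_tsv_plain(run$enrichment, paths["enrichment"])
  } else {
    paths <- paths[names(paths) != "enrichment"]
  }
  manifest <- list(
    package = "tmtdiff", version = as.character(packageVersion("tmtdiff")),
    seed = run$config$seed,
    config = config_echo(run$config),
    counts = run$counts)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest = manifest_path))
}

config_echo <- function(config) {
  ce <- unclass(config)
  if (!is.null(ce$synthetic)) ce$synthetic <- unclass(ce$synthetic)
  if (inherits(ce$gmt, "gene_set_collection")) ce$gmt <- "<in-memory collection>"
  ce
}
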