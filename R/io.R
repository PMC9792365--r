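# Plain TSV I/O.  write_tsv_plain is deliberately deterministic (fixed
# number formatting, no quoting, LF endings) so re-writing a bundle is
# byte-identical.

#' Read a protein abundance TSV
#'
#' Expects a header row with `protein` as the first column and one column per
#' sample; empty cells and `NA` are missing.
#'
#' @param path Path to the TSV.
#' @return Tibble with `protein` plus numeric sample columns.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "protein") {
    tmt_error("tmtdiff_input_error", "Abundance TSV must start with a 'protein' column.")
  }
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  as_tibble(df)
}

#' Read a sample annotation TSV
#'
#' Expects columns `sample`, `group` (case/control/reference), `batch` and
#' optionally `channel`.
#'
#' @param path Path to the TSV.
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample", "group", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    tmt_error("tmtdiff_input_error",
              paste0("Annotation TSV is missing columns: ", paste(miss, collapse = ", ")))
  }
  as_tibble(df)
}

#' Write a synthetic dataset to TSV files
#'
#' Writes the abundance, annotation and ground-truth tables of a
#' [generate_dataset()] result (truth includes the per-batch effects,
#' flattened).
#'
#' @param dataset A `tmt_dataset`.
#' @param outdir Output directory; created if needed.
#' @return Named character vector of files written, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    tmt_error("tmtdiff_io_error", sprintf("Cannot create output directory '%s'.", outdir))
  }
  paths <- file.path(outdir, c(abundance = "abundance.tsv",
                               annotation = "annotation.tsv",
                               truth = "truth.tsv",
                               batch_effects = "batch_effects.tsv"))
  names(paths) <- c("abundance", "annotation", "truth", "batch_effects")
  write_tsv_plain(dataset$abundance, paths["abundance"])
  write_tsv_plain(dataset$annotation, paths["annotation"])
  write_tsv_plain(dataset$truth, paths["truth"])
  write_tsv_plain(attr(dataset$truth, "batch_effects"), paths["batch_effects"])
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- trimws(formatC(df[[j]], digits = 15, format = "g"))
    }
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
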