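#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a set are removed with a warning; duplicate set names or lines with
#' fewer than three fields are errors reporting the line number.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection` tibble: `set`, `description`, `members`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(tibble(set = character(), description = character(),
                            members = list()),
                     class = c("gene_set_collection", "tbl_df", "tbl", "data.frame")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    tmt_error("tmtdiff_parse_error", sprintf(
      "Malformed GMT line %d: expected name, description and at least one member.",
      bad[1]))
  }
  sets <- vapply(fields, `[[`, "", 1)
  dup <- sets[duplicated(sets)]
  if (length(dup)) {
    tmt_error("tmtdiff_parse_error",
              paste0("Duplicate set names: ", paste(unique(dup), collapse = ", ")))
  }
  members <- lapply(fields, function(f) {
    mem <- f[-(1:2)]
    u <- unique(mem)
    if (length(u) < length(mem)) {
      warn(sprintf("Set '%s': %d duplicate members removed.",
                   f[[1]], length(mem) - length(u)))
    }
    u
  })
  structure(tibble(set = sets,
                   description = vapply(fields, `[[`, "", 2),
                   members = members),
            class = c("gene_set_collection", "tbl_df", "tbl", "data.frame"))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(s, d, m) paste(c(s, d, m), collapse = "\t"),
                  collection$set, collection$description, collection$members)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Over-representation analysis against gene sets
#'
#' For each set, tests whether the selected proteins overlap the set more
#' than expected given the background universe, with the one-sided
#' hypergeometric upper-tail p-value (`method = "fisher"`) or its
#' conservative EASE variant (overlap reduced by one).  The per-set columns
#' mirror the classic enrichment-table arithmetic: `count` is the overlap,
#' `ph` the number of set members present in the background (optionally the
#' raw set size), and `percent` is 100 * count / ph to one decimal.
#' Benjamini-Hochberg q-values are computed across sets, and rows are sorted
#' by p.  Identifier matching is case-insensitive.
#'
#' @param selected Character vector of selected ids (subset of `background`).
#' @param background Character vector: the tested universe (typically the
#'   proteins that survived [drop_missing()]).
#' @param sets A `gene_set_collection` from [read_gmt()].
#' @param method `"fisher"` (hypergeometric) or `"ease"`.
#' @param ph_in_background Count `ph` within the background (default) or as
#'   the raw set size (display convention); the test always uses in-background
#'   membership.
#' @return Tibble: `term`, `count`, `ph`, `percent`, `p`, `q_bh`.
#' @export
ora <- function(selected, background, sets, method = c("fisher", "ease"),
                ph_in_background = TRUE) {
  method <- match.arg(method)
  selected <- unique(toupper(selected))
  background <- unique(toupper(background))
  offenders <- setdiff(selected, background)
  if (length(offenders)) {
    tmt_error("tmtdiff_input_error", paste0(
      "Selected ids not in background: ",
      paste(head(offenders, 5), collapse = ", "),
      if (length(offenders) > 5) ", ..."))
  }
  n_bg <- length(background)
  n_sel <- length(selected)
  rows <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    mem <- unique(toupper(sets$members[[i]]))
    mem_bg <- intersect(mem, background)
    k_set <- length(mem_bg)
    k <- length(intersect(selected, mem_bg))
    ph <- if (ph_in_background) k_set else length(mem)
    if (k_set == 0) {
      return(tibble(term = sets$set[i], count = 0L, ph = ph,
                    percent = NA_real_, p = NA_real_))
    }
    kk <- if (method == "ease") max(k - 1L, 0L) else k
    p <- phyper(kk - 1, k_set, n_bg - k_set, n_sel, lower.tail = FALSE)
    tibble(term = sets$set[i], count = k, ph = ph,
           percent = round(100 * k / ph, 1), p = p)
  })
  empty <- is.na(rows$p)
  if (any(empty)) {
    inform(sprintf("%d sets with no background members dropped.", sum(empty)))
    rows <- rows[!empty, ]
  }
  rows$q_bh <- p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows, .data$p, .data$term)
}
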