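# Internal helpers shared across the pipeline verbs.
#
# Pipeline state travels with the table as attributes:
#   tmt_steps      -- character vector of normalization steps applied, in order
#   tmt_annotation -- annotation rows for the sample columns still present

tmt_error <- function(class, msg, ...) {
  abort(msg, class = c(class, "tmtdiff_error"), ...)
}

#' @keywords internal
tmt_steps <- function(x) attr(x, "tmt_steps") %||% character(0)

tmt_annotation_attr <- function(x) {
  ann <- attr(x, "tmt_annotation")
  if (is.null(ann)) {
    tmt_error("tmtdiff_state_error",
              "No sample annotation attached; start the pipeline with reference_normalize() or as_normalized().")
  }
  ann
}

# Enforce pipeline order: the step being applied must follow the recorded
# prefix.  `after` is the step that must be the most recent one applied.
check_steps <- function(x, after, step) {
  steps <- tmt_steps(x)
  if (length(after) == 0L) return(invisible(steps))
  if (length(steps) == 0L || !steps[length(steps)] %in% after) {
    tmt_error("tmtdiff_state_error", sprintf(
      "'%s' must be applied directly after '%s' (steps so far: %s).",
      step, paste(after, collapse = "' or '"),
      if (length(steps)) paste(steps, collapse = " -> ") else "<none>"))
  }
  invisible(steps)
}

stamp <- function(x, annotation, steps) {
  x <- as_tibble(x)
  attr(x, "tmt_annotation") <- annotation
  attr(x, "tmt_steps") <- steps
  x
}

# Numeric matrix view of a protein table (first column = protein ids).
tmt_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "protein")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$protein
  storage.mode(m) <- "double"
  m
}

mat_to_tbl <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(protein = rownames(m)), out)
}

# Case/control column indices for the samples present in `x`.
tmt_groups <- function(x) {
  ann <- tmt_annotation_attr(x)
  samples <- names(x)[-1]
  ann <- ann[match(samples, ann$sample), ]
  if (anyNA(ann$sample)) {
    tmt_error("tmtdiff_input_error", "Annotation is missing rows for some sample columns.")
  }
  ann
}

check_two_groups <- function(ann, min_per_group = 2L) {
  n1 <- sum(ann$group == "case"); n0 <- sum(ann$group == "control")
  if (n1 < min_per_group || n0 < min_per_group) {
    tmt_error("tmtdiff_design_error", sprintf(
      "Both groups need at least %d samples (case: %d, control: %d).",
      min_per_group, n1, n0))
  }
  invisible(c(case = n1, control = n0))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Label permutations stratified by batch: every permutation preserves the
# number of cases assigned to each batch, so permuted labelings stay
# exchangeable with the observed (batch-balanced) one after batch moments
# have been estimated and removed.

permute_labels <- function(is_case, batch) {
  out <- is_case
  for (b in unique(batch)) {
    i <- which(batch == b)
    out[i] <- sample(out[i])
  }
  out
}

n_distinct_assignments <- function(is_case, batch) {
  prod(vapply(unique(batch), function(b) {
    i <- batch == b
    choose(sum(i), sum(is_case[i]))
  }, 0))
}

enumerate_assignments <- function(is_case, batch) {
  ub <- unique(batch)
  per <- lapply(ub, function(b) {
    i <- which(batch == b)
    utils::combn(length(i), sum(is_case[i]), simplify = FALSE)
  })
  grid <- expand.grid(lapply(per, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    flag <- rep(FALSE, length(is_case))
    for (j in seq_along(ub)) {
      i <- which(batch == ub[j])
      flag[i[per[[j]][[grid[r, j]]]]] <- TRUE
    }
    flag
  })
}

# Deterministic sub-seed per pipeline stage, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  offs <- c(generate = 11L, sam = 23L, boot = 37L, null = 41L)[[stage]]
  as.integer((as.numeric(seed) * 101 + offs) %% .Machine$integer.max)
}

#' Mark a matrix-like table as an already-normalized pipeline input
#'
#' Attaches sample annotation and a step history to a table of per-protein
#' values so mid-pipeline verbs (e.g. [combat_adjust()], [sam()]) accept it.
#' Use this to enter the pipeline with data normalized elsewhere.
#'
#' @param x Data frame whose first column is `protein`, remaining columns one
#'   per biological sample.
#' @param annotation Data frame with columns `sample`, `group`, `batch`
#'   (and optionally `channel`) covering the sample columns of `x`.
#' @param steps Character vector of normalization steps already applied, in
#'   order; defaults to the full pre-batch-correction cascade.
#' @return `x` as a tibble carrying the annotation and step history.
#' @export
as_normalized <- function(x, annotation,
                          steps = c("reference", "median", "log2_zscore", "drop_missing")) {
  x <- as_tibble(x)
  if (names(x)[1] != "protein") {
    tmt_error("tmtdiff_input_error", "First column must be 'protein'.")
  }
  annotation <- as_tibble(annotation)
  miss <- setdiff(names(x)[-1], annotation$sample)
  if (length(miss)) {
    tmt_error("tmtdiff_input_error",
              paste0("Annotation is missing samples: ", paste(miss, collapse = ", ")))
  }
  stamp(x, annotation[match(names(x)[-1], annotation$sample), ], steps)
}
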