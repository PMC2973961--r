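#' Construct an expression dataset for one condition
#'
#' The container used throughout the pipeline: a probeset x time x replicate
#' array with a strictly increasing time grid and an optional probeset-to-
#' gene annotation. Missing replicate cells are allowed (`NA`).
#'
#' @param values Numeric array probeset x time x replicate (a matrix is
#'   promoted to a single-replicate array). Rownames are probeset ids.
#' @param timepoints Strictly increasing numeric time grid, one per column.
#' @param condition_id Label for the condition.
#' @param annotation Optional tibble/data frame with columns `probeset_id`,
#'   `gene_symbol`.
#' @return An object of class `coex_dataset`.
#' @export
expression_dataset <- function(values, timepoints, condition_id = "cond1",
                               annotation = NULL) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(dim(values), 1L),
                    dimnames = c(dimnames(values), list("r1")))
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (is.null(dimnames(values)[[1]])) {
    dimnames(values)[[1]] <- sprintf("p%d", seq_len(dim(values)[1]))
  }
  if (anyDuplicated(dimnames(values)[[1]])) {
    stop("duplicate probeset ids", call. = FALSE)
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != dim(values)[2]) {
    stop("`timepoints` length must match the time dimension", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(annotation)) {
    annotation <- tibble::as_tibble(annotation)
    stopifnot(all(c("probeset_id", "gene_symbol") %in% names(annotation)))
  }
  structure(list(condition_id = condition_id, values = values,
                 timepoints = timepoints,
                 probeset_ids = dimnames(values)[[1]],
                 annotation = annotation),
            class = "coex_dataset")
}

#' @export
print.coex_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<coex_dataset> '%s': %d probesets x %d time points x %d replicate(s)\n",
              x$condition_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Read a wide expression TSV with a column manifest
#'
#' The expression file has one probeset per row, an id column, and one
#' numeric column per (time, replicate) measurement. The manifest names each
#' measurement column: a TSV (or tibble) with columns `column`, `time_h`,
#' `replicate`. Columns present in the file but not in the manifest (beyond
#' the id column) are rejected.
#'
#' @param path Path to the expression TSV.
#' @param manifest Path to the manifest TSV, or a data frame.
#' @param id_col Name of the probeset id column (default first column).
#' @param condition_id Condition label for the resulting dataset.
#' @param annotation Optional probeset annotation (see
#'   [expression_dataset()]).
#' @return A `coex_dataset`.
#' @export
read_expression_tsv <- function(path, manifest, id_col = NULL,
                                condition_id = "cond1", annotation = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (is.null(id_col)) id_col <- names(raw)[1]
  if (!id_col %in% names(raw)) {
    stop(sprintf("id column '%s' not found in %s", id_col, path),
         call. = FALSE)
  }
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, check.names = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("column", "time_h", "replicate") %in% names(manifest))) {
    stop("manifest needs columns `column`, `time_h`, `replicate`",
         call. = FALSE)
  }
  missing_cols <- setdiff(manifest$column, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("manifest columns absent from file: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(id_col, manifest$column))
  if (length(unknown)) {
    stop(sprintf("columns not described by the manifest: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate probeset id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  times <- sort(unique(manifest$time_h))
  reps <- sort(unique(manifest$replicate))
  arr <- array(NA_real_, dim = c(length(ids), length(times), length(reps)),
               dimnames = list(ids, paste0("t", times), paste0("r", reps)))
  for (i in seq_len(nrow(manifest))) {
    col <- manifest$column[i]
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA", "na", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[[col]][bad[1]], bad[1], col), call. = FALSE)
    }
    arr[, match(manifest$time_h[i], times),
        match(manifest$replicate[i], reps)] <- v
  }
  expression_dataset(arr, times, condition_id = condition_id,
                     annotation = annotation)
}

#' Filter differentially expressed probesets by one-way ANOVA over time
#'
#' Each probeset's replicate measurements are grouped by time point and
#' tested with a fixed-effects one-way ANOVA; probesets with p < `alpha`
#' are returned. Probesets with fewer than two time groups carrying data, or
#' with no residual degrees of freedom, are excluded with a warning.
#'
#' @param ds A `coex_dataset`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with columns `probeset_id`, `p_value`, `selected`.
#' @export
anova_filter <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "coex_dataset"), alpha > 0, alpha < 1)
  d <- dim(ds$values)
  grp <- factor(rep(seq_len(d[2]), times = d[3]))
  n_skipped <- 0L
  pvals <- vapply(seq_len(d[1]), function(i) {
    y <- as.vector(ds$values[i, , ])
    ok <- !is.na(y)
    g <- droplevels(grp[ok]); y <- y[ok]
    if (nlevels(g) < 2L || length(y) - nlevels(g) < 1L) {
      n_skipped <<- n_skipped + 1L
      return(NA_real_)
    }
    p <- tryCatch(
      stats::oneway.test(y ~ g, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    if (is.nan(p)) NA_real_ else p  # zero variance everywhere -> undefined F
  }, numeric(1))
  if (n_skipped > 0L) {
    warning(sprintf("%d probeset(s) lacked >=2 time groups with data or residual df; excluded",
                    n_skipped), call. = FALSE)
  }
  tibble::tibble(probeset_id = ds$probeset_ids, p_value = pvals,
                 selected = !is.na(pvals) & pvals < alpha)
}

#' Map filtered probesets to the genes common to all conditions
#'
#' Probesets surviving the per-condition filter are mapped to gene symbols
#' (case-insensitive exact match); the intersection of the per-condition
#' gene lists gives the common gene set, and each common gene is then
#' re-mapped to all of its surviving probesets in every condition.
#'
#' @param probesets Named list (one element per condition) of character
#'   vectors of surviving probeset ids.
#' @param annotations Named list (same names) of tibbles with columns
#'   `probeset_id`, `gene_symbol`.
#' @return An object of class `coex_gene_map`: list with `common_genes`
#'   (upper-cased symbols) and `map`, a tibble with columns `condition`,
#'   `gene`, `probeset_id`.
#' @export
build_gene_map <- function(probesets, annotations) {
  stopifnot(is.list(probesets), is.list(annotations),
            identical(names(probesets), names(annotations)))
  per_cond <- purrr::imap(probesets, function(ps, cond) {
    ann <- tibble::as_tibble(annotations[[cond]])
    ann |>
      dplyr::filter(.data$probeset_id %in% ps) |>
      dplyr::mutate(gene = toupper(.data$gene_symbol), condition = cond) |>
      dplyr::select("condition", "gene", "probeset_id")
  })
  gene_lists <- purrr::map(per_cond, ~unique(.x$gene))
  common <- Reduce(intersect, gene_lists)
  if (length(common) == 0L) {
    warning("no genes are common to all conditions", call. = FALSE)
  }
  map <- dplyr::bind_rows(per_cond) |>
    dplyr::filter(.data$gene %in% common) |>
    dplyr::distinct()
  structure(list(common_genes = sort(common), map = map),
            class = "coex_gene_map")
}

#' @export
print.coex_gene_map <- function(x, ...) {
  cat(sprintf("<coex_gene_map> %d common gene(s) across %d condition(s)\n",
              length(x$common_genes), length(unique(x$map$condition))))
  invisible(x)
}

#' Condense replicate measurements into one profile per probeset
#'
#' `method = "mean"` averages replicates at each time point. `method =
#' "weighted"` estimates each replicate channel's residual variance around
#' the per-time means, floors it at the 10th percentile of the observed
#' replicate variances, and forms the inverse-variance-weighted mean; with
#' equal channel variances this reduces to the plain mean. Probesets with a
#' time point carrying no data at all are dropped with a warning.
#'
#' @param ds A `coex_dataset`.
#' @param method `"mean"` (default) or `"weighted"`.
#' @return Numeric matrix probeset x time point.
#' @export
condense_replicates <- function(ds, method = c("mean", "weighted")) {
  stopifnot(inherits(ds, "coex_dataset"))
  method <- match.arg(method)
  v <- ds$values
  d <- dim(v)
  if (d[3] == 1L || method == "mean") {
    prof <- apply(v, c(1, 2), mean, na.rm = TRUE)
  } else {
    # per-probeset, per-replicate residual variance around the time means
    tmean <- apply(v, c(1, 2), mean, na.rm = TRUE)
    resid <- sweep(v, c(1, 2), tmean)
    rvar <- apply(resid, c(1, 3), function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2L) NA_real_ else stats::var(z)
    })
    floor_v <- stats::quantile(rvar, 0.10, na.rm = TRUE, names = FALSE)
    if (!is.finite(floor_v) || floor_v <= 0) floor_v <- 1e-8
    w <- 1 / pmax(rvar, floor_v)         # probeset x replicate
    w[is.na(w)] <- 0
    prof <- matrix(0, d[1], d[2], dimnames = dimnames(v)[1:2])
    wsum <- matrix(0, d[1], d[2])
    for (r in seq_len(d[3])) {
      x <- v[, , r]
      ok <- !is.na(x)
      wr <- matrix(w[, r], d[1], d[2])
      prof <- prof + ifelse(ok, x * wr, 0)
      wsum <- wsum + ifelse(ok, wr, 0)
    }
    prof <- prof / wsum
    prof[!is.finite(prof)] <- NA_real_
  }
  empty <- rowSums(is.na(prof)) > 0
  if (any(empty)) {
    warning(sprintf("dropping %d probeset(s) with an empty time point",
                    sum(empty)), call. = FALSE)
    prof <- prof[!empty, , drop = FALSE]
  }
  prof
}

#' Read a GEO GDS SOFT file (minimal reader)
#'
#' Parses the plain-text SOFT format of a curated GEO dataset: the
#' `!dataset_table_begin` ... `!dataset_table_end` block becomes a tibble
#' (columns `ID_REF`, `IDENTIFIER`, one column per sample), and `^SUBSET`
#' blocks become a tibble of sample groupings. Expression values are used
#' as deposited; no re-normalisation is applied.
#'
#' @param path Path to an uncompressed SOFT text file.
#' @return List with elements `table` (tibble) and `subsets` (tibble with
#'   columns `subset_id`, `description`, `type`, `sample_id`).
#' @export
read_geo_soft <- function(path) {
  lines <- readLines(path, warn = FALSE)
  b <- grep("^!dataset_table_begin", lines)
  e <- grep("^!dataset_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L) {
    stop("no dataset table found in SOFT file", call. = FALSE)
  }
  tab <- utils::read.delim(text = lines[(b + 1L):(e - 1L)],
                           check.names = FALSE)
  subs <- list()
  idx <- grep("^\\^SUBSET", lines)
  for (i in idx) {
    block <- lines[i:length(lines)]
    stop_at <- which(grepl("^\\^", block[-1]))[1]
    block <- block[seq_len(if (is.na(stop_at)) length(block) else stop_at)]
    getv <- function(key) {
      ln <- grep(paste0("^!subset_", key, " *= *"), block, value = TRUE)
      if (length(ln)) sub(paste0("^!subset_", key, " *= *"), "", ln[1]) else NA_character_
    }
    samples <- strsplit(getv("sample_id"), ",")[[1]]
    subs[[length(subs) + 1L]] <- tibble::tibble(
      subset_id = sub("^\\^SUBSET *= *", "", block[1]),
      description = getv("description"),
      type = getv("type"),
      sample_id = trimws(samples))
  }
  list(table = tibble::as_tibble(tab),
       subsets = if (length(subs)) dplyr::bind_rows(subs) else
         tibble::tibble(subset_id = character(), description = character(),
                        type = character(), sample_id = character()))
}
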