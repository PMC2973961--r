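#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same objects
#' under the permutation model: 1 for identical partitions, approximately 0
#' for independent ones. Computed from the contingency table of the two
#' label vectors.
#'
#' @param a,b Label vectors (any atomic type), either both named by object
#'   id or aligned by position; they must cover the same object set.
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different object sets", call. = FALSE)
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different object sets", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("labels must not be NA", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

#' Score recovered modules against known class labels
#'
#' The adjusted Rand index is computed on the selected domain only: genes
#' assigned to a module are compared with the ground-truth classes
#' restricted to those genes.
#'
#' @param ms A `coex_modules`.
#' @param labels Tibble with columns `gene_id`, `class` covering all genes,
#'   or a named vector.
#' @return One-row tibble: `n_selected`, `n_total`, `n_clusters`, `ari`
#'   (NA if nothing was selected).
#' @export
evaluate_recovery <- function(ms, labels) {
  stopifnot(inherits(ms, "coex_modules"))
  if (is.data.frame(labels)) {
    lv <- stats::setNames(labels$class, labels$gene_id)
  } else {
    lv <- labels
  }
  asg <- tidy(ms)
  if (nrow(asg) == 0L) {
    return(tibble::tibble(n_selected = 0L, n_total = length(lv),
                          n_clusters = 0L, ari = NA_real_))
  }
  missing <- setdiff(asg$gene_id, names(lv))
  if (length(missing)) {
    stop("labels do not cover all assigned genes", call. = FALSE)
  }
  truth <- lv[asg$gene_id]
  tibble::tibble(
    n_selected = nrow(asg),
    n_total = length(lv),
    n_clusters = length(ms$clusters),
    ari = adjusted_rand_index(stats::setNames(asg$module, asg$gene_id),
                              truth))
}

#' Per-condition intersection baseline
#'
#' The naive alternative to meta-analysis: cluster each condition
#' separately, then intersect clusters condition-to-condition (every
#' non-empty pairwise intersection becomes a candidate), keeping only
#' intersections with more than `min_size` genes at the end.
#'
#' @param partitions List (one per condition) of either label vectors named
#'   by gene id or tibbles with columns `gene_id`, `cluster`.
#' @param min_size Keep clusters with strictly more than this many genes
#'   (default 5).
#' @return A `coex_modules` whose clusters are the surviving intersections.
#' @export
intersection_baseline <- function(partitions, min_size = 5L) {
  stopifnot(is.list(partitions), length(partitions) >= 1L)
  to_sets <- function(p) {
    if (is.data.frame(p)) p <- stats::setNames(p$cluster, p$gene_id)
    split(names(p), p)
  }
  sets <- to_sets(partitions[[1]])
  all_genes <- unlist(sets, use.names = FALSE)
  for (k in seq_along(partitions)[-1]) {
    nxt <- to_sets(partitions[[k]])
    sets <- purrr::flatten(purrr::map(sets, function(s) {
      purrr::map(nxt, ~intersect(s, .x))
    }))
    sets <- sets[lengths(sets) > 0L]
  }
  keep <- sets[lengths(sets) > min_size]
  keep <- lapply(keep, sort)
  keep <- keep[order(-lengths(keep))]
  if (length(keep)) names(keep) <- sprintf("M%02d", seq_along(keep))
  unassigned <- setdiff(all_genes, unlist(keep, use.names = FALSE))
  new_coex_modules(keep, rep(1L, length(keep)), unassigned, NA_real_)
}
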