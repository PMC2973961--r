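#' Discover coexpressed modules across conditions
#'
#' The full meta-analytic pipeline on condensed per-condition profiles:
#' for each condition an ensemble agreement matrix is built at `nc` (or at a
#' per-condition suggested nc* when `nc = NULL`), probeset agreement is
#' averaged into gene agreement via the gene map, conditions are averaged,
#' clusters are extracted by iterative clusterable-subset selection and
#' agreement-constrained clustering at `delta`, a resampling null on the
#' first condition calibrates the cluster-size significance cutoff at
#' p-value `p`, and significant clusters are optionally merged by the
#' homogeneity + separation heuristic.
#'
#' @param profiles Named list, one probeset x time matrix per condition
#'   (rows are probesets; when `gene_map` is NULL, rownames are gene ids and
#'   every gene has one probeset).
#' @param gene_map Optional `coex_gene_map` (or its `map` tibble with
#'   columns `condition`, `gene`, `probeset_id`).
#' @param delta Coexpression confidence level (default 0.7).
#' @param p P-value for the cluster-size significance cutoff (default 0.05).
#' @param n_r Number of null resamples (default 20).
#' @param nc Input number of clusters for the ensemble; `NULL` (default)
#'   suggests one per condition via [suggest_nc()].
#' @param nc_range Sweep range when suggesting nc.
#' @param members Ensemble members for the final agreement matrices.
#' @param merge Apply the merging heuristic to the significant modules
#'   (default FALSE).
#' @param resample `"permute"` (default) or `"convex"` null scheme.
#' @param seed Master seed.
#' @return An object of class `coex_result`: list with `modules`
#'   (significant `coex_modules`), `modules_raw` (before the significance
#'   filter), `am` (averaged `agreement_matrix`), `condition_ams`,
#'   `significance` (`coex_significance`), `nc_used` (per condition), and
#'   the main parameters.
#' @export
discover_modules <- function(profiles, gene_map = NULL, delta = 0.7,
                             p = 0.05, n_r = 20L, nc = NULL,
                             nc_range = 2:10,
                             members = default_ensemble_members(),
                             merge = FALSE,
                             resample = c("permute", "convex"),
                             seed = 1L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  resample <- match.arg(resample)
  if (is.null(names(profiles))) {
    names(profiles) <- sprintf("cond%d", seq_along(profiles))
  }
  map_tbl <- if (inherits(gene_map, "coex_gene_map")) gene_map$map else
    gene_map

  nc_used <- integer(length(profiles))
  names(nc_used) <- names(profiles)
  gene_ams <- vector("list", length(profiles))
  for (k in seq_along(profiles)) {
    x <- profiles[[k]]
    nc_k <- if (is.null(nc)) {
      suggest_nc(x, nc_range = nc_range, delta = delta,
                 template = ensemble_config(screening_ensemble_members(),
                                            nc = 2L, seed = seed))$nc_star
    } else as.integer(nc)
    nc_used[k] <- nc_k
    cfg <- ensemble_config(members, nc = nc_k,
                           seed = (seed + 59L * k) %% .Machine$integer.max)
    pm <- probeset_agreement(run_ensemble(x, cfg))
    gene_ams[[k]] <- if (is.null(map_tbl)) {
      new_agreement_matrix(unclass(pm), level = "gene-condition")
    } else {
      gm_k <- dplyr::filter(tibble::as_tibble(map_tbl),
                            .data$condition == names(profiles)[k])
      gene_agreement(pm, gm_k)
    }
  }
  am <- average_conditions(gene_ams)
  modules_raw <- iterate_discovery(am, delta)

  sig <- significance_threshold(profiles[[1]], nc = nc_used[1], delta = delta,
                                n_r = n_r, p = p, cfg_members = members,
                                scheme = resample,
                                seed = (seed + 2003L) %% .Machine$integer.max)
  modules <- filter_significant(modules_raw, sig$cutoff)
  if (merge && length(modules$clusters) >= 2L) {
    modules <- merge_similar(modules, profiles, map_tbl)
  }
  structure(list(modules = modules, modules_raw = modules_raw, am = am,
                 condition_ams = stats::setNames(gene_ams, names(profiles)),
                 significance = sig, nc_used = nc_used, delta = delta,
                 p = p, n_r = n_r, merged = merge, seed = seed),
            class = "coex_result")
}

#' @export
print.coex_result <- function(x, ...) {
  g <- glance(x$modules)
  cat(sprintf(
    "<coex_result> %d significant module(s) of %d genes (cutoff %d at p <= %g); delta = %g; nc = %s\n",
    g$n_modules, g$n_selected, x$significance$cutoff, x$p, x$delta,
    paste(x$nc_used, collapse = "/")))
  invisible(x)
}

#' @describeIn discover_modules Tidy the significant module assignments.
#' @param x A `coex_result`.
#' @param ... Unused.
#' @export
tidy.coex_result <- function(x, ...) tidy(x$modules)

#' @describeIn discover_modules One-row run summary.
#' @export
glance.coex_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$modules),
                   tibble::tibble(size_cutoff = x$significance$cutoff,
                                  delta = x$delta, p = x$p,
                                  merged = x$merged))
}

#' Per-module mean expression patterns
#'
#' @param result A `coex_result` (or `coex_modules` plus profiles).
#' @param profiles Named list of probeset x time matrices per condition.
#' @param gene_map Optional gene map as in [discover_modules()].
#' @return Tibble with columns `condition`, `module`, `time_index`, `mean`,
#'   `sd`.
#' @export
module_patterns <- function(result, profiles, gene_map = NULL) {
  ms <- if (inherits(result, "coex_result")) result$modules else result
  if (inherits(gene_map, "coex_gene_map")) gene_map <- gene_map$map
  asg <- tidy(ms)
  purrr::imap_dfr(profiles, function(x, cond) {
    purrr::map_dfr(names(ms$clusters), function(mod) {
      genes <- ms$clusters[[mod]]
      rows <- if (is.null(gene_map)) genes else {
        gm <- dplyr::filter(tibble::as_tibble(gene_map),
                            .data$condition == cond,
                            .data$gene %in% genes)
        gm$probeset_id
      }
      sub <- x[intersect(rows, rownames(x)), , drop = FALSE]
      tibble::tibble(condition = cond, module = mod,
                     time_index = seq_len(ncol(sub)),
                     mean = colMeans(sub),
                     sd = apply(sub, 2, stats::sd))
    })
  })
}

#' Plot per-module mean patterns across conditions
#'
#' @param result A `coex_result`.
#' @param profiles Named list of probeset x time matrices per condition.
#' @param gene_map Optional gene map.
#' @return A ggplot object.
#' @export
plot_module_patterns <- function(result, profiles, gene_map = NULL) {
  df <- module_patterns(result, profiles, gene_map)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_index, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(module ~ condition) +
    ggplot2::labs(x = "time point", y = "mean expression")
}

#' Condense a simulation into per-condition profile matrices
#'
#' Convenience bridging [generate_dataset()] and [discover_modules()]:
#' averages replicates (or weights them, see [condense_replicates()]) in
#' every condition.
#'
#' @param sim A `coex_simulation`.
#' @param method Passed to [condense_replicates()].
#' @return Named list of gene x time matrices.
#' @export
condense_simulation <- function(sim, method = "mean") {
  stopifnot(inherits(sim, "coex_simulation"))
  purrr::imap(sim$datasets, function(arr, cond) {
    ds <- expression_dataset(arr, sim$timepoints, condition_id = cond)
    condense_replicates(ds, method = method)
  })
}
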