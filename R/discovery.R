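#' Select a clusterable subset of genes
#'
#' Agreement entries strictly inside `(1 - delta, delta)` are "moderate":
#' the two genes are neither confidently coexpressed nor confidently
#' separate. Genes are removed greedily — at each step the gene carrying the
#' most moderate entries goes (ties to the lowest index in the matrix
#' order), the counts are updated, and the loop stops when no moderate entry
#' remains. On the selected set every off-diagonal agreement is >= delta or
#' <= 1 - delta.
#'
#' @param am An `agreement_matrix` (any level).
#' @param delta Confidence level in (0.5, 1].
#' @return List with character vectors `selected` and `removed` (removal
#'   order preserved).
#' @export
select_clusterable <- function(am, delta = 0.7) {
  stopifnot(inherits(am, "agreement_matrix"), delta > 0.5, delta <= 1)
  m <- unclass(am)
  ids <- rownames(m)
  mod <- m > (1 - delta) & m < delta
  diag(mod) <- FALSE
  alive <- rep(TRUE, nrow(m))
  removed <- integer(0)
  counts <- rowSums(mod)
  while (any(counts[alive] > 0)) {
    cand <- which(alive & counts == max(counts[alive]))
    drop <- cand[1]  # lowest index among ties
    alive[drop] <- FALSE
    removed <- c(removed, drop)
    counts <- counts - mod[, drop]
    counts[drop] <- 0
    mod[drop, ] <- FALSE
    mod[, drop] <- FALSE
  }
  list(selected = ids[alive], removed = ids[removed])
}

#' Cluster a clusterable subset under the agreement constraint
#'
#' Agglomerates from singletons: two clusters may merge only if every
#' cross-pair agreement is >= delta (complete linkage on agreement). When
#' several merges are admissible the pair with the highest mean
#' cross-agreement is taken. Stops when no admissible merge remains; every
#' output cluster has minimum pairwise agreement >= delta.
#'
#' @param am An `agreement_matrix` restricted to a selected subset.
#' @param delta Confidence level.
#' @return List of character vectors (clusters), ordered by decreasing size.
#' @export
agreement_cluster <- function(am, delta = 0.7) {
  stopifnot(inherits(am, "agreement_matrix"))
  m <- unclass(am)
  n <- nrow(m)
  ids <- rownames(m)
  if (n == 1L) return(list(ids))
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  minA <- m; meanA <- m
  diag(minA) <- -Inf; diag(meanA) <- -Inf
  alive <- rep(TRUE, n)
  repeat {
    adm <- minA >= delta & outer(alive, alive, "&")
    adm[lower.tri(adm, diag = TRUE)] <- FALSE
    if (!any(adm)) break
    sc <- ifelse(adm, meanA, -Inf)
    best <- arrayInd(which.max(sc), dim(sc))
    p <- best[1]; q <- best[2]
    # merge q into p; Lance-Williams updates for min and size-weighted mean
    keep <- alive; keep[c(p, q)] <- FALSE
    minA[p, keep] <- pmin(minA[p, keep], minA[q, keep])
    minA[keep, p] <- minA[p, keep]
    meanA[p, keep] <- (sizes[p] * meanA[p, keep] + sizes[q] * meanA[q, keep]) /
      (sizes[p] + sizes[q])
    meanA[keep, p] <- meanA[p, keep]
    members[[p]] <- c(members[[p]], members[[q]])
    sizes[p] <- sizes[p] + sizes[q]
    alive[q] <- FALSE
  }
  out <- lapply(members[alive], function(ix) ids[sort(ix)])
  out[order(-lengths(out))]
}

#' Iteratively extract all clusters from an agreement matrix
#'
#' Applies clusterable-subset selection and agreement clustering, then
#' repeats the whole process on the sub-matrix of the removed genes, until
#' an iteration yields no cluster of size >= 2. Genes never placed in a
#' cluster of size >= 2 at any iteration are left unassigned (singleton
#' clusters from earlier iterations are kept — the significance filter
#' removes them later).
#'
#' @param am A gene-level or averaged `agreement_matrix`.
#' @param delta Confidence level.
#' @return An object of class `coex_modules`: list with `clusters` (named
#'   list of gene-id vectors), `iteration` (integer per cluster),
#'   `significance` (cluster sizes), `unassigned` (gene ids), and `delta`.
#' @export
iterate_discovery <- function(am, delta = 0.7) {
  stopifnot(inherits(am, "agreement_matrix"))
  domain <- rownames(am)
  clusters <- list()
  iters <- integer(0)
  unassigned <- character(0)
  it <- 0L
  while (length(domain) > 0L) {
    it <- it + 1L
    sub <- subset_am(am, domain)
    sel <- select_clusterable(sub, delta)
    if (length(sel$selected) == 0L) {
      unassigned <- c(unassigned, domain)
      break
    }
    cl <- agreement_cluster(subset_am(am, sel$selected), delta)
    big <- cl[lengths(cl) >= 2L]
    if (length(big) == 0L) {
      unassigned <- c(unassigned, domain)
      break
    }
    clusters <- c(clusters, cl)
    iters <- c(iters, rep(it, length(cl)))
    domain <- sel$removed
    if (it > length(rownames(am))) break  # safety; cannot trigger
  }
  if (length(clusters)) {
    names(clusters) <- sprintf("M%02d", seq_along(clusters))
  }
  new_coex_modules(clusters, iters, unassigned, delta)
}

subset_am <- function(am, ids) {
  new_agreement_matrix(unclass(am)[ids, ids, drop = FALSE],
                       level = attr(am, "level"))
}

new_coex_modules <- function(clusters, iteration, unassigned, delta) {
  structure(list(clusters = clusters,
                 iteration = as.integer(iteration),
                 significance = lengths(clusters),
                 unassigned = unassigned,
                 delta = delta),
            class = "coex_modules")
}

#' @export
print.coex_modules <- function(x, ...) {
  cat(sprintf("<coex_modules> %d cluster(s) (sizes: %s), %d unassigned gene(s)\n",
              length(x$clusters),
              paste(x$significance, collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}

#' @describeIn iterate_discovery Tidy module assignments into a tibble with
#'   columns `gene_id`, `module`, `iteration`.
#' @param x A `coex_modules` object.
#' @param ... Unused.
#' @export
tidy.coex_modules <- function(x, ...) {
  if (length(x$clusters) == 0L) {
    return(tibble::tibble(gene_id = character(), module = character(),
                          iteration = integer()))
  }
  tibble::tibble(
    gene_id = unlist(x$clusters, use.names = FALSE),
    module = rep(names(x$clusters), lengths(x$clusters)),
    iteration = rep(x$iteration, lengths(x$clusters)))
}

#' @describeIn iterate_discovery One-row summary: number of modules, genes
#'   selected, genes unassigned, size of the largest module.
#' @export
glance.coex_modules <- function(x, ...) {
  tibble::tibble(n_modules = length(x$clusters),
                 n_selected = sum(lengths(x$clusters)),
                 n_unassigned = length(x$unassigned),
                 max_size = if (length(x$clusters)) max(x$significance) else 0L)
}

#' Null distribution of cluster sizes and the significance cutoff
#'
#' The null model destroys temporal coexpression while keeping each
#' probeset's marginal values: by default every row of the profile matrix is
#' independently permuted (`scheme = "permute"`); alternatively rows are
#' replaced by random convex combinations of observed rows
#' (`scheme = "convex"`). Each of the `n_r` resamples is pushed through the
#' full single-condition pipeline — ensemble at the same `nc`, agreement
#' matrix, iterative selection/clustering — and the sizes of all extracted
#' clusters form the null multiset. The p-value of a cluster size `cs` is
#' the fraction of null clusters with size >= cs; the returned cutoff is the
#' smallest size with p-value <= `p`.
#'
#' @param profiles Objects x features matrix for one condition (probesets
#'   treated as genes).
#' @param nc Input number of clusters (use the same nc* as the real run).
#' @param delta Confidence level.
#' @param n_r Number of resamples (>= 1).
#' @param p Target p-value in (0, 1).
#' @param cfg_members Ensemble members (default: full ensemble).
#' @param scheme `"permute"` or `"convex"`.
#' @param seed Seed for the resampling and the ensembles.
#' @return An object of class `coex_significance`: list with `cutoff`,
#'   `sizes` (null multiset), `p`, and `pvalue_fun(cs)`.
#' @export
significance_threshold <- function(profiles, nc, delta = 0.7, n_r = 20L,
                                   p = 0.05,
                                   cfg_members = default_ensemble_members(),
                                   scheme = c("permute", "convex"),
                                   seed = 1L) {
  stopifnot(n_r >= 1L, p > 0, p < 1)
  scheme <- match.arg(scheme)
  sizes <- integer(0)
  for (b in seq_len(n_r)) {
    set.seed((seed + 104729L * b) %% .Machine$integer.max)
    null_x <- switch(scheme,
      permute = t(apply(profiles, 1L, sample)),
      convex = {
        w <- matrix(stats::rexp(nrow(profiles)^2), nrow(profiles))
        w <- w / rowSums(w)
        w %*% profiles
      })
    rownames(null_x) <- rownames(profiles)
    cfg <- ensemble_config(cfg_members, nc = nc,
                           seed = (seed + 31L * b) %% .Machine$integer.max)
    am <- probeset_agreement(suppressWarnings(run_ensemble(null_x, cfg)))
    ms <- iterate_discovery(am, delta)
    sizes <- c(sizes, unname(ms$significance))
  }
  cutoff_from_sizes(sizes, p)
}

#' Cutoff implied by a null multiset of cluster sizes
#'
#' @param sizes Integer vector of null cluster sizes (possibly empty).
#' @param p Target p-value.
#' @return A `coex_significance` object; if `sizes` is empty the cutoff
#'   defaults to 2 with a warning.
#' @export
cutoff_from_sizes <- function(sizes, p = 0.05) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) {
    warning("no null clusters found; cluster-size cutoff defaults to 2",
            call. = FALSE)
    return(structure(list(cutoff = 2L, sizes = sizes, p = p,
                          pvalue_fun = function(cs) rep(NA_real_, length(cs))),
                     class = "coex_significance"))
  }
  pvalue_fun <- function(cs) {
    vapply(cs, function(s) mean(sizes >= s), numeric(1))
  }
  cand <- seq(2L, max(sizes) + 1L)
  ok <- pvalue_fun(cand) <= p
  cutoff <- cand[which(ok)[1]]
  structure(list(cutoff = as.integer(cutoff), sizes = sizes, p = p,
                 pvalue_fun = pvalue_fun),
            class = "coex_significance")
}

#' @export
print.coex_significance <- function(x, ...) {
  cat(sprintf("<coex_significance> cutoff %d at p <= %g (%d null clusters)\n",
              x$cutoff, x$p, length(x$sizes)))
  invisible(x)
}

#' Keep clusters at or above the significance cutoff
#'
#' Clusters with size (the cluster-significance statistic) >= `cutoff` are
#' kept; genes in dropped clusters become unassigned.
#'
#' @param ms A `coex_modules`.
#' @param cutoff Minimum cluster size (>= 0).
#' @return A filtered `coex_modules`.
#' @export
filter_significant <- function(ms, cutoff) {
  stopifnot(inherits(ms, "coex_modules"), cutoff >= 0)
  keep <- ms$significance >= cutoff
  dropped <- unlist(ms$clusters[!keep], use.names = FALSE)
  new_coex_modules(ms$clusters[keep], ms$iteration[keep],
                   c(ms$unassigned, dropped), ms$delta)
}

# Per-condition gene-gene mean Pearson similarity, averaging over all
# probeset pairs of the two genes. Zero-variance profiles correlate as 0
# (with one warning per call).
gene_similarity_matrix <- function(profiles, gene_map = NULL) {
  r <- suppressWarnings(stats::cor(t(profiles)))
  if (anyNA(r)) {
    warning("zero-variance profile(s); their correlations are treated as 0",
            call. = FALSE)
    r[!is.finite(r)] <- 0
  }
  if (is.null(gene_map)) {
    diag(r) <- 1
    return(r)
  }
  gene_map <- tibble::as_tibble(gene_map)
  sets <- split(gene_map$probeset_id, gene_map$gene)
  genes <- sort(names(sets))
  ind <- matrix(0, length(genes), nrow(profiles),
                dimnames = list(genes, rownames(profiles)))
  for (g in genes) ind[g, sets[[g]]] <- 1
  cnt <- lengths(sets)[genes]
  (ind %*% r %*% t(ind)) / outer(cnt, cnt)
}

#' Homogeneity-plus-separation objective of a module set
#'
#' The merging criterion: the average within-cluster similarity
#' (homogeneity, skipping singleton clusters) plus the average
#' between-cluster Pearson-correlation distance (separation), averaged over
#' conditions and over clusters / cluster pairs. Similarity between two
#' genes in a condition is the mean Pearson correlation over all pairs of
#' their probesets; dissimilarity is the mean correlation distance `1 - r`.
#'
#' @param ms A `coex_modules` (or a plain list of gene-id vectors).
#' @param profiles Named list, one probeset x time matrix per condition.
#' @param gene_map Optional `coex_gene_map` (or its `map` tibble); omit when
#'   genes and probesets coincide (rownames of `profiles` are gene ids).
#' @return The objective value (homogeneity + separation).
#' @export
module_objective <- function(ms, profiles, gene_map = NULL) {
  clusters <- if (inherits(ms, "coex_modules")) ms$clusters else ms
  sims <- similarity_list(profiles, gene_map)
  objective_from_sims(clusters, sims)
}

similarity_list <- function(profiles, gene_map = NULL) {
  if (inherits(gene_map, "coex_gene_map")) gene_map <- gene_map$map
  if (!is.list(profiles) || is.matrix(profiles)) profiles <- list(profiles)
  purrr::imap(profiles, function(x, cond) {
    gm <- NULL
    if (!is.null(gene_map)) {
      gm <- gene_map
      if ("condition" %in% names(gm)) {
        gm <- dplyr::filter(tibble::as_tibble(gm), .data$condition == cond)
      }
    }
    gene_similarity_matrix(x, gm)
  })
}

objective_from_sims <- function(clusters, sims) {
  stopifnot(all(lengths(clusters) >= 1L))
  n <- length(clusters)
  K <- length(sims)
  H <- 0; S <- 0
  for (sim in sims) {
    for (p in seq_len(n)) {
      Cp <- clusters[[p]]
      np <- length(Cp)
      if (np >= 2L) {
        block <- sim[Cp, Cp]
        H <- H + (sum(block) - sum(diag(block))) / (np * (np - 1))
      }
      if (p < n) {
        for (q in (p + 1L):n) {
          Cq <- clusters[[q]]
          cross <- sim[Cp, Cq, drop = FALSE]
          S <- S + sum(1 - cross) / (np * length(Cq))
        }
      }
    }
  }
  hom <- H / (K * n)
  sep <- if (n >= 2L) 2 * S / (K * n * (n - 1)) else 0
  hom + sep
}

#' Merge clusters with similar expression patterns
#'
#' Greedy heuristic on the homogeneity + separation objective: at each step
#' the pair of clusters whose union most increases the objective is merged;
#' the process stops when every candidate merge would decrease it (the
#' objective is non-decreasing over accepted merges).
#'
#' @inheritParams module_objective
#' @return A `coex_modules` with `merge_trace` attribute: tibble of accepted
#'   merges and the objective after each.
#' @export
merge_similar <- function(ms, profiles, gene_map = NULL) {
  stopifnot(inherits(ms, "coex_modules"))
  sims <- similarity_list(profiles, gene_map)
  clusters <- ms$clusters
  iters <- ms$iteration
  trace <- list()
  obj <- objective_from_sims(clusters, sims)
  while (length(clusters) >= 2L) {
    n <- length(clusters)
    best <- NULL; best_obj <- obj
    for (p in seq_len(n - 1L)) {
      for (q in (p + 1L):n) {
        cand <- clusters[-q]
        cand[[p]] <- sort(c(clusters[[p]], clusters[[q]]))
        o <- objective_from_sims(cand, sims)
        if (o > best_obj + 1e-12) {
          best_obj <- o
          best <- c(p, q)
        }
      }
    }
    if (is.null(best)) break
    p <- best[1]; q <- best[2]
    trace[[length(trace) + 1L]] <- tibble::tibble(
      merged = paste(names(clusters)[c(p, q)], collapse = "+"),
      objective = best_obj)
    clusters[[p]] <- sort(c(clusters[[p]], clusters[[q]]))
    iters[p] <- min(iters[p], iters[q])
    clusters <- clusters[-q]
    iters <- iters[-q]
    obj <- best_obj
  }
  names(clusters) <- sprintf("M%02d", seq_along(clusters))
  out <- new_coex_modules(clusters, iters, ms$unassigned, ms$delta)
  attr(out, "merge_trace") <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(merged = character(), objective = numeric())
  attr(out, "objective") <- obj
  out
}
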