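#' Configure the clustering ensemble
#'
#' The default ensemble has twelve members: hierarchical (average linkage),
#' divisive (diana), fuzzy (fanny) and medoid (pam) clustering, each run on
#' the Pearson-correlation distance (1 - r) and the Manhattan distance; plus
#' k-means, fuzzy c-means, a 1 x nc self-organising map and a Gaussian
#' mixture model on the Euclidean feature space. Fuzzy memberships are
#' hardened by maximal membership (ties to the lowest cluster index).
#'
#' @param members Character vector of members as `"method:metric"` pairs.
#'   Methods: hclust, diana, fanny, pam (metrics pearson/manhattan) and
#'   kmeans, cmeans, som, mclust (metric euclidean).
#' @param nc Input number of clusters (>= 2).
#' @param seed Master seed; each member is run under a seed derived from it,
#'   so the full label matrix is reproducible.
#' @return An object of class `coex_ensemble_config`.
#' @export
ensemble_config <- function(members = default_ensemble_members(), nc = 2L,
                            seed = 1L) {
  if (length(members) == 0L) stop("`members` must be non-empty", call. = FALSE)
  if (nc < 2L) stop("`nc` must be >= 2", call. = FALSE)
  parsed <- strsplit(members, ":", fixed = TRUE)
  bad <- lengths(parsed) != 2L
  if (any(bad)) {
    stop(sprintf("malformed member(s): %s",
                 paste(members[bad], collapse = ", ")), call. = FALSE)
  }
  known <- c("hclust", "diana", "fanny", "pam", "kmeans", "cmeans", "som",
             "mclust")
  meth <- vapply(parsed, `[[`, "", 1)
  metr <- vapply(parsed, `[[`, "", 2)
  if (!all(meth %in% known)) {
    stop(sprintf("unknown method(s): %s",
                 paste(setdiff(meth, known), collapse = ", ")), call. = FALSE)
  }
  if (!all(metr %in% c("pearson", "manhattan", "euclidean"))) {
    stop("metrics must be pearson, manhattan or euclidean", call. = FALSE)
  }
  structure(list(members = members, method = meth, metric = metr,
                 nc = as.integer(nc), seed = as.integer(seed)),
            class = "coex_ensemble_config")
}

#' @rdname ensemble_config
#' @export
default_ensemble_members <- function() {
  c(as.vector(outer(c("hclust", "diana", "fanny", "pam"),
                    c("pearson", "manhattan"), paste, sep = ":")),
    paste(c("kmeans", "cmeans", "som", "mclust"), "euclidean", sep = ":"))
}

# Fast subset used by default when sweeping nc.
screening_ensemble_members <- function() {
  c("hclust:pearson", "hclust:manhattan", "pam:pearson", "pam:manhattan",
    "kmeans:euclidean")
}

# Pearson correlation distance 1 - r; zero-variance rows get r = 0.
pearson_dist <- function(x) {
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  stats::as.dist(1 - r)
}

harden <- function(membership) {
  # argmax per row, ties to the lowest cluster index
  apply(membership, 1L, which.max)
}

run_member <- function(x, method, metric, nc, seed) {
  set.seed(seed)
  d <- switch(metric,
              pearson = pearson_dist(x),
              manhattan = stats::dist(x, method = "manhattan"),
              euclidean = NULL)
  switch(method,
    hclust = stats::cutree(stats::hclust(d, method = "average"), k = nc),
    diana = stats::cutree(stats::as.hclust(cluster::diana(d, diss = TRUE)),
                          k = nc),
    fanny = {
      f <- cluster::fanny(d, k = nc, diss = TRUE, memb.exp = 1.2,
                          maxit = 500, tol = 1e-10)
      harden(f$membership)
    },
    pam = cluster::pam(d, k = nc, diss = TRUE, cluster.only = TRUE),
    kmeans = stats::kmeans(x, centers = nc, nstart = 5, iter.max = 50)$cluster,
    cmeans = {
      cm <- e1071::cmeans(x, centers = nc, iter.max = 200, m = 1.5)
      harden(cm$membership)
    },
    som = {
      # batch SOM on a 1 x nc chain; restart and keep the lowest
      # quantisation error (single runs depend heavily on the random init)
      grid <- class::somgrid(xdim = nc, ydim = 1, topo = "rectangular")
      best <- NULL
      best_q <- Inf
      for (r in 1:10) {
        sm <- class::batchSOM(x, grid, radii = c(4, 3, 2, 1, 0, 0))
        cl <- as.integer(class::knn1(sm$codes, x, seq_len(nrow(sm$codes))))
        q <- sum((x - sm$codes[cl, , drop = FALSE])^2)
        if (q < best_q) {
          best_q <- q
          best <- cl
        }
      }
      best
    },
    mclust = {
      # Mclust() resolves mclustBIC in the calling frame; bind it locally so
      # the package need not be attached
      mclustBIC <- mclust::mclustBIC
      fit <- mclust::Mclust(x, G = nc,
                            modelNames = c("EII", "VII", "EEI", "VVI"),
                            verbose = FALSE)
      if (is.null(fit)) stop("mclust did not return a model")
      fit$classification
    })
}

#' Run the clustering ensemble
#'
#' Each ensemble member produces one hard partition of the rows of
#' `profiles` into at most `cfg$nc` clusters. A member that errors or fails
#' to produce a valid partition is excluded with a warning, reducing the
#' effective ensemble size.
#'
#' @param profiles Numeric matrix, objects (probesets) x features (time
#'   points). Rownames identify the objects.
#' @param cfg A [ensemble_config()].
#' @return Integer label matrix of class `coex_labels`, members x objects,
#'   with member names as rownames and object ids as colnames.
#' @export
run_ensemble <- function(profiles, cfg) {
  stopifnot(is.matrix(profiles), inherits(cfg, "coex_ensemble_config"))
  if (nrow(profiles) < cfg$nc) {
    stop("need at least `nc` objects", call. = FALSE)
  }
  if (any(!is.finite(profiles))) {
    stop("`profiles` must be finite", call. = FALSE)
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("p%d", seq_len(nrow(profiles)))
  }
  labels <- list()
  for (h in seq_along(cfg$members)) {
    seed_h <- (cfg$seed + 7919L * h) %% .Machine$integer.max
    res <- tryCatch(
      run_member(profiles, cfg$method[h], cfg$metric[h], cfg$nc, seed_h),
      error = function(e) e)
    degenerate <- !inherits(res, "error") &&
      (length(res) != nrow(profiles) || anyNA(res) ||
         (cfg$nc >= 2L && length(unique(res)) < 2L))
    if (inherits(res, "error") || degenerate) {
      warning(sprintf("ensemble member '%s' failed and was excluded (%s)",
                      cfg$members[h],
                      if (inherits(res, "error")) conditionMessage(res)
                      else "degenerate or invalid partition"), call. = FALSE)
      next
    }
    labels[[cfg$members[h]]] <- as.integer(res)
  }
  if (length(labels) == 0L) {
    stop("every ensemble member failed", call. = FALSE)
  }
  out <- do.call(rbind, labels)
  colnames(out) <- rownames(profiles)
  class(out) <- c("coex_labels", class(out))
  out
}

#' Construct an agreement matrix from raw entries
#'
#' Validates symmetry and the `[0, 1]` range, and forces a unit diagonal.
#' Useful for assembling an agreement matrix by hand or loading one produced
#' elsewhere.
#'
#' @param entries Square numeric matrix of agreement levels; rownames (or
#'   `object_ids`) identify the objects.
#' @param level One of `"probeset-condition"`, `"gene-condition"`,
#'   `"gene-averaged"`.
#' @param object_ids Optional object ids overriding the dimnames.
#' @return An `agreement_matrix`.
#' @export
agreement_matrix <- function(entries, level = "gene-averaged",
                             object_ids = NULL) {
  if (!is.null(object_ids)) {
    dimnames(entries) <- list(object_ids, object_ids)
  }
  if (is.null(rownames(entries))) {
    dimnames(entries) <- rep(list(sprintf("o%d", seq_len(nrow(entries)))), 2)
  }
  new_agreement_matrix(entries, level)
}

new_agreement_matrix <- function(entries, level) {
  stopifnot(is.matrix(entries), nrow(entries) == ncol(entries))
  if (max(abs(entries - t(entries))) > 1e-12) {
    stop("agreement matrix must be symmetric", call. = FALSE)
  }
  entries <- (entries + t(entries)) / 2
  diag(entries) <- 1
  if (min(entries) < -1e-12 || max(entries) > 1 + 1e-12) {
    stop("agreement levels must lie in [0, 1]", call. = FALSE)
  }
  entries[entries < 0] <- 0; entries[entries > 1] <- 1
  structure(entries, level = level,
            class = c("agreement_matrix", "matrix", "array"))
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("<agreement_matrix> %d x %d objects, level '%s'\n",
              nrow(x), ncol(x), attr(x, "level")))
  invisible(x)
}

#' Probeset-level agreement matrix from ensemble labels
#'
#' Entry (x, y) is the fraction of ensemble runs assigning x and y to the
#' same cluster; the diagonal is 1.
#'
#' @param labels Label matrix from [run_ensemble()] (runs x objects).
#' @return An `agreement_matrix` with level `"probeset-condition"`.
#' @export
probeset_agreement <- function(labels) {
  stopifnot(is.matrix(labels), nrow(labels) >= 1L)
  m <- nrow(labels)
  n <- ncol(labels)
  acc <- matrix(0, n, n, dimnames = list(colnames(labels), colnames(labels)))
  for (h in seq_len(m)) {
    ind <- outer(labels[h, ], labels[h, ], "==")
    acc <- acc + ind
  }
  new_agreement_matrix(acc / m, level = "probeset-condition")
}

#' Gene-level agreement matrix for one condition
#'
#' Averages probeset-level agreement over all probeset pairs of two genes;
#' the diagonal is set to 1.
#'
#' @param pm Probeset-level `agreement_matrix`.
#' @param gene_map Tibble with columns `gene`, `probeset_id` for this
#'   condition; every gene must have at least one probeset present in `pm`.
#' @return An `agreement_matrix` with level `"gene-condition"`, one
#'   row/column per gene (sorted by gene id).
#' @export
gene_agreement <- function(pm, gene_map) {
  stopifnot(inherits(pm, "agreement_matrix"))
  gene_map <- tibble::as_tibble(gene_map)
  stopifnot(all(c("gene", "probeset_id") %in% names(gene_map)))
  missing <- setdiff(gene_map$probeset_id, rownames(pm))
  if (length(missing)) {
    stop(sprintf("probeset(s) absent from the agreement matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  sets <- split(gene_map$probeset_id, gene_map$gene)
  if (any(lengths(sets) == 0L)) stop("gene with no probesets", call. = FALSE)
  genes <- sort(names(sets))
  # indicator matrix genes x probesets; block means via matrix products
  ind <- matrix(0, length(genes), nrow(pm),
                dimnames = list(genes, rownames(pm)))
  for (g in genes) ind[g, sets[[g]]] <- 1
  cnt <- lengths(sets)[genes]
  am <- (ind %*% unclass(pm) %*% t(ind)) / outer(cnt, cnt)
  new_agreement_matrix(am, level = "gene-condition")
}

#' Average gene-level agreement across conditions
#'
#' Entrywise mean of per-condition gene-level agreement matrices over an
#' identical gene set: the cross-condition confidence of coexpression.
#'
#' @param ams List of `agreement_matrix` objects sharing object ids.
#' @return An `agreement_matrix` with level `"gene-averaged"`.
#' @export
average_conditions <- function(ams) {
  stopifnot(is.list(ams), length(ams) >= 1L)
  ids <- rownames(ams[[1]])
  for (a in ams) {
    if (!inherits(a, "agreement_matrix") ||
        !identical(sort(rownames(a)), sort(ids))) {
      stop("all agreement matrices must share the same object ids",
           call. = FALSE)
    }
  }
  acc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ams) acc <- acc + unclass(a)[ids, ids]
  new_agreement_matrix(acc / length(ams), level = "gene-averaged")
}

#' Suggest an input number of clusters
#'
#' Sweeps `nc` over `nc_range`, rebuilding the agreement matrix at each
#' value, and examines how the distribution of agreement levels responds.
#'
#' Two criteria are available. The default, `"elbow"`, tracks the mean
#' off-diagonal agreement level, which falls steeply while added clusters
#' still separate real structure and flattens once they only split it:
#' nc* is the smallest nc whose drop to nc + 1 falls below a quarter of the
#' largest drop in the sweep (equivalently, the point where the area under
#' the consensus CDF stops growing). The `"moderate"` criterion instead
#' minimises the fraction of entries in the moderate band
#' `(1 - delta, delta)`, ties to the smallest nc; it is kept for reference
#' but degenerates towards trivially stable coarse partitions (nc = 2) on
#' well-separated data, so it is not the default.
#'
#' By default a fast screening ensemble is used for the sweep; pass a full
#' config as `template` to sweep the complete ensemble.
#'
#' @param profiles Objects x features matrix.
#' @param nc_range Candidate values (within `[2, n_objects - 1]`).
#' @param delta Confidence level defining the moderate band (default 0.7).
#' @param template A `coex_ensemble_config` whose members/seed are reused at
#'   each `nc`; default is the screening ensemble.
#' @param criterion `"elbow"` (default) or `"moderate"`.
#' @return List with `nc_star`, and `sweep`, a tibble of `nc`,
#'   `mean_agreement` and `moderate_fraction`.
#' @export
suggest_nc <- function(profiles, nc_range = 2:10, delta = 0.7,
                       template = NULL,
                       criterion = c("elbow", "moderate")) {
  if (length(nc_range) == 0L) stop("`nc_range` is empty", call. = FALSE)
  criterion <- match.arg(criterion)
  nc_range <- sort(unique(as.integer(nc_range)))
  if (min(nc_range) < 2L || max(nc_range) > nrow(profiles) - 1L) {
    stop("`nc_range` must lie within [2, n_objects - 1]", call. = FALSE)
  }
  if (is.null(template)) {
    template <- ensemble_config(screening_ensemble_members(), nc = 2L,
                                seed = 1L)
  }
  stats <- vapply(nc_range, function(nc) {
    cfg <- ensemble_config(template$members, nc = nc, seed = template$seed)
    am <- probeset_agreement(suppressWarnings(run_ensemble(profiles, cfg)))
    off <- unclass(am)[upper.tri(am)]
    c(mean(off), mean(off > 1 - delta & off < delta))
  }, numeric(2))
  sweep <- tibble::tibble(nc = nc_range, mean_agreement = stats[1, ],
                          moderate_fraction = stats[2, ])
  nc_star <- if (criterion == "moderate" || length(nc_range) < 3L) {
    nc_range[which.min(sweep$moderate_fraction)]
  } else {
    drops <- -diff(sweep$mean_agreement)
    flat <- which(drops < 0.25 * max(drops))
    if (length(flat)) nc_range[flat[1]] else nc_range[length(nc_range) - 1L]
  }
  list(nc_star = nc_star, sweep = sweep)
}

#' Heatmap of an agreement matrix
#'
#' @param object An `agreement_matrix`.
#' @param order_rows Reorder objects by average-linkage clustering of
#'   `1 - AM` so blocks are visible (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_matrix <- function(object, order_rows = TRUE, ...) {
  m <- unclass(object)
  if (order_rows && nrow(m) > 2) {
    ord <- stats::hclust(stats::as.dist(1 - m), method = "average")$order
    m <- m[ord, ord]
  }
  df <- tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    agreement = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$agreement)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Write / read an agreement matrix as a dense TSV
#'
#' @param am An `agreement_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agreement_tsv <- function(am, path) {
  stopifnot(inherits(am, "agreement_matrix"))
  utils::write.table(data.frame(object_id = rownames(am), unclass(am),
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agreement_tsv
#' @param level Agreement level label to attach on read.
#' @export
read_agreement_tsv <- function(path, level = "gene-averaged") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_agreement_matrix(m, level = level)
}
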