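#' Specification of the multi-condition synthetic benchmark
#'
#' Describes a synthetic time-series benchmark with known class structure:
#' `n_classes` gene classes over `n_timepoints` equally spaced time points,
#' observed in `n_conditions` independent conditions with `n_replicates`
#' noisy measurements per (gene, time point). Four classes follow sine
#' patterns `sin(2*pi*t/10 - w)` with a condition-specific random phase `w`
#' per class, and the last two follow the linear ramps `t/20` and `-t/20`.
#' Measurement noise is Gaussian with standard deviation
#' `noise_factor * sigma_it`, where `sigma_it` is drawn per (gene, time
#' point) from `noise_scale_pool` — a stand-in for empirically observed
#' per-measurement error scales.
#'
#' @param n_genes Total number of genes, partitioned as evenly as possible
#'   across classes (default 400).
#' @param n_classes Number of classes; the benchmark's pattern family
#'   defines six (default 6).
#' @param n_timepoints Number of time points, sampled at integers
#'   `t = 1..n_timepoints` (default 20).
#' @param n_conditions Number of independent conditions `K` (default 5).
#' @param n_replicates Replicate measurements per (gene, time point)
#'   (default 3).
#' @param noise_factor Multiplicative noise level `lambda` (default 6, the
#'   high-noise regime).
#' @param noise_scale_pool Positive numeric vector of per-measurement error
#'   scales from which `sigma_it` is resampled, or `NULL` for the default
#'   log-normal pool (median 0.15, sdlog 0.5, 1000 values).
#' @param seed Integer seed; the same spec and seed always reproduce the
#'   same dataset.
#'
#' @return An object of class `coex_synth_spec` (a named list).
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_genes = 400, n_classes = 6, n_timepoints = 20,
                           n_conditions = 5, n_replicates = 3,
                           noise_factor = 6, noise_scale_pool = NULL,
                           seed = 1L) {
  counts <- c(n_genes = n_genes, n_classes = n_classes,
              n_timepoints = n_timepoints, n_conditions = n_conditions,
              n_replicates = n_replicates)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop(sprintf("`%s` must be a single integer >= 1", nm), call. = FALSE)
    }
  }
  if (n_classes > 6) {
    stop("the pattern family defines at most 6 classes", call. = FALSE)
  }
  if (!is.numeric(noise_factor) || length(noise_factor) != 1L || noise_factor < 0) {
    stop("`noise_factor` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(noise_scale_pool)) {
    noise_scale_pool <- default_noise_pool(seed)
  }
  if (noise_factor > 0 && length(noise_scale_pool) == 0L) {
    stop("`noise_scale_pool` is empty but `noise_factor` > 0", call. = FALSE)
  }
  if (length(noise_scale_pool) && any(noise_scale_pool <= 0)) {
    stop("`noise_scale_pool` must contain positive values", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_classes = as.integer(n_classes),
         n_timepoints = as.integer(n_timepoints),
         n_conditions = as.integer(n_conditions),
         n_replicates = as.integer(n_replicates),
         noise_factor = noise_factor,
         noise_scale_pool = as.numeric(noise_scale_pool),
         seed = as.integer(seed)),
    class = "coex_synth_spec"
  )
}

# Deterministic default pool of per-measurement error scales: log-normal,
# median 0.15, sdlog 0.5. Generated from its own RNG stream so that changing
# the spec seed changes the draws of sigma_it, not the pool itself.
default_noise_pool <- function(seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(980451L)
  stats::rlnorm(1000L, meanlog = log(0.15), sdlog = 0.5)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Noiseless class pattern value
#'
#' Evaluates the benchmark's pattern family: classes 1-4 are sinusoids
#' `sin(2*pi*t/10 - phase)` with period 10; class 5 is the ramp `t/20` and
#' class 6 the ramp `-t/20` (phase ignored for the linear classes).
#'
#' @param class_id Integer class in 1..6 (vectorised).
#' @param t Time point (vectorised).
#' @param phase Phase shift in radians for the sine classes; must lie in
#'   `[0, 2*pi)`.
#' @return Numeric pattern value(s).
#' @examples
#' pattern_value(5, 10)        # 0.5
#' pattern_value(1, 5, phase = 0)  # sin(pi) ~ 0
#' @export
pattern_value <- function(class_id, t, phase = 0) {
  if (any(is.na(class_id)) || any(class_id < 1) || any(class_id > 6) ||
      any(class_id != round(class_id))) {
    stop("`class_id` must be an integer in 1..6", call. = FALSE)
  }
  sine <- class_id <= 4
  if (any(sine & (phase < 0 | phase >= 2 * pi))) {
    stop("`phase` must lie in [0, 2*pi) for sine classes", call. = FALSE)
  }
  out <- numeric(length(class_id))
  n <- max(length(class_id), length(t), length(phase))
  class_id <- rep_len(class_id, n); t <- rep_len(t, n)
  phase <- rep_len(phase, n)
  out <- rep_len(out, n)
  sine <- class_id <= 4
  out[sine] <- sin(2 * pi * t[sine] / 10 - phase[sine])
  out[class_id == 5] <- t[class_id == 5] / 20
  out[class_id == 6] <- -t[class_id == 6] / 20
  out
}

#' Generate a labelled multi-condition synthetic dataset
#'
#' Draws one dataset per condition from a [synthetic_spec()]. Every
#' condition shares the same genes and class labels, but the sine classes
#' receive fresh random phases per (class, condition), so each class has a
#' different pattern in each condition. Each measurement is the class
#' pattern value plus `N(0, (noise_factor * sigma_it)^2)` noise with
#' `sigma_it` resampled per (gene, time point) from the spec's pool.
#'
#' @param spec A `coex_synth_spec` from [synthetic_spec()].
#' @return An object of class `coex_simulation`: a list with
#'   * `datasets`: named list (one per condition) of gene x time x replicate
#'     arrays with dimnames,
#'   * `labels`: tibble with columns `gene_id`, `class`,
#'   * `phases`: tibble with the phase used per (condition, class),
#'   * `timepoints`: the shared integer time grid,
#'   * `spec`: the input spec.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_genes = 24, n_conditions = 2, seed = 7))
#' dim(sim$datasets[[1]])
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "coex_synth_spec"))
  if (spec$noise_factor > 0 && length(spec$noise_scale_pool) == 0L) {
    stop("`noise_scale_pool` is empty but `noise_factor` > 0", call. = FALSE)
  }
  set.seed(spec$seed)
  nG <- spec$n_genes; nC <- spec$n_classes; nT <- spec$n_timepoints
  nK <- spec$n_conditions; nR <- spec$n_replicates

  sizes <- class_sizes(nG, nC)
  labels <- rep(seq_len(nC), times = sizes)
  gene_ids <- sprintf("g%03d", seq_len(nG))
  tgrid <- seq_len(nT)
  cond_ids <- sprintf("cond%d", seq_len(nK))

  phases <- list()
  datasets <- vector("list", nK)
  names(datasets) <- cond_ids
  for (k in seq_len(nK)) {
    w <- stats::runif(nC, 0, 2 * pi)
    w[-seq_len(min(4L, nC))] <- 0  # linear classes carry no phase
    phases[[k]] <- tibble::tibble(condition = cond_ids[k],
                                  class = seq_len(nC), phase = w)
    mu <- outer(labels, tgrid, function(l, t) pattern_value(l, t, w[l]))
    arr <- array(NA_real_, dim = c(nG, nT, nR),
                 dimnames = list(gene_ids, paste0("t", tgrid),
                                 paste0("r", seq_len(nR))))
    # one error scale per (gene, time point), shared by all replicates there
    sig <- if (spec$noise_factor > 0) {
      matrix(sample(spec$noise_scale_pool, nG * nT, replace = TRUE), nG, nT)
    } else NULL
    for (r in seq_len(nR)) {
      if (spec$noise_factor > 0) {
        arr[, , r] <- mu + stats::rnorm(nG * nT, 0, spec$noise_factor * sig)
      } else {
        arr[, , r] <- mu
      }
    }
    datasets[[k]] <- arr
  }

  structure(
    list(datasets = datasets,
         labels = tibble::tibble(gene_id = gene_ids, class = labels),
         phases = dplyr::bind_rows(phases),
         timepoints = tgrid,
         spec = spec),
    class = "coex_simulation"
  )
}

# Most even partition of n_genes into n_classes (larger classes first).
class_sizes <- function(n_genes, n_classes) {
  base <- n_genes %/% n_classes
  extra <- n_genes %% n_classes
  c(rep(base + 1L, extra), rep(base, n_classes - extra))
}

#' @export
print.coex_simulation <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<coex_simulation> %d genes x %d time points x %d replicate(s), %d condition(s), %d classes, lambda = %g\n",
    s$n_genes, s$n_timepoints, s$n_replicates, s$n_conditions, s$n_classes,
    s$noise_factor))
  invisible(x)
}

#' Tidy a synthetic simulation into a long tibble
#'
#' @param x A `coex_simulation`.
#' @param ... Unused.
#' @return Tibble with columns `condition`, `gene_id`, `class`, `time`,
#'   `replicate`, `value`.
#' @export
tidy.coex_simulation <- function(x, ...) {
  purrr::imap_dfr(x$datasets, function(arr, cond) {
    d <- dim(arr)
    tibble::tibble(
      condition = cond,
      gene_id = rep(dimnames(arr)[[1]], times = d[2] * d[3]),
      time = rep(rep(x$timepoints, each = d[1]), times = d[3]),
      replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(arr)
    )
  }) |>
    dplyr::left_join(x$labels, by = "gene_id") |>
    dplyr::relocate("class", .after = "gene_id")
}

#' Plot synthetic class patterns
#'
#' Shows the per-class mean profile (over genes and replicates) in each
#' condition, a quick visual check that sine classes carry different phases
#' across conditions while ramps are shared.
#'
#' @param object A `coex_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coex_simulation <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$condition, .data$class, .data$time) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$class))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(colour = "class", y = "mean expression")
}

#' Write a simulation to disk as wide TSVs
#'
#' One wide table per condition (rows = gene ids, columns `t<j>_r<k>`) plus
#' a `labels.tsv` with columns `gene_id`, `class`.
#'
#' @param sim A `coex_simulation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "coex_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cond in names(sim$datasets)) {
    arr <- sim$datasets[[cond]]
    d <- dim(arr)
    wide <- matrix(arr, nrow = d[1],
                   dimnames = list(dimnames(arr)[[1]], NULL))
    colnames(wide) <- as.vector(outer(paste0("t", sim$timepoints),
                                      paste0("r", seq_len(d[3])),
                                      paste, sep = "_"))
    p <- file.path(dir, paste0(cond, ".tsv"))
    utils::write.table(data.frame(gene_id = rownames(wide), wide,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.tsv")
  utils::write.table(sim$labels, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, lp))
}
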