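test_that("selection keeps everything when no entry is moderate", {
  am <- make_block_am(c(3, 3))
  sel <- select_clusterable(am, 0.7)
  expect_equal(sel$selected, rownames(am))
  expect_length(sel$removed, 0)
})

test_that("the worked 7-gene example reproduces the published trace", {
  am <- make_worked_example_am()
  sel <- select_clusterable(am, 0.7)
  expect_setequal(sel$selected, c("x", "z", "t", "v"))
  expect_equal(sel$removed[1], "w")  # most moderate entries goes first

  cl <- agreement_cluster(coexmod:::subset_am(am, sel$selected), 0.7)
  expect_equal(lapply(cl, sort), list(c("v", "x", "z"), "t"))

  ms <- iterate_discovery(am, 0.7)
  expect_equal(unname(lapply(ms$clusters, sort)),
               list(c("v", "x", "z"), "t", c("u", "y")))
  expect_equal(unname(ms$iteration), c(1L, 1L, 2L))
  expect_equal(ms$unassigned, "w")
})

test_that("greedy removal follows a step-by-step oracle replay", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 1
    am <- agreement_matrix(m)
    m <- unclass(am)  # validated copy carries the object ids
    sel <- select_clusterable(am, 0.7)
    # oracle: recompute moderate counts from scratch each step
    ids <- rownames(am)
    alive <- ids
    removed <- character(0)
    repeat {
      sub <- m[alive, alive, drop = FALSE]
      mod <- sub > 0.3 & sub < 0.7
      diag(mod) <- FALSE
      cnt <- rowSums(mod)
      if (all(cnt == 0)) break
      worst <- alive[which(cnt == max(cnt))]
      victim <- worst[which.min(match(worst, ids))]
      removed <- c(removed, victim)
      alive <- setdiff(alive, victim)
    }
    expect_equal(sel$selected, alive)
    expect_equal(sel$removed, removed)
    # postcondition: no moderate entry strictly inside (0.3, 0.7)
    if (length(alive) > 1) {
      off <- m[alive, alive][upper.tri(diag(length(alive)))]
      expect_true(all(off >= 0.7 | off <= 0.3))
    }
  }
})

test_that("agreement clustering returns blocks, singletons, and obeys delta", {
  am <- make_block_am(c(4, 3))
  cl <- agreement_cluster(am, 0.7)
  expect_equal(lengths(cl), c(4L, 3L))
  expect_setequal(cl[[1]], sprintf("g%02d", 1:4))

  single <- agreement_matrix(matrix(1, 1, 1), object_ids = "g1")
  expect_equal(agreement_cluster(single, 0.7), list("g1"))

  # min-pairwise >= delta holds on every output cluster of a random AM
  set.seed(31)
  m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 1
  am2 <- agreement_matrix(m)
  m2 <- unclass(am2)
  for (cl in agreement_cluster(am2, 0.7)) {
    if (length(cl) > 1) {
      expect_gte(min(m2[cl, cl]), 0.7)
    }
  }
})

test_that("iteration covers the gene set, terminates, and handles edge AMs", {
  # all-ones AM: one iteration, one cluster of everything
  all1 <- agreement_matrix(matrix(1, 5, 5))
  ms <- iterate_discovery(all1, 0.7)
  expect_length(ms$clusters, 1)
  expect_length(ms$clusters[[1]], 5)

  # three clean blocks: three clusters in iteration 1, nothing left
  blocks <- make_block_am(c(4, 3, 3))
  ms2 <- iterate_discovery(blocks, 0.7)
  expect_equal(sort(unname(lengths(ms2$clusters)), decreasing = TRUE),
               c(4L, 3L, 3L))
  expect_equal(unique(ms2$iteration), 1L)
  expect_length(ms2$unassigned, 0)

  # union of clusters + unassigned is always the full gene set
  set.seed(41)
  m <- matrix(runif(144), 12, 12); m <- (m + t(m)) / 2; diag(m) <- 1
  am <- agreement_matrix(m)
  ms3 <- iterate_discovery(am, 0.7)
  covered <- c(unlist(ms3$clusters, use.names = FALSE), ms3$unassigned)
  expect_setequal(covered, rownames(am))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("significance cutoffs follow the printed p-value rule", {
  # worked distribution: 100 null clusters, 4 of size >= 10, 4 of size 9,
  # 2 of size 8, 5 of size 7, the rest smaller
  sizes <- c(rep(10, 4), rep(9, 4), rep(8, 2), rep(7, 5), rep(c(2, 3), c(45, 40)))
  expect_length(sizes, 100)
  sig05 <- cutoff_from_sizes(sizes, p = 0.05)
  sig10 <- cutoff_from_sizes(sizes, p = 0.1)
  expect_equal(sig05$cutoff, 10L)
  expect_equal(sig10$cutoff, 8L)

  # all null clusters of size 2: nothing of size 3 exists
  expect_equal(cutoff_from_sizes(rep(2, 100), p = 0.05)$cutoff, 3L)

  # constructed multiset {2 x 90, 5 x 8, 12 x 2}: oracle scan of the curve
  ms <- c(rep(2, 90), rep(5, 8), rep(12, 2))
  sig <- cutoff_from_sizes(ms, p = 0.05)
  pv <- function(cs) sum(ms >= cs) / length(ms)
  oracle <- min(Filter(function(cs) pv(cs) <= 0.05, 2:13))
  expect_equal(sig$cutoff, oracle)
  # p-value curve is non-increasing in cs
  expect_true(all(diff(sig$pvalue_fun(2:13)) <= 0))
  # cutoff is monotone non-increasing in p
  cuts <- vapply(c(0.01, 0.05, 0.1, 0.5),
                 function(pp) cutoff_from_sizes(ms, pp)$cutoff, integer(1))
  expect_true(all(diff(cuts) <= 0))

  expect_warning(empty <- cutoff_from_sizes(integer(0)), "defaults to 2")
  expect_equal(empty$cutoff, 2L)
})

test_that("resampled significance runs end-to-end on small data", {
  set.seed(6)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(sprintf("p%02d", 1:40),
                                                    NULL))
  sig <- suppressWarnings(
    significance_threshold(x, nc = 3, n_r = 2, p = 0.05,
                           cfg_members = c("hclust:pearson",
                                           "kmeans:euclidean"),
                           seed = 5))
  expect_s3_class(sig, "coex_significance")
  expect_gte(sig$cutoff, 2L)
  sig_cx <- suppressWarnings(
    significance_threshold(x, nc = 3, n_r = 2, p = 0.05,
                           cfg_members = "kmeans:euclidean",
                           scheme = "convex", seed = 5))
  expect_gte(sig_cx$cutoff, 2L)
})

test_that("filter_significant keeps sizes at or above the cutoff", {
  clusters <- list(A = sprintf("a%02d", 1:12), B = sprintf("b%02d", 1:9),
                   C = sprintf("c%02d", 1:3))
  ms <- coexmod:::new_coex_modules(clusters, c(1L, 1L, 2L), character(0), 0.7)
  kept10 <- filter_significant(ms, 10)
  expect_equal(names(kept10$clusters), "A")
  expect_length(kept10$unassigned, 12)
  kept9 <- filter_significant(ms, 9)   # boundary: >= keeps the size-9 cluster
  expect_setequal(names(kept9$clusters), c("A", "B"))
  expect_equal(filter_significant(ms, 0)$clusters, ms$clusters)
})

test_that("the objective matches hand values and the brute-force oracle", {
  # two identical profiles in one cluster, K = 1: homogeneity is exactly 1
  prof <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  expect_equal(module_objective(list(c("g1", "g2")), prof), 1)

  # two singleton clusters with perfectly anti-correlated profiles: S = 2
  prof2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  expect_equal(module_objective(list("g1", "g2"), prof2), 2)

  # random 3-cluster, 2-condition fixture against the quadruple-loop oracle
  set.seed(51)
  genes <- sprintf("g%02d", 1:9)
  profs <- list(c1 = matrix(rnorm(9 * 6), 9, 6, dimnames = list(genes, NULL)),
                c2 = matrix(rnorm(9 * 6), 9, 6, dimnames = list(genes, NULL)))
  cl <- list(genes[1:4], genes[5:7], genes[8:9])
  expect_equal(module_objective(cl, profs), objective_oracle(cl, profs),
               tolerance = 1e-12)

  # with a many-to-one gene map the probeset-pair averaging matches too
  gmap <- tibble::tibble(
    condition = rep(c("c1", "c2"), each = 9),
    gene = rep(c("GA", "GA", "GB", "GB", "GC", "GC", "GD", "GE", "GF"), 2),
    probeset_id = rep(genes, 2))
  clg <- list(c("GA", "GB"), c("GC", "GD"), c("GE", "GF"))
  expect_equal(module_objective(clg, profs, gmap),
               objective_oracle(clg, profs, gmap), tolerance = 1e-12)
})

test_that("zero-variance profiles contribute zero correlation with warning", {
  prof <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  expect_warning(o <- module_objective(list(c("g1", "g2")), prof),
                 "zero-variance")
  expect_equal(o, 0)  # the only similarity is the flat profile's 0
})

test_that("merging joins identical split halves and respects anti-correlation", {
  set.seed(61)
  t <- seq(0, 2 * pi, length.out = 12)
  mk <- function(f, n, pre) {
    m <- t(replicate(n, f + rnorm(12, 0, 0.01)))
    rownames(m) <- paste0(pre, seq_len(n))
    m
  }
  prof <- rbind(mk(sin(t), 6, "s"), mk(cos(2 * t), 4, "c"))
  split_ms <- coexmod:::new_coex_modules(
    list(A = paste0("s", 1:3), B = paste0("s", 4:6), C = paste0("c", 1:4)),
    c(1L, 1L, 1L), character(0), 0.7)
  merged <- merge_similar(split_ms, list(cond1 = prof))
  expect_length(merged$clusters, 2)
  sizes <- sort(lengths(merged$clusters))
  expect_equal(unname(sizes), c(4L, 6L))

  # anti-correlated clusters are never merged
  prof2 <- rbind(mk(sin(t), 4, "u"), mk(-sin(t), 4, "d"))
  anti <- coexmod:::new_coex_modules(
    list(U = paste0("u", 1:4), D = paste0("d", 1:4)),
    c(1L, 1L), character(0), 0.7)
  out <- merge_similar(anti, list(cond1 = prof2))
  expect_length(out$clusters, 2)
})

test_that("greedy merging is monotone and matches exhaustive search", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:10)
  prof <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(genes, NULL))
  start <- list(genes[1:3], genes[4:5], genes[6:8], genes[9:10])
  ms <- coexmod:::new_coex_modules(setNames(start, LETTERS[1:4]),
                                   rep(1L, 4), character(0), 0.7)
  merged <- merge_similar(ms, list(c1 = prof))
  trace <- attr(merged, "merge_trace")
  obj0 <- module_objective(start, list(c1 = prof))
  expect_true(all(diff(c(obj0, trace$objective)) > 0))
  expect_lte(length(merged$clusters), 4)

  # exhaustive search over all merge sequences of <= 4 clusters
  best_obj <- function(clusters) {
    best <- module_objective(clusters, list(c1 = prof))
    if (length(clusters) >= 2) {
      for (p in 1:(length(clusters) - 1)) {
        for (q in (p + 1):length(clusters)) {
          cand <- clusters[-q]
          cand[[p]] <- c(clusters[[p]], clusters[[q]])
          best <- max(best, best_obj(cand))
        }
      }
    }
    best
  }
  greedy_obj <- module_objective(merged$clusters, list(c1 = prof))
  exhaustive <- best_obj(start)
  # greedy reaches a local optimum no better than the exhaustive one
  expect_lte(greedy_obj, exhaustive + 1e-9)
  # and by construction never decreases from the start
  expect_gte(greedy_obj, obj0 - 1e-12)
})
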