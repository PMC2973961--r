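# Small deterministic fixtures shared across test files.

# Three tight classes separable under every metric the ensemble uses:
# distinct profile *shapes* (so correlation distance separates them) at
# distinct locations (so Euclidean/Manhattan do too), with tiny noise.
make_separable_profiles <- function(n_per = 8, seed = 42) {
  set.seed(seed)
  tgrid <- 1:12
  shapes <- list(sin(2 * pi * tgrid / 10),
                 sin(2 * pi * tgrid / 10 - 2.5) + 4,
                 tgrid / 6 - 5)
  x <- do.call(rbind, lapply(shapes, function(sh) {
    t(replicate(n_per, sh + stats::rnorm(length(tgrid), 0, 0.02)))
  }))
  rownames(x) <- sprintf("o%02d", seq_len(nrow(x)))
  x
}

# Block 0/1 agreement matrix: blocks of the given sizes, 1 within, 0 across.
make_block_am <- function(sizes, level = "gene-averaged") {
  lab <- rep(seq_along(sizes), times = sizes)
  m <- outer(lab, lab, "==") * 1
  agreement_matrix(m, level = level,
                   object_ids = sprintf("g%02d", seq_along(lab)))
}

# Agreement matrix reproducing the worked 7-gene selection/clustering
# example: genes x, z, v form a tight cluster, t is clusterable but apart,
# y and u agree with each other but are ambiguous towards the rest, and w is
# ambiguous towards everything.
make_worked_example_am <- function() {
  ids <- c("x", "y", "z", "t", "u", "v", "w")
  m <- matrix(0.1, 7, 7, dimnames = list(ids, ids))
  hi <- function(a, b) {
    m[a, b] <<- 0.9; m[b, a] <<- 0.9
  }
  mid <- function(a, b) {
    m[a, b] <<- 0.5; m[b, a] <<- 0.5
  }
  hi("x", "z"); hi("x", "v"); hi("z", "v")  # cluster (x, z, v)
  hi("y", "u")                               # cluster (y, u)
  for (g in c("x", "z", "t", "v")) { mid("y", g); mid("u", g) }
  for (g in c("x", "y", "z", "t", "u", "v")) mid("w", g)
  diag(m) <- 1
  agreement_matrix(m, level = "gene-averaged")
}

# Independent pair-counting oracle for probeset agreement (Eq. 1).
agreement_oracle <- function(labels) {
  n <- ncol(labels)
  out <- matrix(0, n, n, dimnames = list(colnames(labels), colnames(labels)))
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      out[x, y] <- mean(labels[, x] == labels[, y])
    }
  }
  diag(out) <- 1
  out
}

# Brute-force homogeneity + separation objective (Eq. 4 oracle): quadruple
# loop over clusters, genes and probesets.
objective_oracle <- function(clusters, profiles, gene_map = NULL) {
  if (!is.list(profiles) || is.matrix(profiles)) profiles <- list(profiles)
  K <- length(profiles)
  n <- length(clusters)
  probesets_of <- function(gene, cond) {
    if (is.null(gene_map)) return(gene)
    gm <- gene_map[gene_map$condition == cond & gene_map$gene == gene, ]
    gm$probeset_id
  }
  corr0 <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b))
    if (!is.finite(r)) 0 else r
  }
  sim_g <- function(gi, gj, x, cond) {
    Ri <- probesets_of(gi, cond); Rj <- probesets_of(gj, cond)
    tot <- 0
    for (a in Ri) for (b in Rj) tot <- tot + corr0(x[a, ], x[b, ])
    tot / (length(Ri) * length(Rj))
  }
  H <- 0; S <- 0
  for (k in seq_len(K)) {
    x <- profiles[[k]]
    cond <- names(profiles)[k]
    for (p in seq_len(n)) {
      Cp <- clusters[[p]]
      if (length(Cp) >= 2) {
        tot <- 0
        for (gi in Cp) for (gj in Cp) {
          if (gi != gj) tot <- tot + sim_g(gi, gj, x, cond)
        }
        H <- H + tot / (length(Cp) * (length(Cp) - 1))
      }
      if (p < n) {
        for (q in (p + 1):n) {
          Cq <- clusters[[q]]
          tot <- 0
          for (gi in Cp) for (gj in Cq) {
            tot <- tot + (1 - sim_g(gi, gj, x, cond))
          }
          S <- S + tot / (length(Cp) * length(Cq))
        }
      }
    }
  }
  H / (K * n) + (if (n >= 2) 2 * S / (K * n * (n - 1)) else 0)
}

# Brute-force adjusted Rand index from pair counts.
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- 0; s10 <- 0; s01 <- 0; s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  tot <- s11 + s10 + s01 + s00
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Small labelled expression fixture written to a temp dir as TSV + manifest.
write_expression_fixture <- function(dir = NULL, values = NULL) {
  if (is.null(dir)) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
  }
  if (is.null(values)) {
    values <- matrix(as.numeric(1:12), nrow = 3,
                     dimnames = list(c("p1", "p2", "p3"), NULL))
  }
  df <- data.frame(probeset_id = rownames(values), values,
                   check.names = FALSE)
  colnames(df)[-1] <- c("t0_r1", "t0_r2", "t4_r1", "t4_r2")
  fp <- file.path(dir, "expr.tsv")
  utils::write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(column = colnames(df)[-1],
                         time_h = c(0, 0, 4, 4), replicate = c(1, 2, 1, 2))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(expr = fp, manifest = mp)
}
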