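#' Read a per-base conservation score profile
#'
#' Accepts a two-column TSV (`position`, `score`; positions 1-based and
#' contiguous) or a minimal fixedStep WIG-like track (`fixedStep start=..
#' step=1` followed by one score per line).
#'
#' @param path Path to the profile file.
#' @return Numeric vector of per-base scores.
#' @export
read_score_profile <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^fixedStep", first)) {
    lines <- readLines(path, warn = FALSE)
    vals <- suppressWarnings(as.numeric(lines[-1]))
    if (anyNA(vals)) stop("non-numeric score in WIG track", call. = FALSE)
    return(vals)
  }
  df <- utils::read.delim(path)
  if (ncol(df) < 2L) stop("expected columns position, score", call. = FALSE)
  pos <- df[[1]]; sc <- df[[2]]
  if (anyNA(sc) || !is.numeric(sc)) stop("non-numeric score", call. = FALSE)
  ord <- order(pos)
  sc[ord]
}

#' Call conserved regions from a score profile
#'
#' A conserved region is a maximal run of bases whose score is strictly
#' greater than the arithmetic mean of the whole profile, kept only if the
#' run is longer than `min_len` bases. Coordinates are 0-based half-open.
#'
#' @param scores Numeric vector of per-base scores (finite, non-empty).
#' @param min_len Minimum exclusive run length (default 10: runs of 11+
#'   bases are kept).
#' @return Tibble with columns `start`, `end` (0-based half-open) and
#'   `length`, of class `conserved_regions`.
#' @export
call_conserved_regions <- function(scores, min_len = 10L) {
  stopifnot(length(scores) > 0L, all(is.finite(scores)))
  above <- scores > mean(scores)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_len
  out <- tibble::tibble(start = starts[keep] - 1L, end = ends[keep],
                        length = r$lengths[keep])
  class(out) <- c("conserved_regions", class(out))
  out
}

iupac_ok <- function(motif) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(motif))
}

#' Scan a motif over conserved regions of a promoter
#'
#' Matches an IUPAC consensus (e.g. the glucocorticoid response element
#' `TGTTCT`) against the sequence and keeps hits fully contained in the
#' given conserved regions. With `both_strands` the reverse-complement of
#' the motif is also searched on the forward sequence, reported with strand
#' `"-"`.
#'
#' @param seq A single promoter sequence (character or
#'   [Biostrings::DNAString]).
#' @param motif IUPAC consensus string.
#' @param regions `conserved_regions` tibble (or any tibble with `start`,
#'   `end`, 0-based half-open); `NULL` scans the whole sequence.
#' @param both_strands Also search the reverse strand (default TRUE).
#' @return Tibble with columns `start`, `end` (0-based half-open), `strand`,
#'   `match`.
#' @export
scan_motif <- function(seq, motif, regions = NULL, both_strands = TRUE) {
  if (!iupac_ok(motif)) {
    stop(sprintf("'%s' is not a valid IUPAC motif", motif), call. = FALSE)
  }
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  hits_for <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), s,
                                  fixed = FALSE)
    if (length(m) == 0L) {
      return(tibble::tibble(start = integer(), end = integer(),
                            strand = character(), match = character()))
    }
    tibble::tibble(start = Biostrings::start(m) - 1L,
                   end = Biostrings::end(m),
                   strand = strand,
                   match = as.character(m))
  }
  out <- hits_for(toupper(motif), "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif))))
    if (!identical(rc, toupper(motif))) {
      out <- dplyr::bind_rows(out, hits_for(rc, "-"))
    } else {
      # palindromic motif: every forward hit is also a reverse hit
      rev_hits <- hits_for(rc, "-")
      out <- dplyr::bind_rows(out, rev_hits)
    }
  }
  if (!is.null(regions) && nrow(out)) {
    contained <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      any(regions$start <= out$start[i] & out$end[i] <= regions$end)
    })
    out <- out[contained, , drop = FALSE]
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Scan a position weight matrix over conserved regions
#'
#' A minimal PWM scanner for user-supplied matrices: hits at or above
#' `min_score` (fraction of the maximal PWM score, as in
#' [Biostrings::matchPWM]) and fully contained in the conserved regions.
#' MatInspector-style core/matrix-similarity semantics are not reproduced.
#'
#' @param seq Promoter sequence.
#' @param pwm Numeric matrix with rows A, C, G, T.
#' @param regions Optional `conserved_regions`.
#' @param min_score Score threshold, e.g. `"85%"` (default).
#' @param both_strands Also scan the reverse strand.
#' @return Tibble with columns `start`, `end`, `strand`, `match`.
#' @export
scan_pwm <- function(seq, pwm, regions = NULL, min_score = "85%",
                     both_strands = TRUE) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  rownames(pwm) <- c("A", "C", "G", "T")
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  one <- function(mat, strand) {
    m <- Biostrings::matchPWM(mat, s, min.score = min_score)
    if (length(m) == 0L) {
      return(tibble::tibble(start = integer(), end = integer(),
                            strand = character(), match = character()))
    }
    tibble::tibble(start = Biostrings::start(m) - 1L,
                   end = Biostrings::end(m), strand = strand,
                   match = as.character(m))
  }
  out <- one(pwm, "+")
  if (both_strands) {
    out <- dplyr::bind_rows(out, one(Biostrings::reverseComplement(pwm), "-"))
  }
  if (!is.null(regions) && nrow(out)) {
    contained <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      any(regions$start <= out$start[i] & out$end[i] <= regions$end)
    })
    out <- out[contained, , drop = FALSE]
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Module-level motif commonality
#'
#' A motif's commonality in a module is the fraction of the module's genes
#' carrying it (on the conserved regions of any of their alternative
#' promoters). Motifs present in strictly more than `threshold` of the genes
#' are retained.
#'
#' @param profiles Tibble with columns `gene_id`, `motif` (one row per
#'   gene-motif presence), or a named list of per-gene motif sets.
#' @param threshold Commonality threshold in (0, 1] (default 0.7).
#' @param all Return all motifs with a `retained` flag instead of only the
#'   retained ones.
#' @return Tibble with columns `motif`, `n_genes`, `commonality` (and
#'   `retained` when `all = TRUE`).
#' @export
module_commonality <- function(profiles, threshold = 0.7, all = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- tibble::tibble(
      gene_id = rep(names(profiles), lengths(profiles)),
      motif = unlist(profiles, use.names = FALSE))
  }
  n_module <- dplyr::n_distinct(profiles$gene_id)
  if (n_module == 0L) {
    warning("empty module", call. = FALSE)
    return(tibble::tibble(motif = character(), n_genes = integer(),
                          commonality = numeric()))
  }
  tab <- profiles |>
    dplyr::distinct(.data$gene_id, .data$motif) |>
    dplyr::count(.data$motif, name = "n_genes") |>
    dplyr::mutate(commonality = .data$n_genes / n_module,
                  retained = .data$commonality > threshold) |>
    dplyr::arrange(dplyr::desc(.data$commonality), .data$motif)
  if (all) tab else dplyr::select(dplyr::filter(tab, .data$retained),
                                  -"retained")
}

#' Fraction of genes carrying a conserved-region motif hit
#'
#' For each gene set, the fraction of genes with at least one hit of the
#' motif (default the GRE hexamer TGTTCT) fully inside a conserved region of
#' any of the gene's promoters. Genes without any promoter are excluded from
#' the denominator and counted in the report. Useful for comparing a target
#' module against a random background set.
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param promoter_map Tibble with columns `gene_id`, `promoter_id`.
#' @param sequences Named character vector or `DNAStringSet` of promoter
#'   sequences (names = promoter ids).
#' @param profiles Named list of per-base score vectors (names = promoter
#'   ids).
#' @param motif IUPAC motif (default `"TGTTCT"`).
#' @param both_strands Search both strands (default TRUE).
#' @return Tibble with one row per set: `set`, `n_genes`,
#'   `n_with_promoter`, `n_excluded`, `n_hit`, `rate`.
#' @export
gre_background_rate <- function(gene_sets, promoter_map, sequences, profiles,
                                motif = "TGTTCT", both_strands = TRUE) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  promoter_map <- tibble::as_tibble(promoter_map)
  seq_chr <- as.character(sequences)
  names(seq_chr) <- names(sequences)  # as.character() drops names
  gene_hit <- function(gene) {
    proms <- promoter_map$promoter_id[promoter_map$gene_id == gene]
    proms <- intersect(proms, names(seq_chr))
    if (length(proms) == 0L) return(NA)
    any(vapply(proms, function(pid) {
      sc <- profiles[[pid]]
      if (is.null(sc)) return(FALSE)
      regs <- call_conserved_regions(sc)
      nrow(scan_motif(seq_chr[[pid]], motif, regs, both_strands)) > 0L
    }, logical(1)))
  }
  purrr::imap_dfr(gene_sets, function(genes, set) {
    hits <- vapply(genes, gene_hit, logical(1))
    n_prom <- sum(!is.na(hits))
    tibble::tibble(set = set, n_genes = length(genes),
                   n_with_promoter = n_prom,
                   n_excluded = sum(is.na(hits)),
                   n_hit = sum(hits, na.rm = TRUE),
                   rate = if (n_prom) sum(hits, na.rm = TRUE) / n_prom
                          else NA_real_)
  })
}

#' Write intervals or hits as BED
#'
#' @param x Tibble with `start`, `end` (0-based half-open) and optionally
#'   `strand`.
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1.
#' @param feature_names Feature names (column 4); recycled.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, chrom = "promoter", feature_names = ".") {
  bed <- data.frame(chrom = chrom, start = x$start, end = x$end,
                    name = rep_len(feature_names, nrow(x)), score = 0L,
                    strand = if ("strand" %in% names(x)) x$strand else "*")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
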