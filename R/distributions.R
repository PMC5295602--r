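## Histograms of per-gene statistics, per-bin heterogeneity chi-square LOD
## profiles, 1% tails and their co-occurrence across collections.

#' Bin edges for a statistic
#'
#' F_ST histograms use `seq(-0.05, 1, 0.01)` (per-SNP estimates can be
#' slightly negative), expected-heterozygosity histograms `seq(0, 1, 0.01)`.
#'
#' @param kind `"fst"` or `"hexp"`.
#' @return Numeric vector of bin edges (width 0.01).
#' @export
stat_breaks <- function(kind = c("fst", "hexp")) {
  kind <- match.arg(kind)
  if (kind == "fst") seq(-0.05, 1, 0.01) else seq(0, 1, 0.01)
}

#' Histogram of a per-gene statistic
#'
#' Left-closed, right-open 0.01-wide bins; the last bin is closed on both
#' sides. Out-of-range values are clamped into the end bins with a warning.
#'
#' @param values Per-gene statistic values.
#' @param kind `"fst"` or `"hexp"` (sets the default edges).
#' @param edges Optional explicit bin edges (strictly increasing, uniform
#'   width).
#' @return Object of class `pg_histogram`: list(kind, edges, mids, counts,
#'   total).
#' @export
bin_statistic <- function(values, kind = c("fst", "hexp"), edges = NULL) {
  kind <- match.arg(kind)
  if (is.null(edges)) edges <- stat_breaks(kind)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  values <- values[!is.na(values)]
  nb <- length(edges) - 1L
  if (length(values) &&
      (min(values) < edges[1] || max(values) > edges[length(edges)])) {
    warning("values outside [", edges[1], ", ", edges[length(edges)],
            "] clamped into end bins")
    values <- pmin(pmax(values, edges[1]), edges[length(edges)])
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(kind = kind, edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, total = length(values)),
            class = "pg_histogram")
}

#' @export
print.pg_histogram <- function(x, ...) {
  cat("pg_histogram (", x$kind, "): ", x$total, " values in ",
      length(x$counts), " bins of width ",
      signif(diff(x$edges[1:2]), 3), "\n", sep = "")
  invisible(x)
}

#' Per-bin heterogeneity chi-square LOD profile
#'
#' Compares k histograms bin by bin: for each 0.01 bin, a Pearson
#' chi-square on the k x 2 table of (genes in the bin, genes outside the
#' bin) with k - 1 degrees of freedom, and LOD = -log10(p). A bin empty in
#' every distribution has LOD 0 by convention. LOD = 3 is the conventional
#' stringent cutoff (p = 1e-3).
#'
#' @param histograms List of >= 2 [bin_statistic()] objects with identical
#'   edges.
#' @param lod_cutoff Cutoff reported in the `crossing` column (default 3).
#' @return data.table: bin mid, per-bin counts (one column per histogram),
#'   chi2, df, p, lod, crossing (lod > cutoff).
#' @export
lod_profile <- function(histograms, lod_cutoff = 3) {
  k <- length(histograms)
  if (k < 2) stop("need >= 2 histograms")
  edges <- histograms[[1]]$edges
  for (h in histograms)
    if (!isTRUE(all.equal(h$edges, edges)))
      stop("histograms have differing bin edges")
  counts <- vapply(histograms, `[[`, numeric(length(edges) - 1L), "counts")
  totals <- vapply(histograms, `[[`, numeric(1), "total")
  N <- sum(totals)
  S <- rowSums(counts)                       # genes in the bin, all dists
  ## expected in-bin count for distribution j at bin b: totals_j * S_b / N
  E_in <- outer(S / N, totals)
  E_out <- outer((N - S) / N, totals)
  O_out <- sweep(-counts, 2, totals, `+`)
  num_in <- (counts - E_in)^2
  num_out <- (O_out - E_out)^2
  chi2 <- rowSums(ifelse(E_in > 0, num_in / E_in, 0)) +
    rowSums(ifelse(E_out > 0, num_out / E_out, 0))
  chi2[S == 0] <- 0
  chi2[chi2 < 1e-10] <- 0        # guard against rounding dust at chi2 = 0
  df <- k - 1L
  lod <- -pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  lod[S == 0] <- 0
  p <- 10^(-lod)
  out <- data.table(mid = histograms[[1]]$mids, chi2 = chi2, df = df,
                    p = p, lod = lod, crossing = lod > lod_cutoff)
  nm <- names(histograms)
  if (is.null(nm)) nm <- paste0("dist", seq_len(k))
  for (j in seq_len(k)) out[, (paste0("n_", nm[j])) := counts[, j]]
  out[]
}

#' Extreme 1% tails of a ranked per-gene statistic
#'
#' Ranks genes by value and takes the `floor(fraction * n)` smallest (lower
#' tail) and largest (upper tail) genes. Ties at the cutoff are broken by
#' gene id, so tails are deterministic; lower and upper tails are disjoint
#' whenever `2 * fraction <= 1`.
#'
#' @param values Per-gene values.
#' @param ids Gene ids.
#' @param fraction Tail fraction (default 0.01).
#' @return List with `lower` and `upper` character vectors of gene ids
#'   (empty, with a warning, when `floor(fraction * n) == 0`).
#' @export
extract_tails <- function(values, ids, fraction = 0.01) {
  stopifnot(length(values) == length(ids))
  keep <- !is.na(values)
  values <- values[keep]; ids <- as.character(ids[keep])
  n <- length(values)
  size <- floor(fraction * n)
  if (size == 0) {
    warning("fewer than ", ceiling(1 / fraction),
            " genes: tails are empty")
    return(list(lower = character(0), upper = character(0)))
  }
  o_low <- order(values, ids)
  o_high <- order(-values, ids)
  list(lower = ids[o_low][seq_len(size)],
       upper = ids[o_high][seq_len(size)])
}

#' Cross-collection co-occurrence of tail genes
#'
#' Counts, over the union of k same-direction tail sets, how many genes
#' occur in exactly 1, 2, ..., k collections, and the percentage occurring
#' in only one (rounded to a whole percent).
#'
#' @param tail_sets List of >= 2 character vectors of gene ids.
#' @return List: multiplicity (named integer vector, counts of genes in
#'   exactly m sets), union_size, n_unique, pct_unique.
#' @export
#' @examples
#' # 376 of 490 union genes in exactly one collection -> 77%
cooccurrence_tally <- function(tail_sets) {
  if (length(tail_sets) < 2) stop("need >= 2 tail sets")
  k <- length(tail_sets)
  all_ids <- unlist(lapply(tail_sets, unique), use.names = FALSE)
  mult <- table(all_ids)
  counts <- tabulate(mult, nbins = k)
  names(counts) <- as.character(seq_len(k))
  union_size <- length(mult)
  n_unique <- counts[["1"]]
  list(multiplicity = counts,
       union_size = union_size,
       n_unique = n_unique,
       pct_unique = if (union_size > 0)
         round(100 * n_unique / union_size) else NA_real_)
}

#' Location and spread summary of a per-gene F_ST distribution
#'
#' Mean, SD, median, mode (midpoint of the most populated 0.01 histogram
#' bin), and the lower-5% / upper-95% quantiles (linear interpolation, R
#' type 7, or nearest-rank via `quantile_type = 1`).
#'
#' @param values Per-gene values.
#' @param kind Histogram kind for the modal bin.
#' @param n_snps Optional SNP count to carry into the summary.
#' @param quantile_type Passed to [stats::quantile()] (7 = linear
#'   interpolation).
#' @return List: n_genes, n_snps, mean, sd, median, mode, low5, high95.
#' @export
distribution_summary <- function(values, kind = "fst", n_snps = NA_integer_,
                                 quantile_type = 7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("need >= 1 value")
  h <- bin_statistic(values, kind)
  mode_mid <- h$mids[which.max(h$counts)]
  q <- quantile(values, c(0.05, 0.95), type = quantile_type, names = FALSE)
  list(n_genes = length(values), n_snps = n_snps,
       mean = mean(values), sd = sd(values), median = median(values),
       mode = mode_mid, low5 = q[1], high95 = q[2])
}
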