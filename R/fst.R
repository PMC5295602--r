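## Expected heterozygosity, percent polymorphism, per-SNP and per-gene F_ST,
## and gene-wise paired comparisons.

#' Expected heterozygosity of a site
#'
#' `H_exp = 2 p (1 - p)` for the tracked allele frequency `p`. At its
#' maximum, p = 0.5, it equals 0.5; it is 0 at fixation.
#'
#' @param p Allele frequency vector in `[0, 1]`.
#' @return Numeric vector in `[0, 0.5]`.
#' @export
#' @examples
#' hexp(0.75)  # counts A:30 G:10 -> 0.375
hexp <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies must be in [0, 1]")
  2 * p * (1 - p)
}

#' Percentage of polymorphic sites
#'
#' `100 * (1 - monomorphic / total)`, reported to two decimals.
#'
#' @param monomorphic Number of monomorphic sites.
#' @param total Total sites analysed.
#' @return Percentage, rounded to 2 decimals.
#' @export
#' @examples
#' percent_polymorphic(30229087, 32967403)  # 8.31
percent_polymorphic <- function(monomorphic, total) {
  if (any(total < monomorphic) || any(monomorphic < 0))
    stop("need total >= monomorphic >= 0")
  out <- ifelse(total == 0, NA_real_,
                round(100 * (1 - monomorphic / total), 2))
  out
}

#' Per-SNP F_ST variance components
#'
#' Decomposes allele-frequency variance at each SNP into a
#' between-collection component `a` and a within-collection component `b`:
#' \deqn{b_s = \frac{n_i \alpha_i + n_j \alpha_j}{n_i + n_j - 1}}
#' \deqn{a_s = \frac{4 n_i (p_i - \bar p)^2 + 4 n_j (p_j - \bar p)^2 - b_s}
#'                  {2\,[2 n_i n_j / (n_i + n_j)]}}
#' with \eqn{\alpha = 2 p (1 - p)} the expected heterozygosity and
#' \eqn{\bar p} the coverage-weighted pooled frequency. Then
#' \eqn{F_{ST}(s) = a_s / (a_s + b_s)}, which is 1 at a fixed difference
#' (b = 0, a > 0), non-positive for identical frequencies, and undefined
#' (NA) when a + b = 0.
#'
#' @param p_i,p_j Tracked-allele frequency in collections i and j.
#' @param n_i,n_j Number of diploid individuals (mosquitoes) sampled in each
#'   collection (summed over replicates when replicate counts are summed).
#' @param cov_i,cov_j Read coverages used to weight the pooled frequency
#'   \eqn{\bar p = (cov_i p_i + cov_j p_j) / (cov_i + cov_j)}; equal weights
#'   by default.
#' @return data.table with columns a, b, fst, alpha_i, alpha_j.
#' @export
#' @examples
#' site_fst(1, 0, 12, 12)$fst        # fixed difference -> 1
#' site_fst(0.3, 0.3, 12, 12)$fst    # identical frequencies -> <= 0
site_fst <- function(p_i, p_j, n_i, n_j, cov_i = 1, cov_j = 1) {
  k <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, k); p_j <- rep_len(p_j, k)
  n_i <- rep_len(n_i, k); n_j <- rep_len(n_j, k)
  cov_i <- rep_len(cov_i, k); cov_j <- rep_len(cov_j, k)
  if (any(p_i < 0 | p_i > 1 | p_j < 0 | p_j > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1]")
  if (any(n_i + n_j <= 1))
    stop("need n_i + n_j > 1")
  if (any(cov_i <= 0 | cov_j <= 0))
    stop("coverages must be positive")
  p_bar <- (cov_i * p_i + cov_j * p_j) / (cov_i + cov_j)
  alpha_i <- 2 * p_i * (1 - p_i)
  alpha_j <- 2 * p_j * (1 - p_j)
  b <- (n_i * alpha_i + n_j * alpha_j) / (n_i + n_j - 1)
  a <- (4 * n_i * (p_i - p_bar)^2 + 4 * n_j * (p_j - p_bar)^2 - b) /
    (2 * (2 * n_i * n_j / (n_i + n_j)))
  fst <- ifelse(a + b == 0, NA_real_, a / (a + b))
  data.table(a = a, b = b, fst = fst, alpha_i = alpha_i, alpha_j = alpha_j)
}

#' Gene-level F_ST as a ratio of summed components
#'
#' \eqn{F_{ST}(g) = \sum_s a_s / \sum_s (a_s + b_s)} over the gene's m SNPs —
#' a ratio of sums, not a mean of per-SNP ratios. Sites with undefined
#' per-SNP F_ST (a + b = 0) contribute nothing to either sum.
#'
#' @param a,b Per-SNP variance components.
#' @param gene_id Gene of each SNP.
#' @return data.table: gene_id, m (SNP count), sum_a, sum_ab, fst.
#' @export
#' @examples
#' gene_fst(c(1, 3), c(1, 1), c("g", "g"))$fst  # 4/6, not mean(0.5, 0.75)
gene_fst <- function(a, b, gene_id) {
  dt <- data.table(gene_id = gene_id, a = a, b = b)
  dt <- dt[!is.na(a) & !is.na(b) & (a + b) != 0]
  out <- dt[, .(m = .N, sum_a = sum(a), sum_ab = sum(a + b)), by = gene_id]
  out[, fst := sum_a / sum_ab]
  out[]
}

#' Gene-wise paired comparison of two collections
#'
#' Matches genes by id, counts in how many the first collection's value is
#' greater/lesser, reports the percentage greater (rounded to a whole
#' percent, as in gene-count summary tables), the mean difference, and a
#' two-sided paired t-test with `shared genes - 1` degrees of freedom.
#'
#' @param x,y Named numeric vectors (names are gene ids) or two columns of
#'   per-gene values matched by `ids`.
#' @param ids Optional gene ids when `x`/`y` are unnamed.
#' @return List: n_genes, n_greater, n_lesser, pct_greater (whole %),
#'   pct_greater_1dp (one decimal), mean_diff, t, df, p.
#' @export
genewise_comparison <- function(x, y, ids = NULL) {
  if (!is.null(ids)) {
    names(x) <- ids; names(y) <- ids
  }
  if (is.null(names(x)) || is.null(names(y)))
    stop("gene ids required (named vectors or ids=)")
  shared <- intersect(names(x), names(y))
  if (length(shared) < 2) stop("need >= 2 shared genes")
  xv <- x[shared]; yv <- y[shared]
  d <- xv - yv
  n_greater <- sum(d > 0)
  n_lesser <- sum(d < 0)
  if (all(d == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
               p.value = 1)
  } else {
    tt <- t.test(xv, yv, paired = TRUE)
  }
  list(n_genes = length(shared),
       n_greater = n_greater,
       n_lesser = n_lesser,
       pct_greater = round(100 * n_greater / length(shared)),
       pct_greater_1dp = round(100 * n_greater / length(shared), 1),
       mean_diff = mean(d),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mean site F_ST stratified by annotation
#'
#' Means of per-SNP F_ST within each stratum of a site annotation (gene
#' region, mutation type or consequence), crossed with chromosome
#' assignment. Strata with no sites are absent from the output, not zero.
#'
#' @param ann data.table/data.frame with a numeric `fst` column and the
#'   stratifier columns.
#' @param by Character vector of stratifier column names (e.g.
#'   `c("region", "chrom")`).
#' @return data.table with the stratifiers, `mean_fst` and `n_sites`.
#' @export
stratified_fst_means <- function(ann, by = c("region", "chrom")) {
  dt <- as.data.table(ann)
  missing_cols <- setdiff(c(by, "fst"), names(dt))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dt <- dt[!is.na(fst)]
  for (col in by) dt <- dt[!is.na(dt[[col]])]
  out <- dt[, .(mean_fst = mean(fst), n_sites = .N), by = by]
  data.table::setorderv(out, by)
  out[]
}
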