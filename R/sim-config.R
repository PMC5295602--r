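#' Describe one pooled collection for simulation
#'
#' A collection is one population sample sequenced as `n_replicates`
#' independently prepared pooled libraries, each pooling equal amounts of DNA
#' from `n_individuals_per_replicate` mosquitoes (or other diploid
#' individuals). The replicate structure is what the replicate-concordance
#' SNP filter consumes, so at least two replicates are required.
#'
#' @param name Collection label, used in file names and report tables.
#' @param n_individuals_per_replicate Diploid individuals pooled per replicate
#'   library; enters the F_ST estimator as the mosquito sample size.
#' @param n_replicates Number of replicate libraries (>= 2).
#' @param sex One of `"female"`, `"male"`, `"mixed"`.
#' @return A `collection_spec` list.
#' @export
#' @examples
#' collection_spec("PK10_female", 12, sex = "female")
collection_spec <- function(name, n_individuals_per_replicate,
                            n_replicates = 2L,
                            sex = c("mixed", "female", "male")) {
  sex <- match.arg(sex)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_individuals_per_replicate <- as.integer(n_individuals_per_replicate)
  n_replicates <- as.integer(n_replicates)
  if (n_individuals_per_replicate < 1L)
    stop("n_individuals_per_replicate must be >= 1")
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2 (the concordance filter needs pairs)")
  structure(list(name = name,
                 n_individuals_per_replicate = n_individuals_per_replicate,
                 n_replicates = n_replicates,
                 sex = sex),
            class = "collection_spec")
}

#' Configuration for the synthetic pooled-sequencing study
#'
#' Bundles every tunable of the toy-data generator: a toy exome (genes with
#' 600 bp nontranscribed flanks, UTRs, multi-exon CDS, introns on both
#' strands), Balding-Nichols divergence of per-site allele frequencies
#' between collections, and two-stage pooled sequencing (chromosomes sampled
#' into the pool, then reads sampled at negative-binomial coverage with
#' miscalls).
#'
#' Under the Balding-Nichols model each collection's allele frequency at a
#' segregating site is drawn from Beta(p(1-theta)/theta, (1-p)(1-theta)/theta)
#' around the ancestral frequency p, so `theta` is the expected F_ST between
#' collections; `theta = 0` means all collections share the ancestral
#' frequency exactly.
#'
#' @param seed Integer seed; fixes every generated byte. Stage streams are
#'   derived from it (see Details).
#' @param n_genes Number of toy genes.
#' @param gene_length_bp Approximate transcribed length of each gene (UTRs +
#'   exons + introns), before the two 600 bp nontranscribed flanks.
#' @param ancestral_maf_range Length-2 numeric in (0, 1): the ancestral minor
#'   (non-reference) allele frequency of a segregating site is drawn uniformly
#'   from this range.
#' @param theta Balding-Nichols divergence in `[0, 1)`.
#' @param theta_chrom Optional named numeric vector overriding `theta` for
#'   genes on given chromosomes, e.g. `c("1" = 0.3)`; used to plant
#'   chromosome-specific (e.g. sex-linked) divergence.
#' @param collections List of [collection_spec()] objects.
#' @param coverage_mean Mean reads per site per library.
#' @param coverage_dispersion Negative-binomial size parameter; smaller means
#'   more overdispersed coverage.
#' @param error_rate Per-base miscall probability.
#' @param indel_rate Probability that a segregating site's alternate allele is
#'   an indel rather than a nucleotide.
#' @param repeat_fraction Fraction of sites given 10-100x inflated coverage,
#'   mimicking collapsed repetitive regions (exercises the coverage cap).
#' @param snp_density Fraction of gene-window sites that segregate
#'   ancestrally.
#' @param triallelic_fraction Fraction of segregating sites carrying a second
#'   alternate allele.
#' @return A validated `sim_config` list.
#' @details All random draws derive from `seed` by a fixed split: the
#'   reference genome/annotation uses `seed`, allele frequencies use
#'   `seed + 1`, and the k-th replicate library uses `seed + 2 + k`. Rerunning
#'   any stage with the same config reproduces its output bit-identically.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5,
#'                   collections = list(collection_spec("A", 12),
#'                                      collection_spec("B", 12)))
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       gene_length_bp = 600L,
                       ancestral_maf_range = c(0.05, 0.5),
                       theta = 0.1,
                       theta_chrom = NULL,
                       collections = list(
                         collection_spec("popA", 12L),
                         collection_spec("popB", 12L)),
                       coverage_mean = 100,
                       coverage_dispersion = 10,
                       error_rate = 0.001,
                       indel_rate = 0.05,
                       repeat_fraction = 0.01,
                       snp_density = 0.05,
                       triallelic_fraction = 0.05) {
  seed <- as.integer(seed)
  n_genes <- as.integer(n_genes)
  gene_length_bp <- as.integer(gene_length_bp)
  if (n_genes < 0L) stop("n_genes must be >= 0")
  if (theta < 0 || theta >= 1) stop("theta must be in [0, 1)")
  if (!is.null(theta_chrom)) {
    if (is.null(names(theta_chrom)) || any(theta_chrom < 0 | theta_chrom >= 1))
      stop("theta_chrom must be a named vector with values in [0, 1)")
  }
  if (length(ancestral_maf_range) != 2L ||
      any(ancestral_maf_range <= 0) || any(ancestral_maf_range >= 1) ||
      diff(ancestral_maf_range) < 0)
    stop("ancestral_maf_range must be an increasing pair inside (0, 1)")
  if (coverage_mean < 1) stop("coverage_mean must be >= 1")
  rates <- c(error_rate = error_rate, indel_rate = indel_rate,
             repeat_fraction = repeat_fraction, snp_density = snp_density,
             triallelic_fraction = triallelic_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad)) stop("rates must lie in [0, 1]: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (coverage_dispersion <= 0) stop("coverage_dispersion must be > 0")
  if (!length(collections) || !all(vapply(collections, inherits,
                                          logical(1), "collection_spec")))
    stop("collections must be a non-empty list of collection_spec objects")
  nms <- vapply(collections, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("collection names must be unique")
  if (gene_length_bp < 150L)
    stop("gene_length_bp too small for the minimal feature set ",
         "(need >= 150 bp for UTRs, two CDS exons and an intron)")
  structure(list(seed = seed, n_genes = n_genes,
                 gene_length_bp = gene_length_bp,
                 ancestral_maf_range = as.numeric(ancestral_maf_range),
                 theta = theta, theta_chrom = theta_chrom,
                 collections = collections,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate, indel_rate = indel_rate,
                 repeat_fraction = repeat_fraction,
                 snp_density = snp_density,
                 triallelic_fraction = triallelic_fraction),
            class = "sim_config")
}
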