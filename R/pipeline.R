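## End-to-end orchestration: YAML run configuration, per-collection filter
## cascade, pairwise comparisons, and report tables.

#' Read a YAML run configuration
#'
#' The configuration names the annotation inputs (`genome`, `gtf`, optional
#' `chrom_map`, optional `targets` BED), the collections (each with `name`,
#' replicate `files`, `n_individuals_per_replicate`, `sex`), the list of
#' `comparisons` (pairs of collection names), and the filter thresholds
#' (`min_cov`, `max_cov`, `alpha`, `cap_policy`). Relative paths are
#' resolved against the configuration file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (f in intersect(c("genome", "gtf", "chrom_map", "targets"),
                      names(cfg)))
    cfg[[f]] <- resolve(cfg[[f]])
  cfg$min_cov <- as.integer(cfg$min_cov %||% 15L)
  cfg$max_cov <- as.integer(cfg$max_cov %||% 2000L)
  cfg$alpha <- as.numeric(cfg$alpha %||% 0.05)
  cfg$cap_policy <- cfg$cap_policy %||% "exclude"
  if (!cfg$cap_policy %in% c("exclude", "truncate"))
    stop("cap_policy must be 'exclude' or 'truncate'")
  if (cfg$min_cov <= 0 || cfg$min_cov >= cfg$max_cov)
    stop("need 0 < min_cov < max_cov")
  names(cfg$collections) <-
    vapply(cfg$collections, `[[`, character(1), "name")
  for (cl in cfg$collections) {
    if (length(cl$files) < 2)
      stop("collection '", cl$name, "' needs >= 2 replicate files")
  }
  cfg$collections <- lapply(cfg$collections, function(cl) {
    cl$files <- vapply(unlist(cl$files), resolve, character(1),
                       USE.NAMES = FALSE)
    cl
  })
  for (cmp in cfg$comparisons) {
    cmp <- unlist(cmp)
    if (!all(cmp %in% names(cfg$collections)))
      stop("comparison references undefined collection: ",
           paste(setdiff(cmp, names(cfg$collections)), collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool a collection's replicate libraries through the filter cascade
#'
#' Reads each replicate readcount file, applies the coverage trim/cap per
#' library, intersects the replicates (keeping sites present in all), applies
#' the replicate-concordance chi-square filter, and sums counts. With more
#' than two replicates the intersection folds pairwise in file order.
#'
#' @param files Character vector of >= 2 replicate readcount paths.
#' @param min_cov,max_cov,cap_policy Passed to [trim_sites()].
#' @param alpha Concordance filter level.
#' @return Collection-level long-form readcount table with a `"stages"`
#'   attribute tallying sites per filter stage.
#' @export
pool_collection <- function(files, min_cov = 15L, max_cov = 2000L,
                            cap_policy = "exclude", alpha = 0.05) {
  if (length(files) < 2) stop("need >= 2 replicate files")
  reps <- lapply(files, read_readcounts)
  n_read <- vapply(reps, function(r) nrow(unique(r[, .(contig, pos)])),
                   integer(1))
  reps <- lapply(reps, trim_sites, min_cov = min_cov, max_cov = max_cov,
                 cap_policy = cap_policy)
  n_trim <- vapply(reps, function(r) nrow(unique(r[, .(contig, pos)])),
                   integer(1))
  out <- reps[[1]]
  for (k in 2:length(reps)) out <- intersect_replicates(out, reps[[k]],
                                                        alpha = alpha)
  tally <- attr(out, "tally")
  data.table::setattr(out, "stages",
                      list(sites_read = n_read, sites_trimmed = n_trim,
                           sites_shared = unname(tally["shared"]),
                           sites_concordant = unname(tally["retained"])))
  out
}

site_nid <- function(counts) {
  as.data.table(counts)[count > 0, .(nid = .N, total = sum(count),
                                     ref = ref[1]),
                        by = .(contig, pos)]
}

#' Polymorphism tally for a collection
#'
#' Counts retained sites by the number of distinct nucleotides/indels
#' segregating (nid): monomorphic sites have nid 1. The percentage
#' polymorphic is `100 * (1 - monomorphic / total)`.
#'
#' @param counts Collection-level readcount table.
#' @return List: by_nid (named counts), monomorphic, total, pct_polymorphic.
#' @export
polymorphism_summary <- function(counts) {
  s <- site_nid(counts)
  tab <- table(s$nid)
  mono <- sum(s$nid == 1L)
  total <- nrow(s)
  list(by_nid = tab, monomorphic = mono, total = total,
       pct_polymorphic = percent_polymorphic(mono, total))
}

#' Per-gene expected heterozygosity for a collection
#'
#' Site H_exp is `2 p (1 - p)` with p the reference-allele frequency among
#' the site's total coverage; the gene value averages over all of the gene's
#' retained sites (monomorphic sites included, pulling gene values toward
#' zero as in genome-wide H_exp distributions) or only polymorphic ones.
#'
#' @param counts Collection-level readcount table.
#' @param models A [build_gene_models()] object.
#' @param polymorphic_only Average over nid >= 2 sites only.
#' @return data.table: gene_id, chrom, n_sites, hexp.
#' @export
gene_hexp <- function(counts, models, polymorphic_only = FALSE) {
  s <- site_nid(counts)
  refc <- as.data.table(counts)[allele == ref,
                                .(refcount = sum(count)),
                                by = .(contig, pos)]
  s <- merge(s, refc, by = c("contig", "pos"), all.x = TRUE)
  s[is.na(refcount), refcount := 0L]
  if (polymorphic_only) s <- s[nid >= 2L]
  s[, alpha := hexp(refcount / total)]
  g <- assign_snpid(models, s$contig, s$pos)
  g <- g[!is.na(gene_id)]
  j <- merge(g, s[, .(contig, pos, alpha)], by = c("contig", "pos"))
  out <- j[, .(n_sites = .N, hexp = mean(alpha)), by = .(gene_id, chrom)]
  data.table::setkey(out, gene_id)
  out[]
}

#' Compare two collections: per-SNP and per-gene F_ST with annotation
#'
#' Builds per-SNP contingency tables for the sites shared by the two
#' collections, reduces them to reference/alternate counts, estimates the
#' per-SNP variance components and F_ST (pooled-coverage-weighted p-bar),
#' annotates each SNP (SNPID, gene, region, mutation type, consequence), and
#' aggregates gene-level F_ST as the ratio of summed components.
#'
#' @param cA,cB Collection-level readcount tables (from
#'   [pool_collection()]).
#' @param n_i,n_j Mosquitoes behind the summed counts of each collection
#'   (individuals per replicate times replicates).
#' @param models A [build_gene_models()] object.
#' @return List: `sites` (annotated per-SNP table with a, b, fst, alpha_i,
#'   alpha_j), `genes` (per-gene F_ST with chrom), `summary`
#'   (distribution summary of gene F_ST).
#' @export
compare_collections <- function(cA, cB, n_i, n_j, models) {
  ct <- build_contingency(cA, cB)
  poly <- ct[nid >= 2L & !is.na(alt)]
  poly <- poly[(ref1 + alt1) > 0 & (ref2 + alt2) > 0]
  if (!nrow(poly)) {
    return(list(sites = data.table(), genes = data.table(),
                summary = NULL))
  }
  fs <- site_fst(p_i = poly$ref1 / (poly$ref1 + poly$alt1),
                 p_j = poly$ref2 / (poly$ref2 + poly$alt2),
                 n_i = n_i, n_j = n_j,
                 cov_i = poly$ref1 + poly$alt1,
                 cov_j = poly$ref2 + poly$alt2)
  sites <- cbind(poly, fs)
  ann <- annotate_sites(models,
                        sites[, .(contig, pos, ref, alt)])
  sites <- merge(ann, sites, by = c("contig", "pos", "ref", "alt"),
                 allow.cartesian = TRUE)
  in_gene <- sites[!is.na(gene_id)]
  genes <- gene_fst(in_gene$a, in_gene$b, in_gene$gene_id)
  genes <- merge(genes,
                 unique(models$genes[, .(gene_id, chrom)]),
                 by = "gene_id", all.x = TRUE)
  summ <- if (nrow(genes))
    distribution_summary(genes$fst, kind = "fst", n_snps = nrow(in_gene))
  else NULL
  list(sites = sites, genes = genes, summary = summ)
}

#' Per-gene F_ST between the sexes of one collection
#'
#' Applies the same estimator as [compare_collections()] with the female
#' pool as collection i and the male pool as collection j, returning
#' per-gene F_ST stratified by chromosome assignment.
#'
#' @param counts_f,counts_m Collection-level readcount tables for the female
#'   and male pools; both must be present.
#' @param n_f,n_m Mosquitoes behind each pool.
#' @param models A [build_gene_models()] object.
#' @return As [compare_collections()].
#' @export
sexwise_fst <- function(counts_f, counts_m, n_f, n_m, models) {
  if (is.null(counts_f) || is.null(counts_m) ||
      !nrow(counts_f) || !nrow(counts_m))
    stop("both sex pools are required")
  compare_collections(counts_f, counts_m, n_f, n_m, models)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates every stage: gene models from GTF + FASTA, per-collection
#' trim / replicate intersection / concordance filtering, per-collection
#' polymorphism tallies and per-gene H_exp, and for each configured
#' comparison the per-SNP and per-gene F_ST tables, distribution summary,
#' gene-wise H_exp comparison, F_ST histogram, and per-chromosome gene F_ST.
#' All stages are deterministic given the inputs. When `out_dir` is given,
#' the result tables are written as TSVs along with a manifest.
#'
#' @param config A `run_config` (from [read_run_config()]) or a path to one.
#' @param out_dir Optional output directory for TSV reports.
#' @return List: `models`, `collections` (counts with stage tallies),
#'   `polymorphism` (per collection), `gene_hexp` (per collection),
#'   `comparisons` (per pair: sites, genes, summary, hexp_comparison,
#'   histogram), `tables` (report data.tables).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  models <- build_gene_models(config$gtf, config$genome,
                              chrom_map = config$chrom_map)

  colls <- list(); poly <- list(); ghexp <- list()
  for (cl in config$collections) {
    cc <- pool_collection(cl$files, min_cov = config$min_cov,
                          max_cov = config$max_cov,
                          cap_policy = config$cap_policy,
                          alpha = config$alpha)
    if (!is.null(config$targets))
      cc <- restrict_to_targets(cc, config$targets)
    colls[[cl$name]] <- cc
    poly[[cl$name]] <- polymorphism_summary(cc)
    ghexp[[cl$name]] <- gene_hexp(cc, models)
  }

  n_of <- function(name) {
    cl <- config$collections[[name]]
    cl$n_individuals_per_replicate * length(cl$files)
  }

  cmps <- list()
  for (cmp in config$comparisons) {
    cmp <- unlist(cmp)
    nm <- paste(cmp[1], cmp[2], sep = "_vs_")
    res <- compare_collections(colls[[cmp[1]]], colls[[cmp[2]]],
                               n_i = n_of(cmp[1]), n_j = n_of(cmp[2]),
                               models = models)
    hA <- ghexp[[cmp[1]]]; hB <- ghexp[[cmp[2]]]
    res$hexp_comparison <- tryCatch(
      genewise_comparison(setNames(hA$hexp, hA$gene_id),
                          setNames(hB$hexp, hB$gene_id)),
      error = function(e) NULL)
    res$histogram <- if (nrow(res$genes))
      bin_statistic(res$genes$fst, "fst") else NULL
    cmps[[nm]] <- res
  }

  tables <- list(
    polymorphism = report_polymorphism(poly),
    fst_summary = report_fst_summary(cmps),
    hexp_comparison = report_hexp_comparison(cmps))

  out <- list(models = models, collections = colls, polymorphism = poly,
              gene_hexp = ghexp, comparisons = cmps, tables = tables,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

restrict_to_targets <- function(counts, bed) {
  gr <- rtracklayer::import(bed, format = "bed")
  tg <- data.table(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  dt <- as.data.table(counts)
  hit <- tg[dt, on = .(contig, start <= pos, end >= pos), which = TRUE]
  dt[!is.na(hit)]
}

#' Polymorphism report table (monomorphic and by-nid site counts)
#'
#' One row per collection: monomorphic sites, counts of sites with 2..6+
#' segregating nucleotides/indels, total, percent polymorphic (the percent
#' is recomputed from the row's own counts).
#'
#' @param poly_list Named list of [polymorphism_summary()] results.
#' @return data.table.
#' @export
report_polymorphism <- function(poly_list) {
  rows <- lapply(names(poly_list), function(nm) {
    p <- poly_list[[nm]]
    tab <- p$by_nid
    get <- function(k) if (k %in% names(tab)) as.integer(tab[[k]]) else 0L
    data.table(collection = nm, monomorphic = p$monomorphic,
               nid2 = get("2"), nid3 = get("3"), nid4 = get("4"),
               nid5 = get("5"),
               nid6plus = sum(p$by_nid[as.integer(names(tab)) >= 6]),
               total = p$total,
               pct_polymorphic = percent_polymorphic(p$monomorphic,
                                                     p$total))
  })
  data.table::rbindlist(rows)
}

#' F_ST distribution summary table across comparisons
#'
#' One row per comparison: gene and SNP counts, mean, median, mode, SD, and
#' lower-5% / upper-95% cutoffs of the per-gene F_ST distribution.
#'
#' @param cmps Named list of [compare_collections()] results.
#' @return data.table.
#' @export
report_fst_summary <- function(cmps) {
  rows <- lapply(names(cmps), function(nm) {
    s <- cmps[[nm]]$summary
    if (is.null(s)) return(NULL)
    data.table(comparison = nm, n_genes = s$n_genes, n_snps = s$n_snps,
               mean = s$mean, median = s$median, mode = s$mode, sd = s$sd,
               low5 = s$low5, high95 = s$high95)
  })
  data.table::rbindlist(Filter(Negate(is.null), rows))
}

#' Gene-wise H_exp comparison table across comparisons
#'
#' One row per comparison: shared genes, counts where the first collection's
#' per-gene H_exp is greater/lesser, percent greater, mean difference, and
#' the paired t-test.
#'
#' @param cmps Named list of comparison results carrying `hexp_comparison`.
#' @return data.table.
#' @export
report_hexp_comparison <- function(cmps) {
  rows <- lapply(names(cmps), function(nm) {
    h <- cmps[[nm]]$hexp_comparison
    if (is.null(h)) return(NULL)
    data.table(comparison = nm, n_genes = h$n_genes,
               n_greater = h$n_greater, n_lesser = h$n_lesser,
               pct_greater = h$pct_greater, mean_diff = h$mean_diff,
               t = h$t, df = h$df, p = h$p)
  })
  data.table::rbindlist(Filter(Negate(is.null), rows))
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(dt, name) {
    if (!is.null(dt) && nrow(dt))
      data.table::fwrite(dt, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t")
  }
  w(res$tables$polymorphism, "table_polymorphism")
  w(res$tables$fst_summary, "table_fst_summary")
  w(res$tables$hexp_comparison, "table_hexp_comparison")
  for (nm in names(res$comparisons)) {
    cmp <- res$comparisons[[nm]]
    w(cmp$sites, paste0("sites_", nm))
    w(cmp$genes, paste0("genes_", nm))
  }
  stages <- lapply(res$collections, attr, "stages")
  yaml::write_yaml(list(collections = names(res$collections),
                        comparisons = names(res$comparisons),
                        stage_tallies = stages),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
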