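## Synthetic pooled exome study: toy genome + annotation, Balding-Nichols
## allele frequencies, and two-stage pooled readcount sampling.

stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% 2147483646) + 1L
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy reference genome, gene annotation and capture targets
#'
#' Builds `n_genes` two-exon genes spread over supercontigs that are assigned
#' to chromosomes 1-3 or left unmapped, writes the genome as FASTA, the gene
#' models as GTF (1-based inclusive; `exon` and `CDS` rows carrying
#' `gene_id`/`transcript_id`), capture targets covering the CDS as BED
#' (0-based half-open), and a contig-to-chromosome map as TSV. Genes occur on
#' both strands; every gene has a complete CDS (length divisible by 3) split
#' across two exons by one intron, flanked by UTRs and 600 bp nontranscribed
#' regions.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return List with paths (`fasta`, `gtf`, `bed`, `chrom_map`), the genome as
#'   a [Biostrings::DNAStringSet], and `genes`, a data.table of gene layout
#'   (gene_id, transcript_id, contig, chrom, strand, tx_start, tx_end,
#'   window_start, window_end).
#' @export
simulate_reference <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(stage_seed(config$seed, 0))

  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "genes.gtf"),
                bed = file.path(dir, "targets.bed"),
                chrom_map = file.path(dir, "chrom_map.tsv"))

  if (config$n_genes == 0L) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), paths$fasta)
    writeLines(character(0), paths$gtf)
    writeLines(character(0), paths$bed)
    data.table::fwrite(data.table(contig = character(), chrom = character()),
                       paths$chrom_map, sep = "\t")
    return(list(paths = paths, genome = Biostrings::DNAStringSet(),
                genes = data.table(), features = data.table()))
  }

  chroms <- rep(c("1", "2", "3", "unmapped"), length.out = config$n_genes)
  ntr <- 600L
  genes_per_contig <- 5L

  gene_rows <- vector("list", config$n_genes)
  feat_rows <- vector("list", config$n_genes)
  contig_seq <- list()

  ## per-chromosome supercontig counters and per-contig cursor
  ord <- order(match(chroms, c("1", "2", "3", "unmapped")))
  chroms <- chroms[ord]
  contig_of_gene <- character(config$n_genes)
  sc_index <- c("1" = 0L, "2" = 0L, "3" = 0L, unmapped = 0L)
  in_contig <- c("1" = genes_per_contig, "2" = genes_per_contig,
                 "3" = genes_per_contig, unmapped = genes_per_contig)
  cursor <- list()

  for (g in seq_len(config$n_genes)) {
    ch <- chroms[g]
    if (in_contig[[ch]] >= genes_per_contig) {
      sc_index[[ch]] <- sc_index[[ch]] + 1L
      in_contig[[ch]] <- 0L
    }
    in_contig[[ch]] <- in_contig[[ch]] + 1L
    ctg <- sprintf("chr%s_sc%02d", ch, sc_index[[ch]])
    contig_of_gene[g] <- ctg
    if (is.null(cursor[[ctg]])) cursor[[ctg]] <- 0L

    ## transcribed layout: utr_a | cdsA | intron | cdsB | utr_b
    L <- config$gene_length_bp
    utr_a <- sample(20:40, 1L)
    utr_b <- sample(20:40, 1L)
    intron <- sample(40:80, 1L)
    cds_total <- L - utr_a - utr_b - intron
    cds_total <- cds_total - (cds_total %% 3L)
    if (cds_total < 6L)
      stop("gene_length_bp leaves no room for a CDS")
    intron <- L - utr_a - utr_b - cds_total          # absorb rounding
    cdsA <- (sample(seq(3L, cds_total - 3L, by = 3L), 1L))
    cdsB <- cds_total - cdsA
    strand <- sample(c("+", "-"), 1L)

    tx_start <- cursor[[ctg]] + ntr + 201L           # 200 bp gap + flank
    tx_end <- tx_start + L - 1L
    cursor[[ctg]] <- tx_end + ntr
    window_start <- tx_start - ntr
    window_end <- tx_end + ntr

    gid <- sprintf("GENE%05d", g)
    tid <- paste0(gid, "-RA")

    ## forward-coordinate blocks
    b1 <- c(tx_start, tx_start + utr_a - 1L)                  # utr_a
    b2 <- c(b1[2] + 1L, b1[2] + cdsA)                         # cdsA
    b3 <- c(b2[2] + 1L, b2[2] + intron)                       # intron
    b4 <- c(b3[2] + 1L, b3[2] + cdsB)                         # cdsB
    b5 <- c(b4[2] + 1L, tx_end)                               # utr_b
    exon1 <- c(b1[1], b2[2]); exon2 <- c(b4[1], b5[2])
    if (strand == "-") { exon1 <- c(b1[1], b2[2]) }           # same genomic
    ## CDS phases on the coding strand: first coding exon has phase 0
    if (strand == "+") {
      phases <- c(0L, (3L - cdsA %% 3L) %% 3L)                # cdsA then cdsB
      cds_tab <- data.table(start = c(b2[1], b4[1]), end = c(b2[2], b4[2]),
                            phase = phases)
    } else {
      phases <- c(0L, (3L - cdsB %% 3L) %% 3L)                # cdsB is 5'
      cds_tab <- data.table(start = c(b4[1], b2[1]), end = c(b4[2], b2[2]),
                            phase = phases)
    }

    gene_rows[[g]] <- data.table(
      gene_id = gid, transcript_id = tid, contig = ctg, chrom = ch,
      strand = strand, tx_start = tx_start, tx_end = tx_end,
      window_start = window_start, window_end = window_end)
    feat_rows[[g]] <- rbind(
      data.table(gene_id = gid, transcript_id = tid, contig = ctg,
                 type = "exon", start = c(exon1[1], exon2[1]),
                 end = c(exon1[2], exon2[2]), strand = strand,
                 phase = NA_integer_),
      data.table(gene_id = gid, transcript_id = tid, contig = ctg,
                 type = "CDS", start = cds_tab$start, end = cds_tab$end,
                 strand = strand, phase = cds_tab$phase))
  }

  genes <- data.table::rbindlist(gene_rows)
  feats <- data.table::rbindlist(feat_rows)

  ## contig sequences sized to the furthest window (+ margin)
  contig_len <- genes[, .(len = max(window_end) + 100L), by = contig]
  seqs <- vapply(contig_len$len, rand_dna, character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, contig_len$contig))
  Biostrings::writeXStringSet(genome, paths$fasta)

  ## GTF via rtracklayer (1-based inclusive)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$contig,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$gene_id <- feats$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feats$transcript_id
  S4Vectors::mcols(gr)$phase <- feats$phase
  rtracklayer::export(gr, paths$gtf, format = "gtf")

  ## capture BED over CDS only (rtracklayer converts to 0-based half-open)
  cds <- feats[type == "CDS"]
  bed <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cds$contig, IRanges::IRanges(cds$start, cds$end)))
  rtracklayer::export(bed, paths$bed, format = "bed")

  data.table::fwrite(unique(genes[, .(contig, chrom)]), paths$chrom_map,
                     sep = "\t")

  list(paths = paths, genome = genome, genes = genes, features = feats)
}

#' Draw per-collection true allele frequencies under Balding-Nichols
#'
#' Picks segregating sites inside the gene windows (600 bp flank to 600 bp
#' flank) at density `snp_density`, draws each site's ancestral non-reference
#' frequency uniformly from `ancestral_maf_range`, and then draws every
#' collection's reference-allele frequency from
#' Beta(p(1-theta)/theta, (1-p)(1-theta)/theta) around the ancestral
#' reference frequency p (equal to p exactly when theta = 0). Alternate
#' alleles are nucleotides or indel tokens (`+SEQ` / `-SEQ`) at `indel_rate`;
#' a fraction of sites receive a second alternate allele.
#'
#' @param config A [sim_config()].
#' @param ref Result of [simulate_reference()] (gene windows and genome).
#' @return data.table with one row per segregating site: contig, pos, gene_id,
#'   chrom, ref, alt, alt2 (NA if absent), p_anc (ancestral reference-allele
#'   frequency) and one `p_<collection>` column per collection (true
#'   reference-allele frequency).
#' @export
simulate_pool_frequencies <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1))
  genes <- ref$genes
  if (!nrow(genes)) return(data.table())

  site_list <- genes[, {
    pos <- seq.int(window_start, window_end)
    keep <- runif(length(pos)) < config$snp_density
    list(pos = pos[keep])
  }, by = .(gene_id, contig, chrom)]
  if (!nrow(site_list)) return(data.table())
  sites <- site_list
  n <- nrow(sites)

  ## reference base at each site
  refbase <- character(n)
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    s <- as.character(Biostrings::extractAt(
      ref$genome[[ctg]], IRanges::IRanges(sites$pos[idx], width = 1)))
    refbase[idx] <- s
  }
  data.table::set(sites, j = "ref", value = refbase)

  bases <- c("A", "C", "G", "T")
  other <- function(excl) {
    vapply(excl, function(e) sample(setdiff(bases, e), 1L), character(1))
  }
  is_indel <- runif(n) < config$indel_rate
  ins_tok <- paste0("+", vapply(sample(1:3, n, replace = TRUE),
                                rand_dna, character(1)))
  del_tok <- paste0("-", vapply(sample(1:3, n, replace = TRUE),
                                rand_dna, character(1)))
  indel_is_ins <- runif(n) < 0.5
  alt <- other(sites$ref)
  alt[is_indel] <- ifelse(indel_is_ins[is_indel], ins_tok[is_indel],
                          del_tok[is_indel])
  data.table::set(sites, j = "alt", value = alt)
  has_alt2 <- runif(n) < config$triallelic_fraction
  alt2 <- rep(NA_character_, n)
  need <- which(has_alt2)
  if (length(need)) {
    alt2[need] <- vapply(need, function(i) {
      pool <- setdiff(bases, c(sites$ref[i], sites$alt[i]))
      sample(pool, 1L)
    }, character(1))
  }
  data.table::set(sites, j = "alt2", value = alt2)

  q0 <- runif(n, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  data.table::set(sites, j = "p_anc", value = 1 - q0)

  theta_of <- rep(config$theta, n)
  if (!is.null(config$theta_chrom)) {
    hit <- sites$chrom %in% names(config$theta_chrom)
    theta_of[hit] <- config$theta_chrom[sites$chrom[hit]]
  }

  for (cs in config$collections) {
    p <- sites$p_anc
    pc <- p
    pos_t <- theta_of > 0
    if (any(pos_t)) {
      th <- theta_of[pos_t]
      pc[pos_t] <- rbeta(sum(pos_t),
                         p[pos_t] * (1 - th) / th,
                         (1 - p[pos_t]) * (1 - th) / th)
    }
    sites[, (paste0("p_", cs$name)) := pc]
  }
  data.table::setkey(sites, contig, pos)
  sites[]
}

## sequential (conditional-binomial) multinomial sampling, vectorised over
## sites: prob is an n x k matrix of category probabilities per site
rmultinom_rows <- function(depth, prob) {
  n <- length(depth)
  k <- ncol(prob)
  out <- matrix(0L, n, k)
  remaining <- depth
  ptail <- rowSums(prob)
  for (j in seq_len(k - 1L)) {
    pj <- ifelse(ptail > 0, pmin(prob[, j] / ptail, 1), 0)
    out[, j] <- rbinom(n, remaining, pj)
    remaining <- remaining - out[, j]
    ptail <- ptail - prob[, j]
  }
  out[, k] <- remaining
  out
}

#' Simulate replicate pooled readcount tables
#'
#' Two-stage pooled sampling: for every collection, `2 * n_individuals`
#' chromosomes are drawn binomially from the collection's true allele
#' frequencies once, giving the pool frequency that all of the collection's
#' replicate libraries share; each replicate then samples reads at each site
#' at negative-binomial coverage (mean `coverage_mean`, size
#' `coverage_dispersion`), with nucleotide miscalls at `error_rate` spread
#' uniformly over the other three bases. A fixed `repeat_fraction` of sites
#' (the same sites in every library) get 10-100x inflated coverage to mimic
#' collapsed repeats. One readcount TSV per replicate library is written.
#'
#' @param config A [sim_config()].
#' @param freqs Result of [simulate_pool_frequencies()].
#' @param ref Result of [simulate_reference()].
#' @param dir Output directory.
#' @return Named list of file paths, one per library
#'   (`<collection>_rep<k>.tsv`).
#' @export
simulate_readcounts <- function(config, freqs, ref, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- ref$genes

  ## all window sites, monomorphic included
  all_sites <- if (nrow(genes)) genes[, {
    list(pos = seq.int(window_start, window_end))
  }, by = .(gene_id, contig)][, .(contig, pos)] else
    data.table(contig = character(), pos = integer())
  all_sites <- unique(all_sites)      # overlapping windows: one physical site
  data.table::setkey(all_sites, contig, pos)
  n <- nrow(all_sites)

  refbase <- character(n)
  for (ctg in unique(all_sites$contig)) {
    idx <- which(all_sites$contig == ctg)
    refbase[idx] <- as.character(Biostrings::extractAt(
      ref$genome[[ctg]], IRanges::IRanges(all_sites$pos[idx], width = 1)))
  }
  all_sites[, ref := refbase]

  ## site-level draws shared by all libraries: repeat status
  set.seed(stage_seed(config$seed, 2))
  repeat_mult <- rep(1, n)
  is_rep <- runif(n) < config$repeat_fraction
  repeat_mult[is_rep] <- runif(sum(is_rep), 10, 100)

  seg_idx <- if (nrow(freqs)) {
    all_sites[freqs[, .(contig, pos)], which = TRUE]
  } else integer(0)

  ## per-collection pool frequencies (chromosome sampling, shared by reps)
  pool <- list()
  for (cs in config$collections) {
    q_ref <- rep(1, n); q_alt <- rep(0, n); q_alt2 <- rep(0, n)
    if (length(seg_idx)) {
      pc <- freqs[[paste0("p_", cs$name)]]
      two_n <- 2L * cs$n_individuals_per_replicate
      k_ref <- rbinom(length(seg_idx), two_n, pc)
      k_rest <- two_n - k_ref
      share2 <- ifelse(is.na(freqs$alt2), 0, 0.3)
      k_alt2 <- rbinom(length(seg_idx), k_rest, share2)
      q_ref[seg_idx] <- k_ref / two_n
      q_alt[seg_idx] <- (k_rest - k_alt2) / two_n
      q_alt2[seg_idx] <- k_alt2 / two_n
    }
    pool[[cs$name]] <- list(q_ref = q_ref, q_alt = q_alt, q_alt2 = q_alt2)
  }

  alt_tok <- rep(NA_character_, n); alt2_tok <- rep(NA_character_, n)
  if (length(seg_idx)) {
    alt_tok[seg_idx] <- freqs$alt
    alt2_tok[seg_idx] <- freqs$alt2
  }
  alt_is_base <- !is.na(alt_tok) & alt_tok %in% c("A", "C", "G", "T")

  bases <- c("A", "C", "G", "T")
  e <- config$error_rate
  out_paths <- list()
  lib_no <- 0L

  for (cs in config$collections) {
    pq <- pool[[cs$name]]
    ## true per-base frequency matrix (bases + indel category)
    p_base_true <- matrix(0, n, 4L, dimnames = list(NULL, bases))
    ridx <- match(all_sites$ref, bases)
    p_base_true[cbind(seq_len(n), ridx)] <- pq$q_ref
    ai <- which(alt_is_base)
    if (length(ai)) {
      aidx <- match(alt_tok[ai], bases)
      p_base_true[cbind(ai, aidx)] <-
        p_base_true[cbind(ai, aidx)] + pq$q_alt[ai]
    }
    ii <- which(!is.na(alt_tok) & !alt_is_base)     # indel alternate
    p_indel <- rep(0, n)
    if (length(ii)) p_indel[ii] <- pq$q_alt[ii]
    a2 <- which(!is.na(alt2_tok))
    if (length(a2)) {
      a2idx <- match(alt2_tok[a2], bases)
      p_base_true[cbind(a2, a2idx)] <-
        p_base_true[cbind(a2, a2idx)] + pq$q_alt2[a2]
    }
    ## miscalls among nucleotides only
    p_base_obs <- p_base_true * (1 - e) +
      (rowSums(p_base_true) - p_base_true) * (e / 3)
    probs <- cbind(p_base_obs, indel = p_indel)

    for (r in seq_len(cs$n_replicates)) {
      lib_no <- lib_no + 1L
      set.seed(stage_seed(config$seed, 100 + lib_no))
      depth <- rnbinom(n, mu = config$coverage_mean * repeat_mult,
                       size = config$coverage_dispersion)
      counts <- rmultinom_rows(depth, probs)
      path <- file.path(dir, sprintf("%s_rep%d.tsv", cs$name, r))
      write_readcount_matrix(all_sites, counts, alt_tok, path)
      out_paths[[sprintf("%s_rep%d", cs$name, r)]] <- path
    }
  }
  out_paths
}

## internal writer used by the simulator: counts is n x 5 (A,C,G,T,indel)
write_readcount_matrix <- function(sites, counts, indel_tok, path) {
  depth <- rowSums(counts)
  keep <- depth > 0
  bases <- c("A", "C", "G", "T")
  pieces <- lapply(1:4, function(j) {
    ifelse(counts[, j] > 0, paste0(bases[j], ":", counts[, j]), "")
  })
  pieces[[5]] <- ifelse(counts[, 5] > 0,
                        paste0(indel_tok, ":", counts[, 5]), "")
  tokens <- do.call(paste, c(pieces, sep = "\t"))
  tokens <- gsub("\t+", "\t", tokens)
  tokens <- gsub("^\t|\t$", "", tokens)
  lines <- paste(sites$contig, sites$pos, sites$ref, depth, tokens,
                 sep = "\t")
  lines <- sub("\t$", "", lines)      # depth-0 rows have no tokens
  con <- file(path, open = "wb")      # "wb": byte-identical across platforms
  writeLines(c("contig\tposition\tref\tdepth\tcounts",
               lines[keep]), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Generate a complete synthetic study directory
#'
#' Convenience wrapper running [simulate_reference()],
#' [simulate_pool_frequencies()] and [simulate_readcounts()], then writing a
#' YAML run configuration that [run_pipeline()] can consume directly.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param comparisons Optional list of length-2 character vectors naming
#'   collection pairs to compare; defaults to all pairs.
#' @return List with `paths` (reference files), `libraries` (readcount TSVs),
#'   `config_file` (YAML run config), `freqs` (true frequencies, for
#'   truth-tracking) and `ref` (reference objects).
#' @export
simulate_study <- function(config, dir, comparisons = NULL) {
  ref <- simulate_reference(config, dir)
  freqs <- simulate_pool_frequencies(config, ref)
  libs <- simulate_readcounts(config, freqs, ref, dir)

  coll_cfg <- lapply(config$collections, function(cs) {
    files <- unlist(libs[sprintf("%s_rep%d", cs$name,
                                 seq_len(cs$n_replicates))],
                    use.names = FALSE)
    list(name = cs$name, files = as.list(files),
         n_individuals_per_replicate = cs$n_individuals_per_replicate,
         sex = cs$sex)
  })
  if (is.null(comparisons)) {
    nms <- vapply(config$collections, `[[`, character(1), "name")
    comparisons <- if (length(nms) >= 2)
      utils::combn(nms, 2, simplify = FALSE) else list()
  }
  run_cfg <- list(
    genome = ref$paths$fasta, gtf = ref$paths$gtf,
    chrom_map = ref$paths$chrom_map,
    collections = coll_cfg,
    comparisons = lapply(comparisons, as.list),
    min_cov = 15L, max_cov = 2000L, alpha = 0.05,
    cap_policy = "exclude")
  config_file <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(run_cfg, config_file)
  list(paths = ref$paths, libraries = libs, config_file = config_file,
       freqs = freqs, ref = ref)
}
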