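## Shared fixtures, generated in code. Heavier simulated references are
## cached for the session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

## a small reference + annotation, cached
tiny_reference <- function(seed = 5, n_genes = 8) {
  key <- sprintf("ref_%d_%d", seed, n_genes)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("poolpopgen_", key))
    cfg <- sim_config(seed = seed, n_genes = n_genes)
    .fixture_env[[key]] <- list(cfg = cfg,
                                ref = simulate_reference(cfg, dir),
                                dir = dir)
  }
  .fixture_env[[key]]
}

tiny_models <- function(seed = 5, n_genes = 8) {
  key <- sprintf("models_%d_%d", seed, n_genes)
  if (is.null(.fixture_env[[key]])) {
    fx <- tiny_reference(seed, n_genes)
    .fixture_env[[key]] <- build_gene_models(fx$ref$paths$gtf,
                                             fx$ref$paths$fasta,
                                             fx$ref$paths$chrom_map)
  }
  .fixture_env[[key]]
}

## long-form readcount table from a compact list spec:
## list("c:1" = c(A = 30, G = 10), ...)
toy_readcounts <- function(spec, ref_base = "A") {
  rows <- lapply(names(spec), function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    counts <- spec[[k]]
    data.table::data.table(contig = parts[1], pos = as.integer(parts[2]),
                           ref = ref_base, allele = names(counts),
                           count = as.integer(counts))
  })
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, contig, pos)
  out
}

## the 20-site two-replicate toy input used for filter hand-count checks
toy_filter_pair <- function() {
  mono <- function(n) c(A = n)
  r1 <- list("c:1" = mono(14),            # below min_cov in r1
             "c:2" = mono(15),            # boundary: retained
             "c:3" = mono(2001),          # above cap: excluded
             "c:4" = c(A = 1000, G = 1000),
             "c:5" = c(A = 100),          # discordant with r2 (G only)
             "c:6" = c(A = 50, G = 50),
             "c:7" = mono(30),            # r1 only
             "c:9" = c(A = 20, `+AG` = 10),
             "c:10" = c(A = 90, G = 10))  # discordant with r2
  for (p in 11:20) r1[[paste0("c:", p)]] <- mono(30)
  r2 <- list("c:2" = mono(20),
             "c:4" = c(A = 50, G = 50),
             "c:5" = c(G = 100),
             "c:6" = c(A = 50, G = 50),
             "c:8" = mono(30),            # r2 only
             "c:9" = c(A = 25, `+AG` = 5),
             "c:10" = c(A = 10, G = 90))
  for (p in 11:20) r2[[paste0("c:", p)]] <- mono(30)
  list(r1 = toy_readcounts(r1), r2 = toy_readcounts(r2))
}

## independently written scalar transcription of the F_ST equations,
## used as the dual-implementation oracle
fst_oracle <- function(p_i, p_j, n_i, n_j, cov_i = 1, cov_j = 1) {
  k <- length(p_i)
  n_i <- rep_len(n_i, k); n_j <- rep_len(n_j, k)
  cov_i <- rep_len(cov_i, k); cov_j <- rep_len(cov_j, k)
  t(vapply(seq_len(k), function(s) {
    pi_ <- p_i[s]; pj_ <- p_j[s]
    ni_ <- n_i[s]; nj_ <- n_j[s]
    pbar <- (cov_i[s] * pi_ + cov_j[s] * pj_) / (cov_i[s] + cov_j[s])
    a_i <- 2 * pi_ * (1 - pi_)
    a_j <- 2 * pj_ * (1 - pj_)
    b <- (ni_ * a_i + nj_ * a_j) / (ni_ + nj_ - 1)
    num <- 4 * ni_ * (pi_ - pbar)^2 + 4 * nj_ * (pj_ - pbar)^2 - b
    den <- 2 * (2 * ni_ * nj_ / (ni_ + nj_))
    a <- num / den
    c(a = a, b = b, fst = if (a + b == 0) NA_real_ else a / (a + b))
  }, numeric(3)))
}
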