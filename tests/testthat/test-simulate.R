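test_that("config validation rejects bad parameters", {
  cl <- list(collection_spec("A", 12), collection_spec("B", 12))
  expect_error(sim_config(theta = 1, collections = cl), "theta")
  expect_error(sim_config(error_rate = 1.5, collections = cl), "rates")
  expect_error(sim_config(gene_length_bp = 100, collections = cl),
               "feature set")
  expect_error(collection_spec("A", 12, n_replicates = 1), "concordance")
  expect_error(collection_spec("A", 0), ">= 1")
})

test_that("reference generation is seeded, seed-sensitive, handles n_genes=0", {
  d1 <- file.path(tempdir(), "refA"); d2 <- file.path(tempdir(), "refB")
  d3 <- file.path(tempdir(), "refC")
  cfg1 <- sim_config(seed = 1, n_genes = 10)
  r1 <- simulate_reference(cfg1, d1)
  r2 <- simulate_reference(cfg1, d2)
  expect_identical(readLines(r1$paths$gtf), readLines(r2$paths$gtf))
  expect_identical(readLines(r1$paths$fasta), readLines(r2$paths$fasta))
  expect_equal(length(unique(r1$genes$gene_id)), 10)
  ## every gene has CDS, both strands occur
  expect_true(all(r1$features[, any(type == "CDS"), by = gene_id]$V1))
  expect_setequal(unique(r1$features$strand), c("+", "-"))

  r3 <- simulate_reference(sim_config(seed = 2, n_genes = 10), d3)
  expect_false(identical(readLines(r1$paths$gtf), readLines(r3$paths$gtf)))

  r0 <- simulate_reference(sim_config(seed = 1, n_genes = 0),
                           file.path(tempdir(), "ref0"))
  expect_equal(nrow(r0$genes), 0)
  expect_true(file.exists(r0$paths$fasta))
})

test_that("theta=0 collections share site frequencies; high theta drives fixation", {
  fx <- tiny_reference()
  cfg0 <- sim_config(seed = 5, n_genes = 8, theta = 0)
  f0 <- simulate_pool_frequencies(cfg0, fx$ref)
  expect_equal(f0$p_popA, f0$p_popB)
  expect_equal(f0$p_popA, f0$p_anc)

  cfg99 <- sim_config(seed = 5, n_genes = 8, theta = 0.99,
                      snp_density = 0.2)
  f99 <- simulate_pool_frequencies(cfg99, fx$ref)
  near_fixed <- f99$p_popA < 0.01 | f99$p_popA > 0.99
  expect_gt(mean(near_fixed), 0.9)
})

test_that("Balding-Nichols frequencies recover theta on true frequencies", {
  ## Monte-Carlo oracle: ratio-of-sums estimate over many sites with the
  ## sampling-correction terms switched off by a huge n
  set.seed(42)
  n <- 5000
  p <- runif(n, 0.5, 0.95)
  th <- 0.2
  p1 <- rbeta(n, p * (1 - th) / th, (1 - p) * (1 - th) / th)
  p2 <- rbeta(n, p * (1 - th) / th, (1 - p) * (1 - th) / th)
  fs <- site_fst(p1, p2, 1e6, 1e6)
  expect_equal(sum(fs$a) / sum(fs$a + fs$b), th, tolerance = 0.03 / th)
})

test_that("readcount simulation is deterministic and respects the error model", {
  fx <- tiny_reference()
  cfg <- fx$cfg
  f <- simulate_pool_frequencies(cfg, fx$ref)
  dA <- file.path(tempdir(), "rcA"); dB <- file.path(tempdir(), "rcB")
  p1 <- simulate_readcounts(cfg, f, fx$ref, dA)
  p2 <- simulate_readcounts(cfg, f, fx$ref, dB)
  expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))

  ## error_rate = 0, theta = 0: monomorphic sites report only the reference
  cfg0 <- sim_config(seed = 5, n_genes = 8, theta = 0, error_rate = 0,
                     snp_density = 0, indel_rate = 0,
                     repeat_fraction = 0)
  f0 <- simulate_pool_frequencies(cfg0, fx$ref)
  d0 <- file.path(tempdir(), "rc0")
  paths0 <- simulate_readcounts(cfg0, f0, fx$ref, d0)
  rc <- read_readcounts(paths0[[1]])
  expect_true(all(rc$allele == rc$ref))
})

test_that("mean simulated coverage tracks coverage_mean", {
  cfg <- sim_config(seed = 9, n_genes = 10, coverage_mean = 50,
                    repeat_fraction = 0,
                    collections = list(collection_spec("A", 12),
                                       collection_spec("B", 12)))
  d <- file.path(tempdir(), "cov50")
  ref <- simulate_reference(cfg, d)
  f <- simulate_pool_frequencies(cfg, ref)
  paths <- simulate_readcounts(cfg, f, ref, d)
  rc <- read_readcounts(paths[[1]])
  depth <- rc[, sum(count), by = .(contig, pos)]$V1
  n_sites <- sum(ref$genes$window_end - ref$genes$window_start + 1)
  ## depth-0 sites are not written; count them as zeros
  expect_equal(sum(depth) / n_sites, 50, tolerance = 0.05)
})

test_that("replicates of one collection pass the concordance filter at ~1-alpha", {
  cfg <- sim_config(seed = 13, n_genes = 10, theta = 0.1)
  d <- file.path(tempdir(), "conc")
  ref <- simulate_reference(cfg, d)
  f <- simulate_pool_frequencies(cfg, ref)
  paths <- simulate_readcounts(cfg, f, ref, d)
  r1 <- trim_sites(read_readcounts(paths[["popA_rep1"]]))
  r2 <- trim_sites(read_readcounts(paths[["popA_rep2"]]))
  conc <- replicate_concordance(r1, r2, alpha = 0.05)
  expect_gt(mean(conc$retain), 0.95 - 0.02)
})
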