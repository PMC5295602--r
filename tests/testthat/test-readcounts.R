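test_that("readcount parsing handles simple lines, empty files and bad tokens", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tposition\tref\tdepth\tcounts",
               "chr1\t100\tA\t30\tA:30",
               "chr1\t101\tA\t30\tA:20\tG:10"), f)
  rc <- read_readcounts(f)
  s <- rc[, .(nid = .N, total = sum(count)), by = pos]
  expect_equal(s[pos == 100, nid], 1L)
  expect_equal(s[pos == 100, total], 30L)
  expect_equal(s[pos == 101, nid], 2L)

  writeLines("contig\tposition\tref\tdepth\tcounts", f)
  expect_equal(nrow(read_readcounts(f)), 0)

  writeLines(c("contig\tposition\tref\tdepth\tcounts",
               "chr1\t100\tA\t30\tQ:30"), f)
  expect_error(read_readcounts(f), "unknown allele token 'Q:30'")

  writeLines(c("contig\tposition\tref\tdepth\tcounts",
               "chr1\t100\tA\t99\tA:30"), f)
  expect_warning(read_readcounts(f), "summed")
})

test_that("round-trip write/read reproduces a simulated library byte for byte", {
  fx <- tiny_reference()
  f <- simulate_pool_frequencies(fx$cfg, fx$ref)
  d <- file.path(tempdir(), "rt")
  paths <- simulate_readcounts(fx$cfg, f, fx$ref, d)
  rc <- read_readcounts(paths[[1]])
  out <- tempfile(fileext = ".tsv")
  write_readcounts(rc, out)
  expect_identical(readLines(out), readLines(paths[[1]]))
})

test_that("coverage trim boundaries and cap policies", {
  rc <- toy_readcounts(list("c:1" = c(A = 14), "c:2" = c(A = 15),
                            "c:3" = c(A = 1500, G = 501),
                            "c:4" = c(A = 1500, G = 500)))
  tr <- trim_sites(rc)
  expect_setequal(unique(tr$pos), c(2L, 4L))     # 14 removed, 2001 excluded

  trunc <- trim_sites(rc, cap_policy = "truncate")
  expect_setequal(unique(trunc$pos), c(2L, 3L, 4L))
  expect_lte(trunc[pos == 3, sum(count)], 2000)

  ## idempotence
  expect_identical(trim_sites(tr), tr)
  expect_error(trim_sites(rc, min_cov = 100, max_cov = 50), "min_cov")
})

test_that("concordance chi-square matches hand computation and chisq.test", {
  ## identical rows: chi2 = 0, retain
  r1 <- toy_readcounts(list("c:1" = c(A = 50, G = 50)))
  r2 <- toy_readcounts(list("c:1" = c(A = 50, G = 50)))
  cc <- replicate_concordance(r1, r2)
  expect_equal(cc$chi2, 0)
  expect_true(cc$retain)

  ## complete reversal: hand-computed Pearson chi2 on the 2x2 table = 200
  r1 <- toy_readcounts(list("c:1" = c(A = 100)))
  r2 <- toy_readcounts(list("c:1" = c(G = 100)))
  cc <- replicate_concordance(r1, r2)
  expect_equal(cc$chi2, 200)
  expect_equal(cc$df, 1L)
  expect_false(cc$retain)

  ## monomorphic: df = 0, no test, retained
  r1 <- toy_readcounts(list("c:1" = c(A = 40)))
  r2 <- toy_readcounts(list("c:1" = c(A = 60)))
  cc <- replicate_concordance(r1, r2)
  expect_equal(cc$df, 0L)
  expect_true(cc$retain)

  ## random tables agree with chisq.test(correct = FALSE)
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    m1 <- rpois(k, 40) + 1L
    m2 <- rpois(k, 40) + 1L
    al <- c("A", "C", "G", "+T")[seq_len(k)]
    r1 <- toy_readcounts(setNames(list(setNames(m1, al)), "c:1"))
    r2 <- toy_readcounts(setNames(list(setNames(m2, al)), "c:1"))
    cc <- replicate_concordance(r1, r2)
    or <- suppressWarnings(chisq.test(rbind(m1, m2), correct = FALSE))
    expect_equal(cc$chi2, unname(or$statistic), tolerance = 1e-12)
    expect_equal(cc$df, unname(or$parameter))
    expect_equal(cc$p, or$p.value, tolerance = 1e-12)
  }

  ## tiny expected cells: flagged, retained rather than tested
  r1 <- toy_readcounts(list("c:1" = c(A = 200, T = 1)))
  r2 <- toy_readcounts(list("c:1" = c(A = 200)))
  cc <- replicate_concordance(r1, r2)
  expect_true(cc$flag_lowexp)
  expect_true(cc$retain)
})

test_that("replicate intersection keeps shared sites and sums counts", {
  r1 <- toy_readcounts(list("c:1" = c(A = 30), "c:2" = c(A = 10, G = 20)))
  r2 <- toy_readcounts(list("c:2" = c(A = 12, G = 24), "c:3" = c(A = 30)))
  out <- intersect_replicates(r1, r2)
  expect_equal(unique(out$pos), 2L)
  expect_equal(out[allele == "A", count], 22L)
  expect_equal(out[allele == "G", count], 44L)
  ## disjoint inputs: empty
  r3 <- toy_readcounts(list("c:9" = c(A = 30)))
  expect_equal(nrow(intersect_replicates(r1, r3)), 0)
})

test_that("collection intersection is commutative on snpid sets", {
  a <- toy_readcounts(list("c:1" = c(A = 30), "c:2" = c(A = 30),
                           "c:5" = c(A = 30)))
  b <- toy_readcounts(list("c:2" = c(A = 30), "c:5" = c(A = 30),
                           "c:7" = c(A = 30)))
  ab <- intersect_collections(a, b)
  ba <- intersect_collections(b, a)
  expect_identical(ab, ba)
  expect_equal(ab$pos, c(2L, 5L))
})

test_that("contingency alt allele is the second most common with lexical ties", {
  a <- toy_readcounts(list("c:1" = c(A = 60, G = 30, T = 1)))
  b <- toy_readcounts(list("c:1" = c(A = 60, G = 10)))
  ct <- build_contingency(a, b)
  expect_equal(ct$alt, "G")
  expect_equal(ct$nid, 3L)
  expect_equal(ct$ref1, 60L); expect_equal(ct$alt1, 30L)
  expect_equal(ct$ref2, 60L); expect_equal(ct$alt2, 10L)

  ## tie for second place: C and G both 20 -> lexicographically smallest
  a <- toy_readcounts(list("c:1" = c(A = 50, C = 10, G = 20)))
  b <- toy_readcounts(list("c:1" = c(A = 50, C = 10)))
  ct <- build_contingency(a, b)
  expect_equal(ct$alt, "C")
})

test_that("the 20-site toy input survives each filter stage by hand count", {
  toy <- toy_filter_pair()
  t1 <- trim_sites(toy$r1)
  t2 <- trim_sites(toy$r2)
  ## r1 loses pos 1 (14 < 15) and pos 3 (2001 > 2000): 19 -> 17 sites
  expect_equal(length(unique(t1$pos)), 17)
  expect_equal(length(unique(t2$pos)), 17)
  ## intersection drops the replicate-specific sites 7 and 8
  shared <- intersect_collections(t1, t2)
  expect_equal(nrow(shared), 16)
  ## concordance discards the two discordant sites 5 and 10
  out <- intersect_replicates(t1, t2)
  expect_equal(length(unique(out$pos)), 14)
  conc <- attr(out, "concordance")
  expect_setequal(conc[retain == FALSE, pos], c(5L, 10L))
  ## summed counts at the boundary site
  expect_equal(out[pos == 2, sum(count)], 35L)
})
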