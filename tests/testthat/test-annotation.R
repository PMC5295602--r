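test_that("gene models derive UTRs, introns and strand-aware flanks", {
  m <- tiny_models()
  fx <- tiny_reference()
  expect_s3_class(m, "gene_models")
  expect_equal(nrow(m$genes), 8)
  f <- m$features
  ## one intron per toy gene, between the two exons
  expect_true(all(f[, sum(kind == "intron"), by = transcript_id]$V1 == 1))
  ## NTR5 upstream of the transcript on the coding strand
  for (tid in m$transcripts$transcript_id) {
    tx <- m$transcripts[transcript_id == tid]
    ntr5 <- f[transcript_id == tid & kind == "NTR5"]
    if (tx$strand == "+") expect_lt(ntr5$end, tx$tx_start)
    else expect_gt(ntr5$start, tx$tx_end)
  }
  ## no transcript flagged incomplete in the toy build
  expect_false(any(m$transcripts$incomplete))
})

test_that("every gene-window position maps to exactly one region and lengths sum", {
  m <- tiny_models()
  g <- m$genes[1:3]
  for (k in seq_len(nrow(g))) {
    w <- seq(g$window_start[k], g$window_end[k])
    reg <- classify_region(m, rep(g$contig[k], length(w)), w)
    reg <- reg[gene_id == g$gene_id[k]]
    expect_equal(nrow(reg), length(w))          # exactly one region each
    expect_equal(anyDuplicated(reg$pos), 0)
  }
})

test_that("snpid ordering is hierarchical and deterministic", {
  m <- tiny_models()
  g <- m$genes
  ## within one gene: larger offset, larger snpid
  s <- assign_snpid(m, rep(g$contig[1], 2),
                    c(g$window_start[1] + 5, g$window_start[1] + 9))
  s <- s[gene_id == g$gene_id[1]]
  expect_lt(s$snpid[1], s$snpid[2])
  ## genes in order: all ids of an earlier gene below a later one
  s1 <- assign_snpid(m, g$contig[1], g$window_end[1])[gene_id == g$gene_id[1]]
  s2 <- assign_snpid(m, g$contig[2], g$window_start[2])[gene_id == g$gene_id[2]]
  expect_lt(s1$snpid, s2$snpid)
  ## chromosome hierarchy: chrom 1 genes before chrom 2, before unmapped
  rank <- match(g$chrom, c("1", "2", "3", "unmapped"))
  expect_true(all(diff(rank[order(g$gene_base)]) >= 0))
  ## determinism
  expect_identical(assign_snpid(m, g$contig[1], g$window_start[1] + 3),
                   assign_snpid(m, g$contig[1], g$window_start[1] + 3))
  ## intergenic positions are untracked
  expect_true(is.na(assign_snpid(m, g$contig[1], 1L)$snpid))
})

test_that("codon positions follow the coding strand", {
  ## hand-built single-exon transcripts on both strands
  dir <- file.path(tempdir(), "codon_fix")
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "g.gtf")
  set.seed(1)
  seqs <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                collapse = "")
  writeLines(c(">ctg", seqs), fa)
  gtf_lines <- c(
    paste("ctg", "toy", "exon", 101, 190, ".", "+", ".",
          'gene_id "gp"; transcript_id "gp-RA";', sep = "\t"),
    paste("ctg", "toy", "CDS", 101, 190, ".", "+", "0",
          'gene_id "gp"; transcript_id "gp-RA";', sep = "\t"),
    paste("ctg", "toy", "exon", 401, 490, ".", "-", ".",
          'gene_id "gm"; transcript_id "gm-RA";', sep = "\t"),
    paste("ctg", "toy", "CDS", 401, 490, ".", "-", "0",
          'gene_id "gm"; transcript_id "gm-RA";', sep = "\t"))
  writeLines(gtf_lines, gtf)
  m <- build_gene_models(gtf, fa)

  ## plus strand: 101,102,103 are codon positions 1,2,3 (the positions also
  ## fall in the other gene's flank, so filter to this gene)
  r <- classify_region(m, rep("ctg", 3), 101:103)[gene_id == "gp"]
  expect_equal(r[order(pos)]$region, c("codon1", "codon2", "codon3"))
  ## minus strand: brute-force enumeration of coding-strand offsets says the
  ## highest genomic coordinate (490) is the first codon position
  r2 <- classify_region(m, rep("ctg", 3), c(490, 489, 488))[gene_id == "gm"]
  expect_equal(r2[order(-pos)]$region, c("codon1", "codon2", "codon3"))
  brute <- vapply(401:490, function(p) ((490 - p) %% 3) + 1, numeric(1))
  r3 <- classify_region(m, rep("ctg", 90), 401:490)[gene_id == "gm"]
  expect_equal(r3[order(pos)]$codon_pos, as.integer(brute))
})

test_that("mutation typing follows purine/pyrimidine classes and indel tokens", {
  expect_equal(classify_mutation("A", "G"), "transition")
  expect_equal(classify_mutation("C", "T"), "transition")
  expect_equal(classify_mutation("A", "T"), "transversion")
  expect_equal(classify_mutation("G", "C"), "transversion")
  expect_equal(classify_mutation("A", "+AG"), "insertion")
  expect_equal(classify_mutation("A", "-T"), "deletion")
  expect_error(classify_mutation("A", "A"), "not a SNP")
  expect_error(classify_mutation("A", "X"), "unknown allele")
})

test_that("consequence calls match direct codon translation", {
  expect_equal(classify_consequence("GGA", 3, "G"), "silent")      # Gly>Gly
  expect_equal(classify_consequence("AAA", 1, "G"), "replacement") # Lys>Glu
  expect_equal(classify_consequence("TGG", 3, "A"), "replacement") # Trp>stop
  expect_true(is.na(classify_consequence("GNA", 2, "T")))
})

test_that("consequence agrees with brute-force translation of mutated CDS", {
  m <- tiny_models()
  tx <- m$transcripts[canonical == TRUE]
  set.seed(31)
  checked <- 0
  for (k in seq_len(nrow(tx))) {
    t1 <- tx[k]
    cds <- m$features[transcript_id == t1$transcript_id & kind == "CDS"]
    pos <- unlist(Map(seq, cds$start, cds$end))
    pos <- sample(pos, 12)
    reg <- classify_region(m, rep(t1$contig, length(pos)), pos)
    reg <- reg[transcript_id == t1$transcript_id][order(pos)]
    for (i in seq_len(nrow(reg))) {
      alt_fwd <- sample(setdiff(c("A", "C", "G", "T"), ""), 1)
      site <- data.frame(contig = t1$contig, pos = reg$pos[i],
                         ref = as.character(Biostrings::extractAt(
                           m$genome[[t1$contig]],
                           IRanges::IRanges(reg$pos[i], width = 1))),
                         alt = alt_fwd)
      if (site$ref == site$alt) next
      ann <- annotate_sites(m, site)
      ann <- ann[gene_id == t1$gene_id]
      ## brute force: substitute in the genome, re-splice, translate
      mutated <- Biostrings::replaceLetterAt(
        m$genome[[t1$contig]], reg$pos[i], site$alt)
      pieces <- as.character(Biostrings::extractAt(
        mutated, IRanges::IRanges(cds$start, cds$end)))
      cds_mut <- paste(pieces, collapse = "")
      if (t1$strand == "-")
        cds_mut <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds_mut)))
      aa_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(t1$cds_seq), no.init.codon = TRUE))
      aa_mut <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds_mut), no.init.codon = TRUE))
      expected <- if (aa_ref == aa_mut) "silent" else "replacement"
      expect_equal(ann$consequence, expected,
                   info = paste(t1$transcript_id, reg$pos[i], site$alt))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 30)
})

test_that("reverse-complementing the genome leaves calls invariant", {
  fx <- tiny_reference()
  ref <- fx$ref
  dir <- file.path(tempdir(), "mirror")
  dir.create(dir, showWarnings = FALSE)
  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))

  ## mirrored genome and annotation
  rc_genome <- Biostrings::reverseComplement(ref$genome)
  fa2 <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(rc_genome, fa2)
  f2 <- data.table::copy(ref$features)
  L <- lens[f2$contig]
  f2[, `:=`(start2 = L - end + 1L, end2 = L - start + 1L,
            strand2 = ifelse(strand == "+", "-", "+"))]
  gtf2 <- file.path(dir, "g.gtf")
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   f2$gene_id, f2$transcript_id)
  writeLines(paste(f2$contig, "toy", f2$type, f2$start2, f2$end2, ".",
                   f2$strand2, ifelse(is.na(f2$phase), ".", f2$phase),
                   attrs, sep = "\t"), gtf2)
  m1 <- build_gene_models(ref$paths$gtf, ref$paths$fasta,
                          ref$paths$chrom_map)
  m2 <- build_gene_models(gtf2, fa2, ref$paths$chrom_map)

  ## random nucleotide SNPs in original coordinates
  set.seed(77)
  g <- m1$genes
  pick <- g[sample(.N, 5)]
  for (k in seq_len(nrow(pick))) {
    w <- sample(seq(pick$window_start[k], pick$window_end[k]), 40)
    refb <- as.character(Biostrings::extractAt(
      m1$genome[[pick$contig[k]]], IRanges::IRanges(sort(w), width = 1)))
    altb <- vapply(refb, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    s1 <- data.frame(contig = pick$contig[k], pos = sort(w),
                     ref = refb, alt = altb)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    s2 <- data.frame(contig = pick$contig[k],
                     pos = lens[pick$contig[k]] - sort(w) + 1L,
                     ref = comp[refb], alt = comp[altb])
    a1 <- annotate_sites(m1, s1)[gene_id == pick$gene_id[k]][order(pos)]
    a2 <- annotate_sites(m2, s2)[gene_id == pick$gene_id[k]][order(-pos)]
    expect_equal(a1$region, a2$region)
    expect_equal(a1$consequence, a2$consequence)
    expect_equal(a1$mutation_type, a2$mutation_type)
  }
})
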