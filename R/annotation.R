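## Gene models from GTF + FASTA, hierarchical SNPID coordinates, and
## per-position classification: gene region, codon position, coding
## consequence, mutation type.

REGIONS <- c("NTR5", "UTR5", "codon1", "codon2", "codon3",
             "intron", "UTR3", "NTR3")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build gene models from a GTF annotation and genome FASTA
#'
#' Reads `exon` and `CDS` rows, derives per transcript: 5' and 3' UTRs (exon
#' minus CDS, strand-aware), introns (gaps between exons) and 600 bp
#' nontranscribed flanks (5'NTR upstream of the transcript start on the
#' coding strand, 3'NTR downstream), truncating flanks at contig edges with a
#' flag. CDS frames are computed in coding order; transcripts whose CDS
#' length is not divisible by 3, or whose GTF phases contradict the computed
#' ones, are flagged incomplete and excluded from consequence calls but kept
#' for region calls. Genes get a hierarchical order (chromosome, supercontig,
#' position) from which SNPID coordinates are assigned.
#'
#' @param gtf Path to a GTF file (1-based inclusive).
#' @param fasta Path to the genome FASTA.
#' @param chrom_map Optional data.frame/path with columns `contig`, `chrom`
#'   (values among "1","2","3","unmapped") giving the physical chromosome of
#'   each supercontig; contigs absent from the map are "unmapped".
#' @param ntr_length Nontranscribed flank length in bp (600 as in the study
#'   design).
#' @return An object of class `gene_models`: list with `features` (one row
#'   per located feature: gene_id, transcript_id, contig, chrom, strand,
#'   kind, start, end, frame, cds_before, truncated), `transcripts`
#'   (per-transcript bounds, window, canonical flag, incomplete flag, spliced
#'   CDS sequence), `genes` (per-gene window and SNPID base offset) and the
#'   genome.
#' @export
build_gene_models <- function(gtf, fasta, chrom_map = NULL,
                              ntr_length = 600L) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gtf, format = "gtf")
  md <- as.data.table(S4Vectors::mcols(gr))
  feats <- data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = md$type,
    gene_id = md$gene_id,
    transcript_id = md$transcript_id)
  feats <- feats[type %in% c("exon", "CDS")]
  if (!nrow(feats)) {
    return(structure(list(features = data.table(), transcripts = data.table(),
                          genes = data.table(), genome = genome),
                     class = "gene_models"))
  }
  if (any(!feats$contig %in% names(genome)))
    stop("GTF references contigs absent from the FASTA: ",
         paste(head(setdiff(feats$contig, names(genome))), collapse = ", "))

  cmap <- NULL
  if (!is.null(chrom_map)) {
    cmap <- if (is.character(chrom_map)) data.table::fread(chrom_map)
            else as.data.table(chrom_map)
  }
  contig_chrom <- function(ctg) {
    if (is.null(cmap)) return(rep("unmapped", length(ctg)))
    m <- cmap$chrom[match(ctg, cmap$contig)]
    ifelse(is.na(m), "unmapped", as.character(m))
  }
  clen <- setNames(Biostrings::width(genome), names(genome))

  tx_list <- split(feats, feats$transcript_id)
  feat_out <- vector("list", length(tx_list))
  tx_out <- vector("list", length(tx_list))

  for (k in seq_along(tx_list)) {
    tf <- tx_list[[k]]
    tid <- tf$transcript_id[1]
    gid <- tf$gene_id[1]
    ctg <- tf$contig[1]
    std <- tf$strand[1]
    exons <- tf[type == "exon"][order(start)]
    cds <- tf[type == "CDS"][order(start)]
    tx_start <- min(exons$start); tx_end <- max(exons$end)

    rows <- list()
    add <- function(kind, start, end, frame = NA_integer_,
                    cds_before = NA_integer_, truncated = FALSE) {
      if (end >= start)
        rows[[length(rows) + 1L]] <<- data.table(
          kind = kind, start = start, end = end, frame = frame,
          cds_before = cds_before, truncated = truncated)
    }

    ## nontranscribed flanks, strand-aware, truncated at contig edges
    up_s <- max(1L, tx_start - ntr_length); up_e <- tx_start - 1L
    dn_s <- tx_end + 1L; dn_e <- min(clen[[ctg]], tx_end + ntr_length)
    up_trunc <- (tx_start - up_s) < ntr_length
    dn_trunc <- (dn_e - tx_end) < ntr_length
    if (std == "+") {
      add("NTR5", up_s, up_e, truncated = up_trunc)
      add("NTR3", dn_s, dn_e, truncated = dn_trunc)
    } else {
      add("NTR3", up_s, up_e, truncated = up_trunc)
      add("NTR5", dn_s, dn_e, truncated = dn_trunc)
    }

    ## introns: gaps between consecutive exons
    if (nrow(exons) > 1L) {
      for (i in seq_len(nrow(exons) - 1L))
        add("intron", exons$end[i] + 1L, exons$start[i + 1L] - 1L)
    }

    incomplete <- FALSE
    cds_seq <- NA_character_
    if (nrow(cds)) {
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      ## UTRs: exonic stretches outside the CDS span
      for (i in seq_len(nrow(exons))) {
        e <- exons[i]
        if (e$start < cds_lo) {
          kind <- if (std == "+") "UTR5" else "UTR3"
          add(kind, e$start, min(e$end, cds_lo - 1L))
        }
        if (e$end > cds_hi) {
          kind <- if (std == "+") "UTR3" else "UTR5"
          add(kind, max(e$start, cds_hi + 1L), e$end)
        }
      }
      ## coding order and frames
      coding <- if (std == "+") cds else cds[order(-start)]
      lens <- coding$end - coding$start + 1L
      before <- c(0L, cumsum(lens)[-length(lens)])
      frames <- before %% 3L
      total <- sum(lens)
      if (total %% 3L != 0L) incomplete <- TRUE
      ## genomic order back, carrying coding-order bookkeeping
      ord <- order(coding$start)
      for (i in seq_along(ord)) {
        j <- ord[i]
        add("CDS", coding$start[j], coding$end[j],
            frame = frames[j], cds_before = before[j])
      }
      pieces <- as.character(Biostrings::extractAt(
        genome[[ctg]], IRanges::IRanges(coding$start, coding$end)))
      if (std == "-") pieces <- revcomp_chr(pieces)
      cds_seq <- paste(pieces, collapse = "")
    } else {
      ## no CDS at all: whole transcript treated as UTR of unknown end
      incomplete <- TRUE
      for (i in seq_len(nrow(exons)))
        add(if (std == "+") "UTR5" else "UTR3",
            exons$start[i], exons$end[i])
    }

    ft <- data.table::rbindlist(rows)
    ft[, `:=`(gene_id = gid, transcript_id = tid, contig = ctg,
              strand = std)]
    feat_out[[k]] <- ft
    tx_out[[k]] <- data.table(
      gene_id = gid, transcript_id = tid, contig = ctg, strand = std,
      tx_start = tx_start, tx_end = tx_end,
      window_start = min(ft$start), window_end = max(ft$end),
      cds_len = if (nrow(cds)) sum(cds$end - cds$start + 1L) else 0L,
      incomplete = incomplete, cds_seq = cds_seq)
  }

  features <- data.table::rbindlist(feat_out)
  transcripts <- data.table::rbindlist(tx_out)
  transcripts[, chrom := contig_chrom(contig)]
  features[transcripts, chrom := i.chrom, on = "transcript_id"]

  ## canonical transcript per gene: longest complete CDS, ties by id
  transcripts[, canonical := FALSE]
  pick <- transcripts[order(incomplete, -cds_len, transcript_id),
                      .(transcript_id = transcript_id[1]), by = gene_id]
  transcripts[pick, canonical := TRUE, on = "transcript_id"]

  ## gene table with hierarchical SNPID base offsets:
  ## chromosome -> supercontig -> gene position -> within-gene offset
  canon <- transcripts[canonical == TRUE]
  genes <- canon[, .(gene_id, transcript_id, contig, chrom, strand,
                     window_start, window_end)]
  chrom_rank <- match(genes$chrom, c("1", "2", "3", "unmapped"))
  data.table::setorderv(
    genes[, `:=`(.rank = chrom_rank)],
    c(".rank", "contig", "window_start"))
  genes[, .rank := NULL]
  wlen <- genes$window_end - genes$window_start + 1L
  genes[, gene_ord := .I]
  genes[, gene_base := cumsum(as.numeric(wlen)) - as.numeric(wlen)]

  structure(list(features = features, transcripts = transcripts,
                 genes = genes, genome = genome),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(unique(x$genes$contig)), "contigs\n")
  invisible(x)
}

#' Assign hierarchical SNPID coordinates to genomic positions
#'
#' The SNPID is a total order over tracked positions: genes are ordered by
#' chromosome assignment (1, 2, 3, unmapped), supercontig, and position in
#' the supercontig; within a gene, positions are ordered by their offset in
#' the gene window. A position inside two genes' windows yields one record
#' per gene. Positions outside every gene window get `NA` (intergenic,
#' untracked).
#'
#' @param models A [build_gene_models()] object.
#' @param contig,pos Parallel vectors of genomic positions.
#' @return data.table with columns contig, pos, gene_id, chrom, snpid
#'   (numeric; one row per position x overlapping gene).
#' @export
assign_snpid <- function(models, contig, pos) {
  q <- data.table(contig = contig, pos = as.integer(pos))
  g <- models$genes
  if (!nrow(g)) return(q[, `:=`(gene_id = NA_character_,
                                chrom = NA_character_, snpid = NA_real_)][])
  hits <- g[q, on = .(contig, window_start <= pos, window_end >= pos),
            .(contig, pos = i.pos, gene_id, chrom,
              snpid = gene_base + (i.pos - x.window_start + 1)),
            allow.cartesian = TRUE]
  hits[]
}

#' Classify positions by gene region and codon position
#'
#' Regions are 5'NTR, 5'UTR, codon1/2/3 (first, second, third codon
#' position, computed on the coding strand from CDS frames), intron, 3'UTR,
#' 3'NTR. Positions in the CDS of a transcript flagged incomplete get region
#' `"codon?"`. Classification is against the canonical transcript of each
#' overlapping gene unless `transcript_id` columns are requested via
#' `all_transcripts`.
#'
#' @param models A [build_gene_models()] object.
#' @param contig,pos Parallel position vectors.
#' @param all_transcripts If `TRUE`, classify against every transcript rather
#'   than only canonical ones.
#' @return data.table: contig, pos, gene_id, transcript_id, region,
#'   codon_index (0-based index of the codon in the spliced CDS, NA outside
#'   CDS), codon_pos (1/2/3, NA outside CDS), strand.
#' @export
classify_region <- function(models, contig, pos, all_transcripts = FALSE) {
  q <- data.table(contig = contig, pos = as.integer(pos))
  f <- models$features
  tx <- models$transcripts
  if (!all_transcripts) {
    keep_tx <- tx[canonical == TRUE, transcript_id]
    f <- f[transcript_id %in% keep_tx]
  }
  hits <- f[q, on = .(contig, start <= pos, end >= pos),
            .(contig, pos = i.pos, gene_id, transcript_id, strand,
              kind, fstart = x.start, fend = x.end, frame, cds_before),
            allow.cartesian = TRUE]
  hits <- hits[!is.na(kind)]
  hits[, region := kind]
  hits[, codon_index := NA_real_]
  hits[, codon_pos := NA_integer_]
  cdsrows <- which(hits$kind == "CDS")
  if (length(cdsrows)) {
    h <- hits[cdsrows]
    off <- ifelse(h$strand == "+", h$pos - h$fstart, h$fend - h$pos)
    coding_off <- h$cds_before + off
    cp <- (coding_off %% 3L) + 1L
    ci <- coding_off %/% 3L
    incomplete <- tx$incomplete[match(h$transcript_id, tx$transcript_id)]
    data.table::set(hits, i = cdsrows, j = "codon_pos",
                    value = as.integer(cp))
    data.table::set(hits, i = cdsrows, j = "codon_index", value = ci)
    data.table::set(hits, i = cdsrows, j = "region",
                    value = ifelse(incomplete, "codon?",
                                   paste0("codon", cp)))
  }
  hits[, c("fstart", "fend", "frame", "cds_before", "kind") := NULL]
  hits[]
}

#' Classify a substitution as transition, transversion, insertion or deletion
#'
#' Purine-purine and pyrimidine-pyrimidine changes are transitions, other
#' base changes transversions; allele tokens starting with `+`/`-` are
#' insertions/deletions.
#'
#' @param ref,alt Character vectors of reference and alternate alleles
#'   (`A`/`C`/`G`/`T` or indel tokens like `+AG`, `-T`).
#' @return Character vector among `"transition"`, `"transversion"`,
#'   `"insertion"`, `"deletion"`.
#' @export
#' @examples
#' classify_mutation(c("A", "A", "A"), c("G", "T", "+AG"))
classify_mutation <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (any(!is.na(ref) & !is.na(alt) & ref == alt))
    stop("identical ref and alt alleles: not a SNP")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  out <- rep(NA_character_, length(ref))
  ins <- !is.na(alt) & startsWith(alt, "+")
  del <- !is.na(alt) & startsWith(alt, "-")
  out[ins] <- "insertion"; out[del] <- "deletion"
  both <- !ins & !del & ref %in% names(purine) & alt %in% names(purine)
  out[both] <- ifelse(purine[ref[both]] == purine[alt[both]],
                      "transition", "transversion")
  if (any(is.na(out) & !is.na(ref) & !is.na(alt)))
    stop("unknown allele token: ",
         paste(unique(alt[is.na(out)]), collapse = ", "))
  out
}

#' Classify a codon substitution as silent or replacement
#'
#' Translates the reference codon and the codon with `alt` substituted at
#' `codon_pos` (both read on the coding strand) under the standard genetic
#' code. A change producing the same amino acid is silent; any other change,
#' including changes to or from a stop codon, is replacement.
#'
#' @param codon Reference codons (3-letter strings, coding strand).
#' @param codon_pos Position within the codon (1, 2 or 3).
#' @param alt Alternate base on the coding strand.
#' @return Character vector `"silent"`/`"replacement"`; `NA` where the codon
#'   contains an ambiguous base.
#' @export
#' @examples
#' classify_consequence("GGA", 3, "G")  # Gly -> Gly: silent
#' classify_consequence("AAA", 1, "G")  # Lys -> Glu: replacement
classify_consequence <- function(codon, codon_pos, alt) {
  n <- max(length(codon), length(codon_pos), length(alt))
  codon <- toupper(rep_len(codon, n))
  codon_pos <- rep_len(as.integer(codon_pos), n)
  alt <- toupper(rep_len(alt, n))
  if (any(!codon_pos %in% 1:3, na.rm = TRUE))
    stop("codon_pos must be 1, 2 or 3")
  code <- Biostrings::GENETIC_CODE
  mutated <- codon
  substr(mutated, codon_pos, codon_pos) <- alt
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mutated])
  out <- ifelse(is.na(aa_ref) | is.na(aa_alt), NA_character_,
                ifelse(aa_ref == aa_alt, "silent", "replacement"))
  out
}

#' Annotate sites with SNPID, region, mutation type and consequence
#'
#' Joins positions to the canonical gene models: assigns SNPIDs, gene
#' regions, codon positions, mutation types and, for coding nucleotide
#' substitutions, silent/replacement consequences (the alternate base is
#' complemented onto the coding strand for minus-strand genes). Sites in
#' overlapping genes produce one record per gene.
#'
#' @param models A [build_gene_models()] object.
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (alt may be `NA` for monomorphic sites).
#' @return data.table: contig, pos, ref, alt, gene_id, chrom, snpid, region,
#'   codon_pos, mutation_type, consequence.
#' @export
annotate_sites <- function(models, sites) {
  s <- as.data.table(sites)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(s)))
  ids <- assign_snpid(models, s$contig, s$pos)
  reg <- classify_region(models, s$contig, s$pos)
  ann <- merge(ids, reg[, .(contig, pos, gene_id, transcript_id, strand,
                            region, codon_index, codon_pos)],
               by = c("contig", "pos", "gene_id"), all.x = TRUE)
  ann <- merge(ann, s, by = c("contig", "pos"), all.x = TRUE,
               allow.cartesian = TRUE)

  ann[, mutation_type := NA_character_]
  hasalt <- !is.na(ann$alt)
  if (any(hasalt))
    data.table::set(ann, i = which(hasalt), j = "mutation_type",
                    value = classify_mutation(ann$ref[hasalt],
                                              ann$alt[hasalt]))

  ## consequences: coding nucleotide substitutions in complete transcripts
  ann[, consequence := "not_applicable"]
  tx <- models$transcripts
  cod <- which(ann$region %in% c("codon1", "codon2", "codon3") &
               !is.na(ann$alt) & ann$alt %in% c("A", "C", "G", "T"))
  if (length(cod)) {
    h <- ann[cod]
    txi <- match(h$transcript_id, tx$transcript_id)
    codon <- substr(tx$cds_seq[txi], 3 * h$codon_index + 1,
                    3 * h$codon_index + 3)
    alt_cs <- ifelse(h$strand == "-", chartr("ACGT", "TGCA", h$alt), h$alt)
    cons <- classify_consequence(codon, h$codon_pos, alt_cs)
    cons[is.na(cons)] <- "not_applicable"
    ## the "mutated" codon may equal the reference codon when the observed
    ## alt matches the reference base (should not happen for true SNPs)
    data.table::set(ann, i = cod, j = "consequence", value = cons)
  }
  ann[, c("transcript_id", "strand", "codon_index") := NULL]
  data.table::setkey(ann, contig, pos)
  ann[]
}
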