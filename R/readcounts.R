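## Readcount dialect I/O and the SNP filter cascade: coverage trim/cap,
## replicate-concordance heterogeneity chi-square, replicate and collection
## intersections, per-SNP contingency tables.

ALLELE_RE <- "^([ACGT]|[+-][ACGTN]+):([0-9]+)$"

#' Read a per-site readcount table
#'
#' The dialect is tab-separated with a header line and columns `contig`,
#' `position`, `ref`, `depth`, followed by a variable number of
#' `allele:count` pairs (`A`/`C`/`G`/`T` or indel tokens `+SEQ`/`-SEQ`).
#' Malformed lines are reported with their line number; an unknown allele
#' token is an error naming the token. When the stated depth disagrees with
#' the summed allele counts, the summed value wins with a warning.
#'
#' @param path Path to a readcount TSV.
#' @return A keyed data.table in long form: one row per (site, allele) with
#'   columns contig, pos, ref, allele, count. Attributes are not used; totals
#'   and allele numbers are recomputed by downstream steps.
#' @export
read_readcounts <- function(path) {
  lines <- readLines(path)
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), allele = character(),
                      count = integer())
  data.table::setkey(empty, contig, pos)
  if (length(lines) <= 1L) return(empty)
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 4L)
  if (length(bad))
    stop("malformed readcount line(s) at ",
         paste(bad + 1L, collapse = ", "), " in ", path)

  contig <- vapply(parts, `[[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ref <- vapply(parts, `[[`, character(1), 3L)
  depth <- as.integer(vapply(parts, `[[`, character(1), 4L))
  if (anyNA(pos) || anyNA(depth))
    stop("non-numeric position or depth in ", path, " at line(s) ",
         paste(which(is.na(pos) | is.na(depth)) + 1L, collapse = ", "))

  toks <- lapply(parts, function(p) p[-(1:4)])
  ntok <- lengths(toks)
  row_id <- rep.int(seq_along(lines), ntok)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat)) {
    ok <- grepl(ALLELE_RE, flat)
    if (any(!ok))
      stop("unknown allele token '", flat[!ok][1], "' at line ",
           row_id[!ok][1] + 1L, " in ", path)
  }
  allele <- sub(":[0-9]+$", "", flat)
  count <- as.integer(sub("^.*:", "", flat))

  dt <- data.table(contig = contig[row_id], pos = pos[row_id],
                   ref = ref[row_id], allele = allele, count = count)
  dt <- dt[count > 0]
  sums <- dt[, .(total = sum(count)), by = .(contig, pos)]
  declared <- data.table(contig = contig, pos = pos, depth = depth)
  chk <- merge(sums, declared, by = c("contig", "pos"))
  n_bad <- sum(chk$total != chk$depth)
  if (n_bad)
    warning(n_bad, " site(s) in ", path,
            " have depth differing from summed allele counts; ",
            "summed values used")
  data.table::setkey(dt, contig, pos)
  dt[]
}

#' Write a readcount table
#'
#' Inverse of [read_readcounts()]: writes the dialect bit-exactly (alleles
#' ordered A, C, G, T then indel tokens lexicographically; depth is the
#' allele-count sum).
#'
#' @param counts Long-form readcount data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_readcounts <- function(counts, path) {
  dt <- as.data.table(counts)
  ord <- function(a) {
    base <- match(a, c("A", "C", "G", "T"))
    ifelse(is.na(base), 5L, base)
  }
  dt <- dt[count > 0][order(contig, pos, ord(allele), allele)]
  rows <- dt[, .(ref = ref[1], depth = sum(count),
                 toks = paste(paste0(allele, ":", count), collapse = "\t")),
             by = .(contig, pos)]
  con <- file(path, open = "wb")
  writeLines(c("contig\tposition\tref\tdepth\tcounts",
               paste(rows$contig, rows$pos, rows$ref, rows$depth, rows$toks,
                     sep = "\t")), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Coverage trim and repetitive-region cap
#'
#' Removes sites whose total coverage is below `min_cov` (applied per
#' library, before any replicate summing) and handles sites above `max_cov`
#' by the cap policy: `"exclude"` drops them (high coverage taken as a sign
#' of collapsed repetitive DNA), `"truncate"` scales the allele counts
#' proportionally so they sum to `max_cov`.
#'
#' @param counts Long-form readcount data.table.
#' @param min_cov Minimum total site coverage (default 15; a site with 14
#'   reads is removed, one with 15 retained).
#' @param max_cov Coverage cap (default 2000).
#' @param cap_policy `"exclude"` or `"truncate"`.
#' @return Filtered readcount data.table.
#' @export
trim_sites <- function(counts, min_cov = 15L, max_cov = 2000L,
                       cap_policy = c("exclude", "truncate")) {
  cap_policy <- match.arg(cap_policy)
  if (min_cov <= 0 || max_cov <= 0 || min_cov >= max_cov)
    stop("need 0 < min_cov < max_cov")
  dt <- as.data.table(counts)
  if (!nrow(dt)) return(dt)
  dt[, total := sum(count), by = .(contig, pos)]
  dt <- dt[total >= min_cov]
  if (cap_policy == "exclude") {
    dt <- dt[total <= max_cov]
  } else if (nrow(dt)) {
    over <- dt$total > max_cov
    if (any(over)) {
      scaled <- floor(dt$count[over] * (max_cov / dt$total[over]))
      data.table::set(dt, i = which(over), j = "count",
                      value = as.integer(pmax(scaled, 0)))
      dt <- dt[count > 0]
    }
  }
  dt[, total := NULL]
  data.table::setkey(dt, contig, pos)
  dt[]
}

#' Replicate-concordance heterogeneity chi-square filter
#'
#' For every site present in both replicates, a Pearson heterogeneity
#' chi-square is computed on the 2 x nid table of allele counts, where nid is
#' the number of distinct nucleotides/indels segregating in the pooled pair,
#' with nid - 1 degrees of freedom. Sites whose allele frequencies differ
#' significantly between replicates (p < alpha) are discarded; monomorphic
#' sites (nid = 1, df = 0) are trivially retained. A replicate with zero
#' total coverage at the site discards it with reason "empty replicate".
#' Tables containing any expected cell below 1 are retained with a flag
#' (`flag_lowexp`), the statistic being unreliable there.
#'
#' No continuity correction is applied and no multiple-testing adjustment is
#' made: the filter screens each SNP on its own, so `alpha` is a per-SNP
#' false-discard rate.
#'
#' @param rc1,rc2 Long-form readcount tables of the two replicates.
#' @param alpha Significance level for discarding (default 0.05).
#' @return data.table with one row per shared site: contig, pos, nid, chi2,
#'   df, p, retain (logical), reason, flag_lowexp.
#' @export
replicate_concordance <- function(rc1, rc2, alpha = 0.05) {
  r1 <- as.data.table(rc1)[, .(count1 = sum(count)),
                           by = .(contig, pos, allele)]
  r2 <- as.data.table(rc2)[, .(count2 = sum(count)),
                           by = .(contig, pos, allele)]
  m <- merge(r1, r2, by = c("contig", "pos", "allele"), all = TRUE)
  shared <- merge(unique(r1[, .(contig, pos)]), unique(r2[, .(contig, pos)]),
                  by = c("contig", "pos"))
  m <- m[shared, on = c("contig", "pos")]
  if (!nrow(m))
    return(data.table(contig = character(), pos = integer(),
                      nid = integer(), chi2 = numeric(), df = integer(),
                      p = numeric(), retain = logical(),
                      reason = character(), flag_lowexp = logical()))
  m[is.na(count1), count1 := 0L]
  m[is.na(count2), count2 := 0L]
  m <- m[count1 + count2 > 0]

  ## vectorised Pearson chi-square over all sites at once
  site <- m[, .(n1 = sum(count1), n2 = sum(count2), nid = .N),
            by = .(contig, pos)]
  m <- site[m, on = c("contig", "pos")]
  N <- m$n1 + m$n2
  ctot <- m$count1 + m$count2
  e1 <- m$n1 * ctot / N
  e2 <- m$n2 * ctot / N
  m[, `:=`(
    contrib = ifelse(e1 > 0 & e2 > 0,
                     (count1 - e1)^2 / e1 + (count2 - e2)^2 / e2, 0),
    emin = pmin(ifelse(e1 > 0, e1, Inf), ifelse(e2 > 0, e2, Inf)))]
  stats <- m[, .(nid = nid[1], n1 = n1[1], n2 = n2[1],
                 chi2 = sum(contrib), exp_min = min(emin)),
             by = .(contig, pos)]
  stats[, df := pmax(nid - 1L, 0L)]
  empty <- stats$n1 == 0L | stats$n2 == 0L
  mono <- !empty & stats$nid <= 1L
  test <- !empty & !mono
  stats[, `:=`(p = NA_real_, retain = FALSE, reason = "empty replicate",
               flag_lowexp = FALSE)]
  if (any(mono))
    stats[which(mono), `:=`(chi2 = 0, p = 1, retain = TRUE,
                     reason = "monomorphic")]
  if (any(test)) {
    pv <- pchisq(stats$chi2[test], stats$df[test], lower.tail = FALSE)
    low <- stats$exp_min[test] < 1
    stats[which(test), `:=`(
      p = pv,
      flag_lowexp = low,
      retain = low | pv >= alpha,
      reason = ifelse(low, "low expected counts",
                      ifelse(pv >= alpha, "concordant", "discordant")))]
  }
  if (any(empty)) stats[which(empty), chi2 := NA_real_]
  stats[, c("n1", "n2", "exp_min") := NULL]
  data.table::setkey(stats, contig, pos)
  stats[]
}

#' Intersect replicate libraries of one collection
#'
#' Keeps the sites present in both (trimmed) replicate tables, applies the
#' replicate-concordance filter, and sums the replicate allele counts of the
#' retained sites into a single collection-level table.
#'
#' @param rc1,rc2 Trimmed long-form readcount tables.
#' @param alpha Concordance filter level; `NULL` skips the filter.
#' @return Long-form readcount table of summed counts; attribute
#'   `"concordance"` holds the per-site filter statistics and attribute
#'   `"tally"` the retained/discarded site counts.
#' @export
intersect_replicates <- function(rc1, rc2, alpha = 0.05) {
  conc <- replicate_concordance(rc1, rc2,
                                alpha = if (is.null(alpha)) 0 else alpha)
  keep <- if (is.null(alpha)) conc[, .(contig, pos)]
          else conc[retain == TRUE, .(contig, pos)]
  r1 <- as.data.table(rc1)[keep, on = c("contig", "pos"), nomatch = NULL]
  r2 <- as.data.table(rc2)[keep, on = c("contig", "pos"), nomatch = NULL]
  both <- rbind(r1, r2)
  out <- both[, .(count = sum(count)),
              by = .(contig, pos, ref, allele)]
  data.table::setkey(out, contig, pos)
  data.table::setattr(out, "concordance", conc)
  data.table::setattr(out, "tally",
                      c(shared = nrow(conc),
                        retained = sum(conc$retain),
                        discarded = sum(!conc$retain)))
  out[]
}

#' SNPs common to two collections
#'
#' @param cA,cB Collection-level readcount tables from
#'   [intersect_replicates()].
#' @return data.table of shared (contig, pos) keys.
#' @export
intersect_collections <- function(cA, cB) {
  a <- unique(as.data.table(cA)[, .(contig, pos)])
  b <- unique(as.data.table(cB)[, .(contig, pos)])
  out <- merge(a, b, by = c("contig", "pos"))
  data.table::setkey(out, contig, pos)
  out[]
}

#' Per-SNP contingency tables for a pair of collections
#'
#' For every site common to the two collections, pools the allele coverages
#' and determines the alternate allele as the second most common allele over
#' all pooled coverage (ties broken by the lexicographically smallest allele
#' token). Returns the reduced bi-allelic counts used by the F_ST estimator
#' together with nid, the total number of segregating nucleotides/indels.
#'
#' @param cA,cB Collection-level readcount tables.
#' @param common Optional precomputed [intersect_collections()] result.
#' @return data.table: contig, pos, ref, alt, nid, ref1, alt1, total1
#'   (collection A), ref2, alt2, total2 (collection B). `alt` is `NA` at
#'   sites monomorphic across both collections.
#' @export
build_contingency <- function(cA, cB, common = NULL) {
  if (is.null(common)) common <- intersect_collections(cA, cB)
  a <- as.data.table(cA)[common, on = c("contig", "pos"), nomatch = NULL]
  b <- as.data.table(cB)[common, on = c("contig", "pos"), nomatch = NULL]
  a <- a[, .(count1 = sum(count)), by = .(contig, pos, ref, allele)]
  b <- b[, .(count2 = sum(count)), by = .(contig, pos, ref, allele)]
  m <- merge(a, b, by = c("contig", "pos", "ref", "allele"), all = TRUE)
  m[is.na(count1), count1 := 0L]
  m[is.na(count2), count2 := 0L]

  out <- m[, {
    pooled <- count1 + count2
    o <- order(-pooled, allele)          # ties: lexicographically smallest
    al <- allele[o]; pl <- pooled[o]
    nid_ <- sum(pooled > 0)
    major <- al[1]
    alt_ <- if (nid_ >= 2L) al[2] else NA_character_
    ## bi-allelic reduction: reference vs alternate; if the reference allele
    ## carries no coverage the major allele stands in for it
    refal <- if (ref[1] %in% al[pl > 0]) ref[1] else major
    if (!is.na(alt_) && alt_ == refal) alt_ <- al[1]
    r1 <- sum(count1[allele == refal])
    r2 <- sum(count2[allele == refal])
    a1 <- if (is.na(alt_)) 0L else sum(count1[allele == alt_])
    a2 <- if (is.na(alt_)) 0L else sum(count2[allele == alt_])
    list(ref = ref[1], alt = alt_, nid = nid_,
         ref1 = r1, alt1 = a1, total1 = sum(count1),
         ref2 = r2, alt2 = a2, total2 = sum(count2))
  }, by = .(contig, pos)]
  data.table::setkey(out, contig, pos)
  out[]
}
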