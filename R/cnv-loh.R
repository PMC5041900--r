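#' Select germline heterozygous SNPs from normal-sample BAF records
#'
#' Bi-allelic SNPs whose B-allele frequency in the patient's normal sample
#' lies between `lo` and `hi` inclusive.  Zero-depth sites are skipped and
#' counted.
#'
#' @param normal_bafs BAF records from the normal sample (`chrom`, `pos`,
#'   `ref_count`, `alt_count`, optional `baf`; an optional `n_alleles`
#'   column marks multi-allelic sites for exclusion).
#' @param lo,hi inclusive BAF bounds (defaults 0.4 and 0.6).
#' @return the selected sites, with attribute `"n_zero_depth"`.
#' @export
select_het_snps <- function(normal_bafs, lo = 0.4, hi = 0.6) {
  depth <- normal_bafs$ref_count + normal_bafs$alt_count
  zero <- depth == 0
  if (any(zero))
    warning(sum(zero), " zero-depth site(s) skipped")
  x <- normal_bafs[!zero, , drop = FALSE]
  baf <- x$alt_count / (x$ref_count + x$alt_count)
  keep <- baf >= lo & baf <= hi
  if ("n_alleles" %in% names(x)) keep <- keep & x$n_alleles == 2L
  out <- x[keep, , drop = FALSE]
  out$baf <- baf[keep]
  attr(out, "n_zero_depth") <- sum(zero)
  out
}

# Recursive binary segmentation of a numeric series: split where the
# two-sample t statistic between the flanks is maximal, recurse while the
# split is significant at `alpha`.  Returns integer breakpoints (last
# index of each left part).
binary_segment <- function(d, alpha = 0.01, min_size = 5L) {
  n <- length(d)
  if (n < 2L * min_size) return(integer())
  cs <- cumsum(d); cs2 <- cumsum(d^2)
  best_t <- -Inf; best_s <- NA_integer_
  for (s in seq(min_size, n - min_size)) {
    n1 <- s; n2 <- n - s
    m1 <- cs[s] / n1; m2 <- (cs[n] - cs[s]) / n2
    ss1 <- cs2[s] - n1 * m1^2
    ss2 <- (cs2[n] - cs2[s]) - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    if (sp2 <= 0) sp2 <- .Machine$double.eps
    tt <- abs(m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    if (tt > best_t) { best_t <- tt; best_s <- s }
  }
  p <- 2 * stats::pt(-best_t, n - 2)
  if (is.na(p) || p >= alpha) return(integer())
  left <- binary_segment(d[seq_len(best_s)], alpha, min_size)
  right <- binary_segment(d[(best_s + 1L):n], alpha, min_size) + best_s
  sort(c(left, best_s, right))
}

#' Segment LOH from tumor BAF at germline heterozygous sites
#'
#' Works on the mirrored deviation `d = |BAF - 0.5|` (phase is
#' unobservable from unphased SNPs).  Each chromosome is split by
#' recursive binary segmentation (maximal two-sample t statistic between
#' flanks, recursing while `p < alpha`); segments with mean deviation at
#' least `deviation_threshold` over at least `min_snps` SNPs are flagged
#' LOH, and neighbouring LOH segments are merged.  Segments never span a
#' chromosome boundary.
#'
#' @param tumor_bafs tumor-sample BAF records at the selected het sites
#'   (`chrom`, `pos`, `baf`), sorted by (chrom, pos).
#' @param min_snps minimum informative SNPs per LOH segment (default 10).
#' @param deviation_threshold mean `|BAF - 0.5|` calling threshold
#'   (default 0.15).
#' @param alpha split significance level for the segmentation
#'   (default 0.01).
#' @return `data.frame(chrom, start, end, n_snps, mean_abs_deviation,
#'   mean_baf, is_loh, start_index, end_index)`; `start_index`/`end_index`
#'   are per-chromosome SNP indices (for boundary-recovery checks).
#'   Chromosomes with fewer than `min_snps` sites are reported in
#'   `attr(, "insufficient")`.
#' @export
segment_loh <- function(tumor_bafs, min_snps = 10L,
                        deviation_threshold = 0.15, alpha = 0.01) {
  stopifnot(all(c("chrom", "pos", "baf") %in% names(tumor_bafs)))
  out <- list(); insufficient <- character()
  for (ch in unique(tumor_bafs$chrom)) {
    x <- tumor_bafs[tumor_bafs$chrom == ch, , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    x <- x[!is.na(x$baf), , drop = FALSE]
    if (nrow(x) < min_snps) {
      insufficient <- c(insufficient, ch)
      next
    }
    d <- abs(x$baf - 0.5)
    bp <- binary_segment(d, alpha = alpha,
                         min_size = max(2L, min_snps %/% 2L))
    bounds <- cbind(c(1L, bp + 1L), c(bp, nrow(x)))
    seg <- data.frame(chrom = ch,
                      start = x$pos[bounds[, 1]], end = x$pos[bounds[, 2]],
                      n_snps = bounds[, 2] - bounds[, 1] + 1L,
                      mean_abs_deviation = vapply(seq_len(nrow(bounds)),
                        function(i) mean(d[bounds[i, 1]:bounds[i, 2]]),
                        numeric(1)),
                      mean_baf = vapply(seq_len(nrow(bounds)),
                        function(i) mean(x$baf[bounds[i, 1]:bounds[i, 2]]),
                        numeric(1)),
                      start_index = bounds[, 1], end_index = bounds[, 2],
                      stringsAsFactors = FALSE)
    seg$is_loh <- seg$mean_abs_deviation >= deviation_threshold &
      seg$n_snps >= min_snps
    # merge neighbouring LOH segments
    i <- 1L
    while (i < nrow(seg)) {
      if (seg$is_loh[i] && seg$is_loh[i + 1L]) {
        n1 <- seg$n_snps[i]; n2 <- seg$n_snps[i + 1L]
        seg$end[i] <- seg$end[i + 1L]
        seg$end_index[i] <- seg$end_index[i + 1L]
        seg$mean_abs_deviation[i] <-
          (n1 * seg$mean_abs_deviation[i] +
             n2 * seg$mean_abs_deviation[i + 1L]) / (n1 + n2)
        seg$mean_baf[i] <- (n1 * seg$mean_baf[i] +
                              n2 * seg$mean_baf[i + 1L]) / (n1 + n2)
        seg$n_snps[i] <- n1 + n2
        seg <- seg[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    out[[ch]] <- seg
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_snps = integer(), mean_abs_deviation = numeric(),
               mean_baf = numeric(), start_index = integer(),
               end_index = integer(), is_loh = logical())
  rownames(res) <- NULL
  attr(res, "insufficient") <- insufficient
  res
}

#' Call copy-number state from tumor/normal target coverage
#'
#' Median-normalizes each sample's per-target coverage, takes
#' `log2(tumor / normal)` per target, aggregates per gene, and assigns a
#' state by thresholds.  Invariant to global multiplicative scaling of
#' either sample.  Targets with zero normal coverage are masked.
#'
#' @param tumor,normal data frames with `gene`, `chrom`, `coverage`
#'   (one row per target), matched by gene.
#' @param loss_threshold log2-ratio below which a gene is a loss
#'   (default -0.4).
#' @param gain_threshold log2-ratio above which a gene is a gain
#'   (default 0.3).
#' @return `data.frame(gene, chrom, log2_ratio, state)` with attribute
#'   `"masked"` (genes masked for zero normal coverage).
#' @export
call_cnv <- function(tumor, normal, loss_threshold = -0.4,
                     gain_threshold = 0.3) {
  m <- merge(tumor[, c("gene", "chrom", "coverage")],
             normal[, c("gene", "coverage")],
             by = "gene", suffixes = c("_t", "_n"))
  masked <- m$gene[m$coverage_n == 0]
  m <- m[m$coverage_n > 0, , drop = FALSE]
  t_norm <- m$coverage_t / stats::median(m$coverage_t)
  n_norm <- m$coverage_n / stats::median(m$coverage_n)
  lr <- log2(t_norm / n_norm)
  res <- data.frame(gene = m$gene, chrom = m$chrom, log2_ratio = lr,
                    state = ifelse(lr < loss_threshold, "loss",
                                   ifelse(lr > gain_threshold, "gain",
                                          "neutral")),
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene), ]
  rownames(res) <- NULL
  attr(res, "masked") <- masked
  res
}

#' Paired comparison of per-patient CNV counts, pre vs post treatment
#'
#' Two-sided paired Student t test on per-patient differences between the
#' post-treatment CNV count (mean over nephrectomy samples) and the
#' pre-treatment (biopsy) count.  All-zero differences give p = 1.
#'
#' @param cnv_counts `data.frame(patient_id, pre, post)`.
#' @return list with `t`, `df`, `p_value`, `mean_difference`.
#' @export
compare_cnv_counts <- function(cnv_counts) {
  d <- cnv_counts$post - cnv_counts$pre
  if (length(d) < 2L) stop("need at least 2 patients")
  if (all(d == d[1])) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1, p_value = 1,
                  mean_difference = 0))
    stop("zero variance in paired differences with non-zero mean")
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(d))
}
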