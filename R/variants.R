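#' Detect homopolymer runs in a DNA sequence
#'
#' Maximal runs of an identical non-N base of at least `min_len` bases.
#' Coordinates are local to `seq`, 1-based inclusive.
#'
#' @param seq string over A/C/G/T/N.
#' @param min_len minimum run length (>= 2).
#' @return `data.frame(start, end, base)`, possibly with zero rows.
#' @export
detect_homopolymer_runs <- function(seq, min_len = 4L) {
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 2L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) && any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(setdiff(chars, c("A", "C", "G", "T", "N"))),
               collapse = ", "))
  if (!length(chars))
    return(data.frame(start = integer(), end = integer(),
                      base = character(), stringsAsFactors = FALSE))
  r <- rle(chars)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values != "N"
  data.frame(start = start[keep], end = end[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

# Distance (in bp) from the variant-affected reference span to the nearest
# base of the nearest homopolymer run of >= min_len within the flank.
# The affected span is the REF allele for SNVs/MNVs, the deleted bases
# (REF minus the shared anchor base) for deletions, and the anchor base
# for insertions.  Returns Inf when no run exists.  Distance 0 = overlap.
homopolymer_distance <- function(flank_seq, ref, alt, min_len = 4L) {
  offset <- (nchar(flank_seq) - nchar(ref)) / 2 + 1
  if (offset != floor(offset))
    stop("flank_seq must be symmetric around the REF allele")
  span <- c(offset, offset + nchar(ref) - 1L)
  if (nchar(ref) > nchar(alt) &&
      substr(ref, 1, nchar(alt)) == alt) {        # deletion: deleted bases
    span[1] <- span[1] + nchar(alt)
  } else if (nchar(alt) > nchar(ref)) {           # insertion: anchor base
    span[2] <- span[1]
  }
  runs <- detect_homopolymer_runs(flank_seq, min_len)
  if (!nrow(runs)) return(Inf)
  d <- pmax(0, pmax(runs$start - span[2], span[1] - runs$end))
  min(d)
}

#' Filter variant calls on genotype quality, VAF and homopolymer context
#'
#' Keeps calls with genotype quality >= `min_gq`, variant allele frequency
#' (summed over alternate alleles) >= `min_vaf`, and whose affected
#' reference span lies strictly more than `max_homopolymer_dist` bp away
#' from every homopolymer run of at least `hp_min_len` bp in the flanking
#' reference context.  Input order is preserved; the function is
#' idempotent.
#'
#' @param calls data frame with columns `GQ`, `VAF`, `flank_seq`, `ref`,
#'   `alt` (long format, one row per call).
#' @param min_gq genotype-quality threshold (default 60).
#' @param min_vaf VAF threshold (default 0.10).
#' @param hp_min_len homopolymer run length considered risky (default 4).
#' @param max_homopolymer_dist maximum distance (bp) to a run that still
#'   triggers exclusion (default 1; 0 = inside the run).
#' @return the retained calls, with an attribute `"removed"` giving the
#'   number removed by each criterion.
#' @export
filter_variants <- function(calls, min_gq = 60, min_vaf = 0.10,
                            hp_min_len = 4L, max_homopolymer_dist = 1L) {
  if (!nrow(calls)) {
    attr(calls, "removed") <- c(gq = 0L, vaf = 0L, homopolymer = 0L)
    return(calls)
  }
  if (any(is.na(calls$flank_seq) | calls$flank_seq == ""))
    stop("context unavailable: flanking sequence missing for ",
         sum(is.na(calls$flank_seq) | calls$flank_seq == ""), " call(s)")
  hp <- vapply(seq_len(nrow(calls)), function(i)
    homopolymer_distance(calls$flank_seq[i], calls$ref[i], calls$alt[i],
                         hp_min_len), numeric(1))
  fail_gq <- calls$GQ < min_gq
  fail_vaf <- calls$VAF < min_vaf
  fail_hp <- hp <= max_homopolymer_dist
  keep <- !(fail_gq | fail_vaf | fail_hp)
  out <- calls[keep, , drop = FALSE]
  attr(out, "removed") <- c(gq = sum(fail_gq), vaf = sum(fail_vaf),
                            homopolymer = sum(fail_hp))
  out
}

#' Classify per-patient variant sharing
#'
#' For each patient and variant key (chrom, pos, ref, alt):
#' \itemize{
#'   \item \strong{germline} — non-reference genotype in the patient's own
#'     normal sample;
#'   \item \strong{truncal} — in all of the patient's tumor samples (and
#'     not the normal);
#'   \item \strong{private} — in exactly one tumor sample;
#'   \item \strong{shared} — in more than one but not all tumor samples.
#' }
#' `tumor_specific` is TRUE when the variant is absent from the patient's
#' normal \emph{and} from every normal sample across the cohort (candidate
#' somatic mutation).  Patients without a normal sample are classified
#' against the cohort normal panel only and can never be labelled
#' germline.
#'
#' @param calls long-format filtered calls (must include `patient_id`,
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param meta sample metadata with `sample_id`, `patient_id`, `tissue`.
#' @return `data.frame(patient_id, chrom, pos, ref, alt, gene, category,
#'   tumor_specific, n_tumor_present, carriers)`.
#' @export
classify_sharing <- function(calls, meta) {
  stopifnot(all(calls$sample_id %in% meta$sample_id))
  tissue <- meta$tissue[match(calls$sample_id, meta$sample_id)]
  normals_by_patient <- tapply(meta$tissue == "normal", meta$patient_id, any)
  tumors_by_patient <- tapply(meta$tissue != "normal", meta$patient_id, sum)
  if (any(tumors_by_patient[unique(calls$patient_id)] == 0))
    stop("patient with zero tumor samples")

  cohort_normal_keys <- unique(paste(
    calls$chrom, calls$pos, calls$ref, calls$alt)[tissue == "normal"])

  res <- list()
  for (p in unique(calls$patient_id)) {
    pc <- calls[calls$patient_id == p, , drop = FALSE]
    pt <- tissue[calls$patient_id == p]
    n_tumor <- tumors_by_patient[[p]]
    key <- paste(pc$chrom, pc$pos, pc$ref, pc$alt)
    for (k in unique(key)) {
      rows <- key == k
      in_normal <- isTRUE(normals_by_patient[[p]]) && any(pt[rows] == "normal")
      tumor_carriers <- pc$sample_id[rows & pt != "normal"]
      nt <- length(unique(tumor_carriers))
      category <- if (in_normal) "germline"
        else if (nt == n_tumor) "truncal"
        else if (nt == 1L) "private"
        else "shared"
      first <- which(rows)[1]
      res[[length(res) + 1L]] <- data.frame(
        patient_id = p, chrom = pc$chrom[first], pos = pc$pos[first],
        ref = pc$ref[first], alt = pc$alt[first],
        gene = if ("gene" %in% names(pc)) pc$gene[first] else NA,
        category = category,
        tumor_specific = !in_normal && !(k %in% cohort_normal_keys),
        n_tumor_present = nt,
        carriers = paste(sort(unique(pc$sample_id[rows])), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call candidate driver mutations from consequence annotations
#'
#' A somatic variant is a candidate driver when its consequence is
#' frameshift, in-frame deletion, nonsense (stop gained), splice acceptor
#' or splice donor, or when it is a missense variant predicted at least
#' possibly damaging by SIFT or PolyPhen-2.  Everything else is a putative
#' passenger.
#'
#' @param variants data frame with `consequence`, `sift_label`,
#'   `polyphen_label` columns.
#' @param strict if TRUE (default) an unknown consequence term is an
#'   error; if FALSE it is treated as a passenger.
#' @return the input with `is_candidate_driver` (logical) and `rationale`
#'   (NA for passengers) appended.
#' @export
call_candidate_drivers <- function(variants, strict = TRUE) {
  driver_terms <- c("frameshift", "inframe_deletion", "stop_gained",
                    "splice_acceptor", "splice_donor")
  known <- c(driver_terms, "missense", "synonymous", "intron",
             "upstream", "downstream", "utr")
  unknown <- setdiff(unique(variants$consequence), known)
  if (length(unknown)) {
    if (strict)
      stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  }
  damaging <- (!is.na(variants$sift_label) &
                 variants$sift_label == "damaging") |
    (!is.na(variants$polyphen_label) &
       variants$polyphen_label %in% c("possibly_damaging",
                                      "probably_damaging"))
  is_term <- variants$consequence %in% driver_terms
  is_missense <- variants$consequence == "missense" & damaging
  variants$is_candidate_driver <- is_term | is_missense
  variants$rationale <- ifelse(is_term, variants$consequence,
                               ifelse(is_missense, "damaging_missense", NA))
  variants
}

#' Per-patient private mutation counts
#'
#' Counts, per patient, the somatic variants whose carrier set is exactly
#' one tumor sample: the biopsy count, each nephrectomy's count, and the
#' median over the nephrectomy samples.
#'
#' @param sharing output of [classify_sharing()].
#' @param meta sample metadata.
#' @return `data.frame(patient_id, biopsy_private, median_nephrectomy_private)`
#'   with attribute `"per_sample"` holding the full per-sample counts.
#' @export
count_private_mutations <- function(sharing, meta) {
  priv <- sharing[sharing$category == "private", , drop = FALSE]
  per_sample <- meta[meta$tissue != "normal",
                     c("sample_id", "patient_id", "tissue")]
  per_sample$private_count <- vapply(per_sample$sample_id, function(s)
    sum(priv$carriers == s), integer(1))
  res <- lapply(split(per_sample, per_sample$patient_id), function(d) {
    data.frame(patient_id = d$patient_id[1],
               biopsy_private = sum(d$private_count[d$tissue == "biopsy"]),
               median_nephrectomy_private =
                 stats::median(d$private_count[d$tissue == "nephrectomy"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  out
}

#' Exact / approximate two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution by full enumeration of group assignments when
#' both group sizes are at most `exact_max` (valid with ties, since the
#' enumeration conditions on the observed ranks); otherwise the normal
#' approximation with tie correction.  The two-sided p doubles the smaller
#' tail, capped at 1.
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-enumeration size switch (default 10).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- utils::combn(r, n1, sum)
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * (n1 + n2 + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Per-gene candidate-driver count comparison, biopsy vs nephrectomy
#'
#' For each gene, the number of candidate driver mutations per sample is
#' compared between all biopsy and all nephrectomy samples with the
#' two-sided Wilcoxon rank-sum test of [wilcoxon_rank_sum()].
#'
#' @param drivers classified variants with `is_candidate_driver`; rows are
#'   (patient, variant) records with `carriers` as in [classify_sharing()].
#' @param meta sample metadata.
#' @param genes optional gene universe; defaults to genes observed among
#'   drivers.  Genes with no candidate driver anywhere get `p = NA`.
#' @return `data.frame(gene, mean_biopsy, mean_nephrectomy, p_value)`.
#' @export
compare_driver_counts <- function(drivers, meta, genes = NULL) {
  drv <- drivers[drivers$is_candidate_driver, , drop = FALSE]
  tum <- meta[meta$tissue != "normal", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(drv$gene))
  counts <- matrix(0L, length(genes), nrow(tum),
                   dimnames = list(genes, tum$sample_id))
  for (i in seq_len(nrow(drv))) {
    carriers <- strsplit(drv$carriers[i], ",", fixed = TRUE)[[1]]
    carriers <- intersect(carriers, tum$sample_id)
    if (drv$gene[i] %in% genes)
      counts[drv$gene[i], carriers] <- counts[drv$gene[i], carriers] + 1L
  }
  bx <- tum$sample_id[tum$tissue == "biopsy"]
  nx <- tum$sample_id[tum$tissue == "nephrectomy"]
  res <- lapply(genes, function(g) {
    cb <- counts[g, bx]; cn <- counts[g, nx]
    p <- if (all(c(cb, cn) == 0)) NA_real_
         else wilcoxon_rank_sum(cb, cn)$p_value
    data.frame(gene = g, mean_biopsy = mean(cb), mean_nephrectomy = mean(cn),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Unpaired pooled-variance (Student) t test that tolerates degenerate
# input the way the pipeline needs: identical constant groups -> p = 1;
# zero variance with different means -> flagged error.
student_t_test <- function(x, y) {
  if (stats::sd(c(x, y)) == 0)
    return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                degenerate = TRUE))
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) != mean(y))
    stop("zero variance in both groups with unequal means")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Compare per-patient private-mutation burden, biopsy vs nephrectomy
#'
#' Unpaired two-sided Student t test of the biopsy private counts against
#' the per-patient median nephrectomy private counts, plus the per-patient
#' split (more in biopsy / more in nephrectomy / equal).
#'
#' @param private_table output of [count_private_mutations()].
#' @return list with `t`, `df`, `p_value` and `split` (named counts).
#' @export
compare_private_counts <- function(private_table) {
  if (nrow(private_table) < 2L)
    stop("need at least 2 patients")
  b <- private_table$biopsy_private
  n <- private_table$median_nephrectomy_private
  ht <- student_t_test(b, n)
  split <- c(biopsy = sum(b > n), nephrectomy = sum(b < n),
             equal = sum(b == n))
  c(ht, list(split = split))
}
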