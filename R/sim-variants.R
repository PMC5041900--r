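#' Simulate somatic and germline variant calls with sharing structure
#'
#' Per patient, draws Poisson numbers of truncal (present in all tumor
#' samples), shared (in at least two but not all) and private (exactly one
#' tumor sample) somatic variants, plus germline variants present in the
#' normal and every tumor sample of that patient.  Each call carries
#' genotype quality, allele depths, VAF, a 21-bp reference flank
#' (10 bp either side of the REF allele) and consequence / SIFT / PolyPhen
#' annotations.  A configurable fraction of somatic variants violates each
#' quality filter (low GQ, low VAF, adjacent homopolymer run) so that
#' filtering is exercised.
#'
#' @param design a [cohort_design()].
#' @return list with `calls` (one row per variant per carrying sample) and
#'   `truth` (one row per variant: patient, key, sharing class, carrier
#'   sample ids, injected filter violation).
#' @export
simulate_variants <- function(design) {
  validate_design(design)
  set.seed(stage_seed(design$seed, "variants"))

  meta <- sample_metadata(design)
  genes <- target_genes(design)
  fv <- design$filter_violation_frac
  bases <- c("A", "C", "G", "T")

  # flank with no homopolymer run of >= 4 anywhere: never three repeats
  clean_seq <- function(n) {
    s <- character(n)
    s[1] <- sample(bases, 1)
    run <- 1L
    for (i in seq_len(n)[-1]) {
      if (run >= 3L) {
        s[i] <- sample(setdiff(bases, s[i - 1]), 1)
        run <- 1L
      } else {
        s[i] <- sample(bases, 1)
        run <- if (s[i] == s[i - 1]) run + 1L else 1L
      }
    }
    paste(s, collapse = "")
  }

  consequences <- c("missense", "stop_gained", "frameshift",
                    "inframe_deletion", "splice_acceptor", "splice_donor",
                    "synonymous", "intron")
  cons_prob <- c(0.35, 0.1, 0.1, 0.05, 0.05, 0.05, 0.2, 0.1)

  one_variant <- function(patient, class, carriers, germline = FALSE) {
    g <- genes[sample.int(nrow(genes), 1), ]
    pos <- sample(g$start:g$end, 1)
    type <- sample(c("snv", "del", "ins"), 1, prob = c(0.8, 0.1, 0.1))
    if (type == "snv") {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
    } else if (type == "del") {
      ref <- paste(sample(bases, sample(2:4, 1), replace = TRUE),
                   collapse = "")
      alt <- substr(ref, 1, 1)
    } else {
      alt_len <- sample(2:4, 1)
      ref <- sample(bases, 1)
      alt <- paste0(ref, paste(sample(bases, alt_len - 1, replace = TRUE),
                               collapse = ""))
    }
    viol <- "none"
    if (!germline) {
      u <- stats::runif(1)
      if (u < fv[["gq"]]) viol <- "gq"
      else if (u < fv[["gq"]] + fv[["vaf"]]) viol <- "vaf"
      else if (u < fv[["gq"]] + fv[["vaf"]] + fv[["homopolymer"]])
        viol <- "homopolymer"
    }
    # a deletion REF that is itself a homopolymer would always violate
    while (nchar(ref) >= 4L &&
           length(unique(strsplit(ref, "")[[1]])) == 1L) {
      ref <- paste(sample(bases, nchar(ref), replace = TRUE), collapse = "")
      ref <- paste0(substr(alt, 1, 1), substr(ref, 2, nchar(ref)))
    }
    has_run <- function(s) nrow(detect_homopolymer_runs(s)) > 0
    repeat {  # no run of >= 4 anywhere in the flank, junctions included
      flank <- paste0(clean_seq(10), ref, clean_seq(10))
      if (!has_run(flank)) break
    }
    if (viol == "homopolymer") {
      # run of >= 4 ending within 1 bp of the variant-affected span
      ref1 <- substr(ref, 1, 1)
      if (nchar(ref) > nchar(alt)) {
        # deletion: span starts after the anchor; run through the anchor
        up <- paste0(substr(flank, 1, 7), strrep(ref1, 3))
      } else {
        hb <- sample(setdiff(bases, ref1), 1)
        up <- paste0(substr(flank, 1, 6), strrep(hb, 4))
      }
      flank <- paste0(up, substr(flank, 11, nchar(flank)))
    }
    cons <- sample(consequences, 1, prob = cons_prob)
    if (nchar(ref) > nchar(alt)) cons <- sample(
      c("frameshift", "inframe_deletion"), 1)
    if (nchar(alt) > nchar(ref)) cons <- "frameshift"
    sift <- polyphen <- NA_character_
    if (cons == "missense") {
      sift <- sample(c("damaging", "tolerated"), 1)
      polyphen <- sample(c("probably_damaging", "possibly_damaging",
                           "benign"), 1)
    }
    rows <- lapply(carriers, function(s) {
      depth <- round(stats::runif(1, 100, 400))
      v <- if (germline) 0.5
           else if (viol == "vaf") stats::runif(1, 0.02, 0.09)
           else stats::runif(1, 0.2, 0.6)
      ad_alt <- max(1L, round(depth * v))
      if (viol == "vaf") ad_alt <- min(ad_alt, ceiling(depth * 0.1) - 1L)
      gq <- if (viol == "gq") stats::runif(1, 10, 59)
            else stats::runif(1, 60, 99)
      data.frame(patient_id = patient, sample_id = s,
                 chrom = g$chrom, pos = pos, ref = ref, alt = alt,
                 gene = g$gene, genotype = "0/1", GQ = round(gq, 1),
                 ref_depth = depth - ad_alt, alt_depth = ad_alt,
                 VAF = ad_alt / depth, flank_seq = flank,
                 consequence = cons, sift_label = sift,
                 polyphen_label = polyphen, stringsAsFactors = FALSE)
    })
    list(calls = do.call(rbind, rows),
         truth = data.frame(patient_id = patient, chrom = g$chrom,
                            pos = pos, ref = ref, alt = alt,
                            class = class,
                            carriers = paste(carriers, collapse = ","),
                            violation = viol, stringsAsFactors = FALSE))
  }

  all_calls <- list(); all_truth <- list()
  for (p in unique(meta$patient_id)) {
    pm <- meta[meta$patient_id == p, ]
    tumors <- pm$sample_id[pm$tissue != "normal"]
    normal <- pm$sample_id[pm$tissue == "normal"]
    nt <- length(tumors)
    counts <- c(truncal = stats::rpois(1, design$n_truncal),
                shared = if (nt > 2) stats::rpois(1, design$n_shared) else 0L,
                private = stats::rpois(1, design$n_private),
                germline = stats::rpois(1, design$n_germline))
    draws <- list()
    for (i in seq_len(counts[["truncal"]]))
      draws <- c(draws, list(one_variant(p, "truncal", tumors)))
    for (i in seq_len(counts[["shared"]])) {
      k <- if (nt == 3L) 2L else sample(2:(nt - 1), 1)
      draws <- c(draws, list(one_variant(p, "shared", sample(tumors, k))))
    }
    for (i in seq_len(counts[["private"]]))
      draws <- c(draws, list(one_variant(p, "private", sample(tumors, 1))))
    for (i in seq_len(counts[["germline"]]))
      draws <- c(draws, list(one_variant(p, "germline",
                                         c(normal, tumors),
                                         germline = TRUE)))
    if (length(draws)) {
      for (i in seq_along(draws)) {
        id <- length(all_truth) + 1L
        tr <- draws[[i]]$truth; tr$draw_id <- id
        cl <- draws[[i]]$calls; cl$draw_id <- id
        all_truth[[id]] <- tr
        all_calls[[id]] <- cl
      }
    }
  }
  calls <- do.call(rbind, all_calls)
  truth <- do.call(rbind, all_truth)
  # drop whole draws whose (patient, key) collides with an earlier draw
  key <- paste(truth$patient_id, truth$chrom, truth$pos, truth$ref,
               truth$alt)
  truth <- truth[!duplicated(key), , drop = FALSE]
  calls <- calls[calls$draw_id %in% truth$draw_id, , drop = FALSE]
  truth$draw_id <- NULL
  calls$draw_id <- NULL
  rownames(calls) <- rownames(truth) <- NULL
  list(calls = calls, truth = truth)
}
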