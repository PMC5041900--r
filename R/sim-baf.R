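#' Simulate B-allele frequency tracks at germline heterozygous SNPs
#'
#' Places `baf_n_snps` heterozygous SNPs uniformly over the simulated
#' genome and draws binomial allele counts for the normal and every tumor
#' sample of each patient.  The normal allele fraction is 0.5 everywhere;
#' tumor SNPs falling inside an injected LOH segment have their expected
#' BAF shifted by `baf_shift` (e.g. +0.3 gives a mean tumor BAF of 0.8).
#' Because counts are binomial with a success probability strictly inside
#' (0, 1), the segment-level BAF never collapses fully to 0 or 1 — the
#' signature of sub-clonal LOH or residual normal cells.
#'
#' @param design a [cohort_design()]; `design$loh_segments` gives the
#'   injected segments (validated against the simulated chromosome bounds).
#' @return `data.frame(patient_id, sample_id, tissue, chrom, pos,
#'   ref_count, alt_count, baf, in_loh)`, sorted by (chrom, pos).
#' @export
simulate_baf <- function(design) {
  validate_design(design)
  set.seed(stage_seed(design$seed, "baf"))

  meta <- sample_metadata(design)
  gen <- sim_genome()
  n <- design$baf_n_snps
  chrom <- sort(sample(rep(gen$chrom, length.out = n)))
  pos <- unlist(lapply(split(seq_len(n), chrom)[unique(chrom)],
                       function(i) sort(sample.int(5e7, length(i)))),
                use.names = FALSE)
  snps <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  snps <- snps[order(match(snps$chrom, gen$chrom), snps$pos), ]

  shift <- numeric(nrow(snps))
  if (!is.null(design$loh_segments)) {
    seg <- design$loh_segments
    for (k in seq_len(nrow(seg))) {
      hit <- snps$chrom == seg$chrom[k] & snps$pos >= seg$start[k] &
        snps$pos <= seg$end[k]
      shift[hit] <- seg$baf_shift[k]
    }
  }

  rows <- lapply(seq_len(nrow(meta)), function(i) {
    is_tumor <- meta$tissue[i] != "normal"
    p <- if (is_tumor) 0.5 + shift else rep(0.5, nrow(snps))
    depth <- stats::rpois(nrow(snps), design$baf_depth)
    alt <- stats::rbinom(nrow(snps), depth, p)
    data.frame(patient_id = meta$patient_id[i],
               sample_id = meta$sample_id[i], tissue = meta$tissue[i],
               chrom = snps$chrom, pos = snps$pos,
               ref_count = depth - alt, alt_count = alt,
               baf = ifelse(depth > 0, alt / depth, NA_real_),
               in_loh = is_tumor & shift != 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-target sequencing coverage for CNV calling
#'
#' Mean on-target coverage per panel gene for the normal and each tumor
#' sample of every patient.  Tumor coverage is the normal baseline times
#' `2^logratio` for genes named in `design$cnv_gene_logratio`, with
#' multiplicative gamma noise.
#'
#' @param design a [cohort_design()].
#' @param cv coefficient of variation of the multiplicative noise.
#' @return `data.frame(patient_id, sample_id, tissue, gene, chrom,
#'   coverage)`.
#' @export
simulate_target_coverage <- function(design, cv = 0.1) {
  validate_design(design)
  set.seed(stage_seed(design$seed, "coverage"))
  meta <- sample_metadata(design)
  genes <- target_genes(design)
  lr <- stats::setNames(numeric(nrow(genes)), genes$gene)
  if (!is.null(design$cnv_gene_logratio)) {
    bad <- setdiff(names(design$cnv_gene_logratio), genes$gene)
    if (length(bad)) stop("unknown CNV genes: ", paste(bad, collapse = ", "))
    lr[names(design$cnv_gene_logratio)] <- design$cnv_gene_logratio
  }
  base <- stats::runif(nrow(genes), 1000, 6000)  # per-gene capture bias
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    is_tumor <- meta$tissue[i] != "normal"
    mu <- base * if (is_tumor) 2^lr else 1
    noise <- stats::rgamma(nrow(genes), shape = 1 / cv^2, rate = 1 / cv^2)
    data.frame(patient_id = meta$patient_id[i],
               sample_id = meta$sample_id[i], tissue = meta$tissue[i],
               gene = genes$gene, chrom = genes$chrom,
               coverage = mu * noise, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
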