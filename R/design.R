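#' Cohort design for the synthetic multi-region study generator
#'
#' Bundles every parameter of the synthetic cohort: sampling layout
#' (1 normal + 1 pre-treatment biopsy + `n_nephrectomy` post-treatment
#' nephrectomy regions per patient), the negative-binomial methylation count
#' model, the somatic variant sharing structure, and the allelic (BAF / CNV)
#' landscape.  The resulting object drives [simulate_methylation_counts()],
#' [simulate_variants()], [simulate_baf()] and [simulate_target_coverage()].
#'
#' Coordinates are 1-based inclusive throughout the package; the BED writer
#' converts to half-open 0-based at the file boundary.
#'
#' @param n_patients number of patients (default 14, the study layout).
#' @param n_nephrectomy spatially separated post-treatment samples per
#'   patient (default 3).
#' @param n_cores number of methylation cores ("loci") simulated.
#' @param n_target_genes number of panel target genes (default 48); each
#'   target gene owns `cores_per_target` promoter cores.
#' @param cores_per_target promoter methylation cores per target gene.
#' @param library_size_range range (min, max) of nephrectomy library sizes
#'   (fragments); biopsies are scaled down by `biopsy_libsize_frac`.
#' @param biopsy_libsize_frac range of the biopsy/nephrectomy library-size
#'   ratio; the default 0.25--0.5 emulates the much lower biopsy coverage
#'   typical of needle cores.
#' @param nb_dispersion negative-binomial dispersion (must be > 0); variance
#'   is `mu + dispersion * mu^2`.
#' @param patient_effect_sd SD (log2 scale) of the per-patient, per-core
#'   random methylation offset shared by all samples of a patient.
#' @param treatment_logfc named numeric vector, `core_id -> injected log2
#'   fold change` (post vs pre).  Targets must be promoter cores of target
#'   genes.  `NULL` means no injected effect.
#' @param n_truncal,n_shared,n_private,n_germline per-patient Poisson means
#'   of somatic truncal / shared / private and germline variant counts.
#' @param filter_violation_frac named vector with elements `gq`, `vaf`,
#'   `homopolymer`: fraction of simulated somatic variants that violate each
#'   quality filter (to exercise filtering).
#' @param loh_segments `data.frame(chrom, start, end, baf_shift)` of LOH
#'   segments injected into tumor BAF tracks, or `NULL`.
#' @param baf_n_snps number of germline heterozygous SNPs simulated.
#' @param baf_depth mean sequencing depth at BAF SNPs.
#' @param cnv_gene_logratio named numeric vector `gene -> log2 coverage
#'   ratio` injected into tumor target coverage, or `NULL`.
#' @param cohort label, `"sunitinib"` or `"hypoxia"`.
#' @param seed integer seed; identical seed + design gives bit-identical
#'   output from every generator.
#'
#' @return an object of class `cohort_design` (a validated list).
#' @seealso [hypoxia_design()] for the two-patient ligation control preset.
#' @export
cohort_design <- function(n_patients = 14L,
                          n_nephrectomy = 3L,
                          n_cores = 2000L,
                          n_target_genes = 48L,
                          cores_per_target = 2L,
                          library_size_range = c(5e5, 1e6),
                          biopsy_libsize_frac = c(0.25, 0.5),
                          nb_dispersion = 0.05,
                          patient_effect_sd = 0.5,
                          treatment_logfc = NULL,
                          n_truncal = 5,
                          n_shared = 3,
                          n_private = 4,
                          n_germline = 20,
                          filter_violation_frac = c(gq = 0.05, vaf = 0.05,
                                                    homopolymer = 0.05),
                          loh_segments = NULL,
                          baf_n_snps = 1000L,
                          baf_depth = 200,
                          cnv_gene_logratio = NULL,
                          cohort = c("sunitinib", "hypoxia"),
                          seed = 1L) {
  design <- list(
    n_patients = as.integer(n_patients),
    n_nephrectomy = as.integer(n_nephrectomy),
    n_cores = as.integer(n_cores),
    n_target_genes = as.integer(n_target_genes),
    cores_per_target = as.integer(cores_per_target),
    library_size_range = as.numeric(library_size_range),
    biopsy_libsize_frac = as.numeric(biopsy_libsize_frac),
    nb_dispersion = nb_dispersion,
    patient_effect_sd = patient_effect_sd,
    treatment_logfc = treatment_logfc,
    n_truncal = n_truncal,
    n_shared = n_shared,
    n_private = n_private,
    n_germline = n_germline,
    filter_violation_frac = filter_violation_frac,
    loh_segments = loh_segments,
    baf_n_snps = as.integer(baf_n_snps),
    baf_depth = baf_depth,
    cnv_gene_logratio = cnv_gene_logratio,
    cohort = match.arg(cohort),
    seed = as.integer(seed))
  class(design) <- "cohort_design"
  validate_design(design)
  design
}

#' Two-patient renal-artery-ligation control preset
#'
#' The hypoxia control set: 2 patients, each with one pre-ligation biopsy
#' and `n_nephrectomy` post-ligation samples, and no injected treatment
#' effect.  Used to show that sampling/hypoxia alone does not produce
#' differential methylation calls.
#'
#' @param ... overrides passed on to [cohort_design()].
#' @return a `cohort_design`.
#' @export
hypoxia_design <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 2L, treatment_logfc = NULL,
                   cohort = "hypoxia")
  args <- utils::modifyList(defaults, args)
  args$cohort <- "hypoxia"
  do.call(cohort_design, args)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_patients < 1L)
    stop("design requires at least one patient")
  if (design$n_nephrectomy < 1L)
    stop("at least one nephrectomy sample per patient is required")
  if (design$n_cores < 1L || design$n_target_genes < 1L)
    stop("n_cores and n_target_genes must be positive")
  if (!is.numeric(design$nb_dispersion) || design$nb_dispersion <= 0)
    stop("nb_dispersion must be a positive real")
  if (design$patient_effect_sd < 0)
    stop("patient_effect_sd must be non-negative")
  if (length(design$library_size_range) != 2L ||
      any(design$library_size_range <= 0) ||
      diff(design$library_size_range) < 0)
    stop("library_size_range must be an increasing pair of positive numbers")
  if (any(design$biopsy_libsize_frac <= 0) ||
      any(design$biopsy_libsize_frac > 1))
    stop("biopsy_libsize_frac must lie in (0, 1]")
  if (design$n_target_genes * design$cores_per_target > design$n_cores)
    stop("n_cores too small for the requested target genes")
  if (!is.null(design$treatment_logfc)) {
    if (is.null(names(design$treatment_logfc)))
      stop("treatment_logfc must be a named vector (core_id -> logFC)")
    cores <- core_table(design)
    targets <- cores$core_id[cores$is_target]
    bad <- setdiff(names(design$treatment_logfc), targets)
    if (length(bad))
      stop("treatment targets must be promoter cores of target genes; ",
           "unknown: ", paste(bad, collapse = ", "))
  }
  if (!is.null(design$loh_segments)) {
    seg <- design$loh_segments
    stopifnot(is.data.frame(seg),
              all(c("chrom", "start", "end", "baf_shift") %in% names(seg)))
    if (any(seg$end < seg$start)) stop("loh segment end < start")
    if (any(seg$baf_shift + 0.5 <= 0 | seg$baf_shift + 0.5 >= 1))
      stop("baf_shift would place the mean BAF outside (0, 1)")
    gen <- sim_genome()
    if (any(!seg$chrom %in% gen$chrom))
      stop("loh segment chromosome outside the simulated genome")
    if (any(seg$end > gen$length[match(seg$chrom, gen$chrom)]))
      stop("loh segment exceeds chromosome bounds")
  }
  fv <- design$filter_violation_frac
  if (!all(c("gq", "vaf", "homopolymer") %in% names(fv)) ||
      any(fv < 0) || any(fv > 1))
    stop("filter_violation_frac needs gq/vaf/homopolymer entries in [0, 1]")
  invisible(design)
}

# Simulated genome: a small set of chromosomes, enough to exercise
# per-chromosome logic (LOH segmentation never crosses a boundary).
sim_genome <- function() {
  data.frame(chrom = paste0("chr", 1:4),
             length = rep(5e7, 4),
             stringsAsFactors = FALSE)
}

#' Target gene panel of a design
#'
#' Deterministic panel layout: `n_target_genes` genes placed on the
#' simulated genome, 5 kb each.  The first four carry the canonical ccRCC
#' driver symbols so that reports read naturally; the rest are generic.
#'
#' @param design a `cohort_design`.
#' @return `data.frame(gene, chrom, start, end)`, 1-based inclusive.
#' @export
target_genes <- function(design) {
  n <- design$n_target_genes
  canonical <- c("VHL", "PBRM1", "BAP1", "SETD2")
  gene <- c(canonical[seq_len(min(4L, n))],
            sprintf("TGT%02d", seq_len(max(0L, n - 4L)) + 4L))
  gen <- sim_genome()
  chrom <- gen$chrom[((seq_len(n) - 1L) %% nrow(gen)) + 1L]
  idx <- (seq_len(n) - 1L) %/% nrow(gen)
  start <- 1e6 + idx * 2e5 + 1
  data.frame(gene = gene, chrom = chrom, start = start,
             end = start + 4999, stringsAsFactors = FALSE)
}

#' Methylation core annotation table of a design
#'
#' Deterministic (seed-independent) layout of the simulated methylation
#' cores.  Each target gene owns `cores_per_target` promoter cores; the
#' remaining cores alternate between non-target promoter cores and
#' non-promoter (gene body / intergenic) cores, which the core filter is
#' expected to remove.
#'
#' @param design a `cohort_design`.
#' @return `data.frame(core_id, chrom, start, end, promoter, gene,
#'   is_target)`, coordinates 1-based inclusive.
#' @export
core_table <- function(design) {
  n <- design$n_cores
  tg <- target_genes(design)
  k <- design$cores_per_target
  n_target_cores <- nrow(tg) * k
  gene <- character(n)
  promoter <- logical(n)
  is_target <- logical(n)
  gene[seq_len(n_target_cores)] <- rep(tg$gene, each = k)
  promoter[seq_len(n_target_cores)] <- TRUE
  is_target[seq_len(n_target_cores)] <- TRUE
  rest <- setdiff(seq_len(n), seq_len(n_target_cores))
  # 60% of the remaining cores are promoters of filler genes
  promoter[rest] <- (seq_along(rest) %% 5L) < 3L
  gene[rest] <- ifelse(promoter[rest],
                       sprintf("FILLER%04d", seq_along(rest)), NA)
  gen <- sim_genome()
  chrom <- gen$chrom[((seq_len(n) - 1L) %% nrow(gen)) + 1L]
  idx <- (seq_len(n) - 1L) %/% nrow(gen)
  start <- 2e7 + idx * 5000 + 1
  width <- 150L
  data.frame(core_id = sprintf("core%05d", seq_len(n)),
             chrom = chrom, start = start, end = start + width,
             promoter = promoter, gene = gene, is_target = is_target,
             stringsAsFactors = FALSE)
}

#' Sample metadata of a design
#'
#' One row per sample: patient, tissue role (normal / biopsy /
#' nephrectomy), timepoint (pre / post; NA for normals) and cohort label.
#'
#' @param design a `cohort_design`.
#' @return `data.frame(sample_id, patient_id, tissue, timepoint, cohort)`.
#' @export
sample_metadata <- function(design) {
  pats <- sprintf("P%02d", seq_len(design$n_patients))
  rows <- lapply(pats, function(p) {
    neph <- sprintf("%s_Nx%d", p, seq_len(design$n_nephrectomy))
    data.frame(
      sample_id = c(paste0(p, "_N"), paste0(p, "_Bx"), neph),
      patient_id = p,
      tissue = c("normal", "biopsy", rep("nephrectomy", design$n_nephrectomy)),
      timepoint = c(NA, "pre", rep("post", design$n_nephrectomy)),
      cohort = design$cohort,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Stage-specific child seed derived from the design seed; fixed offsets so
# each generator is reproducible when re-run in isolation.
stage_seed <- function(seed, stage) {
  offsets <- c(methylation = 1000L, variants = 2000L, baf = 3000L,
               coverage = 4000L, pipeline = 5000L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
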