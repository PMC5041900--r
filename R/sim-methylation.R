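#' Simulate MethylCap-seq fragment counts for a cohort
#'
#' Draws a per-core by per-tumor-sample matrix of negative-binomial
#' fragment counts with the structure the downstream analysis assumes:
#' per-sample library sizes (biopsies deliberately shallow), a per-core
#' baseline abundance, a per-patient per-core random offset (log2 scale)
#' shared by all samples of a patient, and an injected treatment log2 fold
#' change on designated target cores (post vs pre).
#'
#' The count mean is
#' `mu_gi = libsize_i * base_g * 2^(patient_effect_gp + treat_i * logFC_g)`
#' and counts are `NB(mu, dispersion)` with variance `mu + phi * mu^2`.
#' Normal tissue is not methylome-profiled (only tumor samples enter the
#' matrix), matching the paired biopsy/nephrectomy analysis.
#'
#' @param design a [cohort_design()].
#' @return a list with
#'   \describe{
#'     \item{counts}{integer matrix, cores x tumor samples, with
#'       `attr(counts, "lib_size")` the drawn target library sizes.}
#'     \item{meta}{sample metadata (tumor samples only).}
#'     \item{cores}{core annotation table ([core_table()]).}
#'     \item{truth}{list with `logfc` (named per-core injected log2 FC)
#'       and the design parameters used.}
#'   }
#' @export
simulate_methylation_counts <- function(design) {
  validate_design(design)
  if (design$n_patients < 2L)
    stop("methylation simulation requires at least 2 patients")
  set.seed(stage_seed(design$seed, "methylation"))

  meta <- sample_metadata(design)
  meta <- meta[meta$tissue != "normal", , drop = FALSE]
  cores <- core_table(design)
  G <- design$n_cores
  S <- nrow(meta)

  lo <- design$library_size_range[1]; hi <- design$library_size_range[2]
  lib <- stats::runif(S, lo, hi)
  is_bx <- meta$tissue == "biopsy"
  lib[is_bx] <- lib[is_bx] *
    stats::runif(sum(is_bx), design$biopsy_libsize_frac[1],
                 design$biopsy_libsize_frac[2])

  base <- stats::rgamma(G, shape = 2, rate = 2)
  base <- base / sum(base)

  pats <- unique(meta$patient_id)
  pe <- matrix(stats::rnorm(G * length(pats), sd = design$patient_effect_sd),
               nrow = G, dimnames = list(NULL, pats))

  lfc <- stats::setNames(numeric(G), cores$core_id)
  if (!is.null(design$treatment_logfc))
    lfc[names(design$treatment_logfc)] <- design$treatment_logfc

  treat <- as.numeric(meta$timepoint == "post")
  mu <- matrix(0, G, S)
  for (j in seq_len(S)) {
    mu[, j] <- lib[j] * base *
      2^(pe[, meta$patient_id[j]] + treat[j] * lfc)
  }
  counts <- matrix(stats::rnbinom(G * S, mu = mu,
                                  size = 1 / design$nb_dispersion),
                   nrow = G,
                   dimnames = list(cores$core_id, meta$sample_id))
  attr(counts, "lib_size") <- stats::setNames(lib, meta$sample_id)
  truth <- list(logfc = lfc,
                patient_effect_sd = design$patient_effect_sd,
                nb_dispersion = design$nb_dispersion)
  list(counts = counts, meta = meta, cores = cores, truth = truth)
}
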