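#' Filter methylation cores for analysis
#'
#' Keeps cores annotated to promoter regions (including exon 1) with an
#' average coverage of at least one mapped fragment per core across the
#' samples.  Low-coverage loci lack power and would only inflate the
#' number of hypotheses tested.
#'
#' @param counts cores x samples count matrix (rownames = core ids).
#' @param cores core annotation with `core_id` and `promoter`.
#' @param min_mean minimum mean count (default 1, inclusive).
#' @return the filtered matrix, with attribute `"removed"` =
#'   `c(non_promoter = ..., low_coverage = ...)`.
#' @export
filter_cores <- function(counts, cores, min_mean = 1) {
  promoter <- cores$promoter[match(rownames(counts), cores$core_id)]
  if (any(is.na(promoter)))
    stop("counts contain cores absent from the annotation")
  mean_ok <- rowMeans(counts) >= min_mean
  keep <- promoter & mean_ok
  if (!any(keep)) stop("no analyzable cores")
  out <- counts[keep, , drop = FALSE]
  attr(out, "lib_size") <- attr(counts, "lib_size")
  attr(out, "removed") <- c(non_promoter = sum(!promoter),
                            low_coverage = sum(promoter & !mean_ok))
  out
}

#' Log2 counts per million
#'
#' `x_gi = log2((y_gi + 0.5) / (R_i + 1) * 1e6)` with `R_i` the library
#' size (column sums unless supplied); the half-count offset keeps zeros
#' finite.
#'
#' @param counts cores x samples count matrix.
#' @param lib_size optional per-sample library sizes; defaults to the
#'   `"lib_size"` attribute, then to column sums.
#' @return numeric matrix of the same shape.
#' @export
logcpm <- function(counts, lib_size = NULL) {
  if (is.null(lib_size)) lib_size <- attr(counts, "lib_size")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("zero library size")
  t(log2(t(counts + 0.5) / (lib_size + 1) * 1e6))
}

#' Quantile normalization
#'
#' Replaces each column by the cross-column mean of the order statistics
#' at each rank, so every column acquires exactly the same empirical
#' distribution (identical sorted value vectors).  Ties are resolved
#' deterministically by original row order (`ties = "split"`, the
#' default), which preserves the exact distributional identity; with
#' `ties = "average"` tied entries instead receive the mean of their tied
#' reference values, which equalises ties within a column but makes the
#' sorted columns only approximately identical when tie patterns differ
#' across columns.
#'
#' @param x numeric matrix without missing values.
#' @param ties `"split"` or `"average"`.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x, ties = c("split", "average")) {
  ties <- match.arg(ties)
  stopifnot(is.matrix(x), !anyNA(x))
  ref <- rowMeans(apply(x, 2, sort, method = "radix"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j], method = "radix")       # stable: row order breaks ties
    if (ties == "split") {
      out[o, j] <- ref
    } else {
      xs <- x[o, j]                 # tied groups get their mean ref value
      out[o, j] <- stats::ave(ref, match(xs, unique(xs)), FUN = mean)
    }
  }
  out
}

#' Precision weights from the empirical mean-variance trend
#'
#' voom-style observation weights: per-core ordinary least squares on the
#' log-CPM matrix, a lowess trend of `sqrt(residual sd)` against the
#' average log-count, and per-observation predicted standard deviations
#' read off the trend at each fitted value; the weight is the predicted
#' standard deviation to the power -4.
#'
#' @param y log-CPM matrix (cores x samples).
#' @param design design matrix (samples x coefficients), full rank.
#' @param lib_size optional per-sample library sizes.  When supplied, the
#'   trend is fitted and evaluated on the log-count scale (fitted log-CPM
#'   shifted by each sample's log library size), so that the same
#'   abundance in a shallow library correctly receives a larger predicted
#'   standard deviation.  Without library sizes the log-CPM scale is used.
#' @param span lowess span (default 0.5).
#' @param min_loci below this many cores the trend is unreliable and unit
#'   weights are returned with a warning (default 50).
#' @return list with `weights` (matrix like `y`) and `trend`
#'   (`data.frame(x, y)` of the fitted lowess curve).
#' @export
voom_weights <- function(y, design, lib_size = NULL, span = 0.5,
                         min_loci = 50L) {
  stopifnot(is.matrix(y), nrow(design) == ncol(y))
  if (qr(design)$rank < ncol(design)) stop("design matrix not full rank")
  df_resid <- ncol(y) - ncol(design)
  if (df_resid < 2L) stop("need at least 2 residual degrees of freedom")
  if (nrow(y) < min_loci) {
    warning("fewer than ", min_loci, " loci: falling back to unit weights")
    return(list(weights = matrix(1, nrow(y), ncol(y),
                                 dimnames = dimnames(y)),
                trend = NULL))
  }
  fit <- stats::lm.fit(design, t(y))
  fitted <- t(design %*% fit$coefficients)
  s <- sqrt(colSums(fit$residuals^2) / df_resid)     # per-core residual sd
  if (!is.null(lib_size)) {
    shift <- log2(lib_size + 1) - log2(1e6)          # log-CPM -> log-count
    amean <- rowMeans(y) + mean(shift)
    fitted <- sweep(fitted, 2, shift, `+`)
  } else {
    amean <- rowMeans(y)
  }
  lo <- stats::lowess(amean, sqrt(s), f = span)
  pred <- stats::approx(lo$x, lo$y, xout = as.numeric(fitted),
                        rule = 2)$y
  pred4 <- pmax(pred, 1e-4)^4                  # weight = predicted sd^-4
  w <- matrix(1 / pred4, nrow(y), ncol(y), dimnames = dimnames(y))
  list(weights = w, trend = data.frame(x = lo$x, y = lo$y))
}

# Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Weighted linear model fit with empirical-Bayes moderated t statistics
#'
#' Per core: weighted least squares for the contrast coefficient (log2
#' fold change, post vs pre), residual variance `s2_g` on `d_g` degrees
#' of freedom; then an empirical-Bayes prior `(s0^2, d0)` is estimated
#' from the marginal moments of `log s2_g` (digamma/trigamma inversion),
#' each variance is shrunk to
#' `s_tilde2_g = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`, and the moderated
#' `t_g = logFC_g / (SE_g * sqrt(s_tilde2_g / s2_g))` is referred to a t
#' distribution on `d0 + d_g` degrees of freedom.  When the variances are
#' near-identical the trigamma inversion diverges and the fit takes the
#' `d0 = Inf` branch (`s_tilde2 = s0^2` for all cores).
#'
#' @param y normalized log-CPM matrix (cores x samples).
#' @param design design matrix.
#' @param coef name or index of the contrast coefficient (default
#'   `"treat"`).
#' @param weights optional observation weights (same shape as `y`).
#' @param prior_df optional fixed prior degrees of freedom overriding the
#'   moment estimate (0 gives the ordinary unmoderated t).
#' @return `data.frame(core_id, logFC, t, p_value, s2, df_residual,
#'   df_total)` with attributes `"s0_2"` and `"d0"`.
#' @export
fit_moderated <- function(y, design, coef = "treat", weights = NULL,
                          prior_df = NULL) {
  stopifnot(is.matrix(y), nrow(design) == ncol(y))
  if (is.character(coef)) coef <- match(coef, colnames(design))
  if (is.na(coef)) stop("contrast coefficient not found in design")
  G <- nrow(y); S <- ncol(y); p <- ncol(design)
  d_g <- S - p
  if (d_g < 1L) stop("need at least 1 residual degree of freedom")
  if (is.null(weights)) weights <- matrix(1, G, S)

  beta <- se_unscaled <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    Xw <- design * sw
    yw <- y[g, ] * sw
    qr_x <- qr(Xw)
    b <- qr.coef(qr_x, yw)
    res <- yw - Xw %*% b
    s2[g] <- sum(res^2) / d_g
    XtXinv <- chol2inv(qr.R(qr_x))
    beta[g] <- b[coef]
    se_unscaled[g] <- sqrt(XtXinv[coef, coef])
  }

  # empirical-Bayes prior from the marginal distribution of log s2
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_2 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  } else {
    evar <- stats::var(e) - trigamma(d_g / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    }
  }

  if (is.infinite(d0)) {
    s_tilde2 <- rep(s0_2, G)
    df_total <- rep(Inf, G)
  } else if (d0 == 0) {
    s_tilde2 <- s2
    df_total <- rep(d_g, G)
  } else {
    s_tilde2 <- (d0 * s0_2 + d_g * s2) / (d0 + d_g)
    df_total <- rep(d0 + d_g, G)
  }
  tstat <- beta / (se_unscaled * sqrt(s_tilde2))
  pval <- 2 * stats::pt(-abs(tstat), df_total)
  ids <- rownames(y)
  if (is.null(ids)) ids <- sprintf("core%05d", seq_len(G))
  out <- data.frame(core_id = ids, logFC = beta, t = tstat,
                    p_value = pval, s2 = s2, df_residual = d_g,
                    df_total = df_total, stringsAsFactors = FALSE)
  attr(out, "s0_2") <- s0_2
  attr(out, "d0") <- d0
  out
}

#' Benjamini-Hochberg FDR over a restricted test family
#'
#' Adjusted values are computed over the restricted index set only (the
#' supervised target family); everything outside the restriction gets
#' `NA`.
#'
#' @param p p-values in `[0, 1]`.
#' @param restrict_to indices (or logical mask) of the family; defaults
#'   to all.
#' @return numeric vector like `p` with BH-adjusted values on the family.
#' @export
bh_fdr <- function(p, restrict_to = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(restrict_to)) restrict_to <- seq_along(p)
  if (is.logical(restrict_to)) restrict_to <- which(restrict_to)
  if (!length(restrict_to)) stop("empty restriction set")
  out <- rep(NA_real_, length(p))
  out[restrict_to] <- stats::p.adjust(p[restrict_to], method = "BH")
  out
}

#' Top-variance hierarchical clustering of samples
#'
#' Selects the `k` loci with the largest variance of the normalized
#' matrix and clusters the samples with Euclidean distance and complete
#' linkage.
#'
#' @param y normalized matrix (loci x samples).
#' @param k number of top-variance loci (default 1000); when fewer loci
#'   exist, all are used with a warning.
#' @return an `hclust` over the samples.
#' @export
top_variance_clustering <- function(y, k = 1000L) {
  v <- apply(y, 1, stats::var)
  if (all(v == 0)) stop("constant matrix: zero variance everywhere")
  if (nrow(y) < k) {
    warning("fewer than ", k, " loci; using all ", nrow(y))
    k <- nrow(y)
  }
  top <- order(v, decreasing = TRUE)[seq_len(k)]
  cohort_dendrogram(t(y[top, , drop = FALSE]), metric = "euclidean",
                    linkage = "complete")
}

#' Per-patient quantile-category methylation calls for one region
#'
#' The quartile boundaries (25/50/75th percentiles, linear-interpolation
#' quantile definition) of all samples' normalized counts for the region
#' define four categories: "No to low methylation", "Low to medium",
#' "Medium to high" and "High to very high".  Per patient, the
#' pre-treatment value is the biopsy value and the post-treatment value
#' the mean over nephrectomy samples; a value exactly on a boundary goes
#' to the higher category.  The top two categories count as
#' hypermethylated.
#'
#' @param values named numeric vector: normalized value of the region per
#'   sample.
#' @param meta sample metadata.
#' @return list with `table` (`data.frame(patient_id, pre_value,
#'   post_value, pre_category, post_category, pre_hyper, post_hyper)`),
#'   `boundaries`, and `summary` (`pct_hyper_pre`, `pct_hyper_post` over
#'   patients with both timepoints).
#' @export
categorize_region <- function(values, meta) {
  labels <- c("No to low methylation", "Low to medium",
              "Medium to high", "High to very high")
  v <- values[!is.na(values)]
  bounds <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  categorize <- function(x) {
    if (max(v) == min(v)) return(labels[1])    # degenerate: all equal
    labels[1 + sum(x >= bounds)]
  }
  pats <- unique(meta$patient_id)
  rows <- lapply(pats, function(p) {
    pm <- meta[meta$patient_id == p, ]
    bx <- pm$sample_id[pm$tissue == "biopsy"]
    nx <- pm$sample_id[pm$tissue == "nephrectomy"]
    pre <- if (length(bx) && all(bx %in% names(values)))
      unname(values[bx[1]]) else NA_real_
    post <- if (length(nx) && any(nx %in% names(values)))
      mean(values[intersect(nx, names(values))], na.rm = TRUE)
      else NA_real_
    data.frame(patient_id = p, pre_value = pre, post_value = post,
               pre_category = if (is.na(pre)) NA else categorize(pre),
               post_category = if (is.na(post)) NA else categorize(post),
               pre_hyper = if (is.na(pre)) NA else
                 categorize(pre) %in% labels[3:4],
               post_hyper = if (is.na(post)) NA else
                 categorize(post) %in% labels[3:4],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  complete <- !is.na(tab$pre_hyper) & !is.na(tab$post_hyper)
  list(table = tab, boundaries = bounds,
       summary = c(pct_hyper_pre = 100 * mean(tab$pre_hyper[complete]),
                   pct_hyper_post = 100 * mean(tab$post_hyper[complete]),
                   n_patients = sum(complete)))
}

#' Compare methylation change between responder groups
#'
#' Unpaired two-sided Student t test of per-patient post-minus-pre
#' methylation deltas between good- and poor-response patients.
#'
#' @param deltas named numeric vector, patient -> delta.
#' @param response named character vector, patient -> `"good"` / `"poor"`.
#' @return list with `t`, `df`, `p_value`, group means.
#' @export
responder_comparison <- function(deltas, response) {
  g <- deltas[names(response)[response == "good"]]
  p <- deltas[names(response)[response == "poor"]]
  g <- g[!is.na(g)]; p <- p[!is.na(p)]
  if (length(g) < 2L || length(p) < 2L)
    stop("need at least 2 patients per response group")
  ht <- student_t_test(g, p)
  c(ht, list(mean_good = mean(g), mean_poor = mean(p)))
}

#' Differential methylation analysis of a cohort count matrix
#'
#' The full engine: core filtering, log-CPM, quantile normalization,
#' precision weights, patient-blocked (default) or two-group weighted
#' linear model with empirical-Bayes moderated t, and Benjamini-Hochberg
#' FDR restricted to the target cores.
#'
#' @param counts cores x tumor-samples count matrix.
#' @param cores core annotation ([core_table()]-like, with `promoter`,
#'   `gene`, `is_target`).
#' @param meta sample metadata (tumor samples of the matrix).
#' @param design_type `"blocked"` (treatment + patient fixed effects,
#'   default: samples are patient-matched) or `"grouped"` (two-group).
#' @param lib_size optional library sizes.
#' @return `data.frame(core_id, gene, is_target, logFC, t, p_value, fdr)`
#'   sorted by p within targets first; attributes `"s0_2"`, `"d0"`,
#'   `"removed"` and `"normalized"` (the normalized matrix used).
#' @export
dm_analysis <- function(counts, cores, meta,
                        design_type = c("blocked", "grouped"),
                        lib_size = NULL) {
  design_type <- match.arg(design_type)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  filtered <- filter_cores(counts, cores)
  if (is.null(lib_size)) lib_size <- attr(counts, "lib_size")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  y <- logcpm(filtered, lib_size)
  yq <- quantile_normalize(y)

  treat <- as.numeric(meta$timepoint == "post")
  design <- if (design_type == "blocked") {
    stats::model.matrix(~ 0 + factor(meta$patient_id) + treat)
  } else {
    stats::model.matrix(~ treat)
  }
  colnames(design)[ncol(design)] <- "treat"
  vw <- voom_weights(yq, design, lib_size = lib_size)
  fit <- fit_moderated(yq, design, coef = "treat", weights = vw$weights)

  ann <- cores[match(fit$core_id, cores$core_id), ]
  fit$gene <- ann$gene
  fit$is_target <- ann$is_target
  fit$fdr <- bh_fdr(fit$p_value, restrict_to = fit$is_target)
  out <- fit[order(!fit$is_target, fit$p_value),
             c("core_id", "gene", "is_target", "logFC", "t", "p_value",
               "fdr")]
  rownames(out) <- NULL
  attr(out, "s0_2") <- attr(fit, "s0_2")
  attr(out, "d0") <- attr(fit, "d0")
  attr(out, "removed") <- attr(filtered, "removed")
  attr(out, "normalized") <- yq
  out
}
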