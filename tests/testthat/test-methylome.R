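make_cores <- function(ids, promoter = TRUE, target = promoter) {
  data.frame(core_id = ids, chrom = "chr1",
             start = seq_along(ids) * 1000,
             end = seq_along(ids) * 1000 + 150,
             promoter = promoter, gene = ids, is_target = target,
             stringsAsFactors = FALSE)
}

test_that("core filtering keeps promoters with mean coverage >= 1", {
  counts <- rbind(core1 = c(0, 0, 0, 0),      # zero everywhere
                  core2 = c(4, 4, 4, 4),      # non-promoter
                  core3 = c(1, 1, 1, 1),      # mean exactly 1
                  core4 = c(0, 1, 1, 1))      # mean 0.75
  cores <- make_cores(rownames(counts),
                      promoter = c(TRUE, FALSE, TRUE, TRUE))
  kept <- filter_cores(counts, cores)
  expect_equal(rownames(kept), "core3")
  expect_equal(attr(kept, "removed")[["non_promoter"]], 1L)
  expect_equal(attr(kept, "removed")[["low_coverage"]], 2L)
  expect_error(filter_cores(counts[1, , drop = FALSE], cores),
               "no analyzable")
})

test_that("log-CPM follows the offset formula and is monotone", {
  m <- matrix(0, 1, 1)
  expect_equal(logcpm(m, lib_size = 1e6 - 1)[1, 1], -1)  # log2(0.5)
  y <- matrix(c(0, 5, 50, 500), 4, 1)
  x <- logcpm(y, lib_size = 1e6)
  expect_false(is.unsorted(x))
  expect_error(logcpm(y, lib_size = 0), "library size")
  # doubling counts and library sizes converges to invariance
  big <- matrix(c(1e4, 2e4), 2, 1)
  expect_equal(logcpm(big, 1e6), logcpm(2 * big, 2e6), tolerance = 1e-3)
})

test_that("quantile normalization: hand case, exact post-condition, ties", {
  m <- cbind(c(1, 3), c(2, 4))
  expect_equal(unname(quantile_normalize(m)), cbind(c(1.5, 3.5),
                                                    c(1.5, 3.5)))
  same <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)
  set.seed(6)
  for (i in 1:10) {
    x <- matrix(sample(0:5, 60, replace = TRUE), 12, 5)  # heavy ties
    q <- quantile_normalize(x)
    sorted <- apply(q, 2, sort)
    expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0)
    # column ranks are preserved
    expect_equal(order(q[, 1]), order(x[, 1], method = "radix"))
  }
  # averaging mode gives tied inputs tied outputs
  xa <- cbind(c(1, 1, 2), c(1, 2, 3))
  qa <- quantile_normalize(xa, ties = "average")
  expect_equal(qa[1, 1], qa[2, 1])
})

test_that("precision weights are flat for homoskedastic data and positive", {
  set.seed(9)
  n <- 28
  design <- cbind(1, rep(0:1, each = n / 2))
  colnames(design) <- c("intercept", "treat")
  y <- matrix(rnorm(5000 * n, mean = 8, sd = 0.4), 5000, n)
  vw <- voom_weights(y, design)
  expect_true(all(vw$weights > 0))
  expect_lt(sd(vw$weights) / mean(vw$weights), 0.10)
  # a high-noise regime drags its neighbourhood's weights down
  y2 <- y
  y2[1:2500, ] <- matrix(rnorm(2500 * n, mean = 2, sd = 1.5), 2500, n)
  vw2 <- voom_weights(y2, design)
  expect_lt(mean(vw2$weights[1:2500, ]), mean(vw2$weights[2501:5000, ]))
  # tiny matrices fall back to unit weights
  expect_warning(vw3 <- voom_weights(y[1:10, ], design), "unit weights")
  expect_true(all(vw3$weights == 1))
})

test_that("moderated fit: shrinkage identities and limma cross-check", {
  set.seed(15)
  n <- 12; G <- 400
  design <- cbind(1, rep(0:1, each = n / 2))
  colnames(design) <- c("intercept", "treat")
  y <- matrix(rnorm(G * n, sd = rep(runif(G, 0.3, 1.5), n)), G, n,
              dimnames = list(sprintf("g%03d", 1:G), NULL))
  # prior_df = 0: ordinary t per core
  fit0 <- fit_moderated(y, design, prior_df = 0)
  g <- 17
  lmf <- summary(lm(y[g, ] ~ design[, "treat"]))$coefficients
  expect_equal(fit0$logFC[g], lmf[2, 1], tolerance = 1e-9)
  expect_equal(fit0$t[g], lmf[2, 3], tolerance = 1e-9)
  # moderated t equals the ordinary t scaled by sqrt(s2 / s_tilde2)
  fit <- fit_moderated(y, design)
  d0 <- attr(fit, "d0"); s0 <- attr(fit, "s0_2")
  stld <- (d0 * s0 + fit$df_residual * fit$s2) / (d0 + fit$df_residual)
  expect_equal(fit$t, fit0$t * sqrt(fit$s2 / stld), tolerance = 1e-9)
  expect_true(all(fit$df_total == d0 + fit$df_residual))

  skip_if_not_installed("limma")
  lf <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(fit$logFC, unname(lf$coefficients[, "treat"]),
               tolerance = 1e-9)
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 0.05)
  expect_equal(fit$t, unname(lf$t[, "treat"]), tolerance = 1e-6)
  expect_equal(fit$p_value, unname(lf$p.value[, "treat"]),
               tolerance = 1e-6)
})

test_that("near-identical variances take the infinite-prior branch", {
  set.seed(30)
  n <- 100                         # huge residual df: log s2 nearly constant
  design <- cbind(1, rep(0:1, each = n / 2))
  colnames(design) <- c("intercept", "treat")
  y <- matrix(rnorm(60 * n), 60, n)
  fit <- fit_moderated(y, design, prior_df = Inf)
  expect_true(all(is.infinite(fit$df_total)))
  expect_equal(length(unique(round(
    (fit$logFC / fit$t)^2, 12))), 1L)   # common shrunk variance
})

test_that("restricted BH matches the brute-force definition", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_force_bh(p))
  }
  # restriction: only the family is adjusted, the rest is NA
  p <- c(0.001, 0.5, 0.02, 0.9)
  q <- bh_fdr(p, restrict_to = c(1, 3))
  expect_equal(q[c(2, 4)], c(NA_real_, NA_real_))
  expect_equal(q[c(1, 3)], brute_force_bh(p[c(1, 3)]))
  expect_true(all(q >= p, na.rm = TRUE))
  expect_error(bh_fdr(p, integer()), "empty")
})

test_that("top-variance clustering selects loci and matches full clustering", {
  set.seed(14)
  y <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  full <- cohort_dendrogram(t(y))
  top <- top_variance_clustering(y, k = 200)
  expect_equal(top$height, full$height)
  expect_warning(top_variance_clustering(y, k = 500), "fewer than")
  # ranking invariant to locus order
  perm <- sample(200)
  t2 <- top_variance_clustering(y[perm, ], k = 50)
  t1 <- top_variance_clustering(y, k = 50)
  expect_equal(t1$height, t2$height)
})

test_that("quantile categories: hand boundaries and hypermethylation calls", {
  meta <- rbind(make_meta(2, "P01"), make_meta(2, "P02"),
                make_meta(2, "P03"), make_meta(2, "P04"))
  tum <- meta$sample_id[meta$tissue != "normal"]
  values <- setNames(as.numeric(1:8), tum)
  got <- categorize_region(values, meta)
  expect_equal(unname(got$boundaries), c(2.75, 4.5, 6.25))
  # value 5 lands in "Medium to high", which is hypermethylated
  expect_equal(got$table$post_category[got$table$patient_id == "P03"],
               "Medium to high")
  expect_true(got$table$post_hyper[got$table$patient_id == "P03"])
  # a value exactly on a quartile boundary goes to the higher category
  v2 <- setNames(c(0, 3, 3, 6, 6, 9, 9, 12), tum)
  got2 <- categorize_region(v2, meta)
  expect_equal(unname(got2$boundaries), c(3, 6, 9))
  # P01 post value 3 sits on the 25% boundary -> second category
  expect_equal(got2$table$post_category[got2$table$patient_id == "P01"],
               "Low to medium")
  # P02 post value 6 sits on the median -> third category, hypermethylated
  expect_equal(got2$table$post_category[got2$table$patient_id == "P02"],
               "Medium to high")
  expect_true(got2$table$post_hyper[got2$table$patient_id == "P02"])
  # degenerate all-equal region collapses to the lowest category
  same <- setNames(rep(3, length(tum)), tum)
  got3 <- categorize_region(same, meta)
  expect_true(all(got3$table$pre_category == "No to low methylation"))
  expect_equal(unname(got3$summary["pct_hyper_pre"]), 0)
})

test_that("responder comparison: closed form, symmetry, degenerate input", {
  deltas <- c(P1 = 0.5, P2 = 1.0, P3 = 0.6, P4 = 0.9)
  resp <- c(P1 = "good", P2 = "good", P3 = "poor", P4 = "poor")
  got <- responder_comparison(deltas, resp)
  # pooled-variance t with df = 2
  expect_equal(got$df, 2)
  expect_equal(got$t,
               (0.75 - 0.75) / sqrt(mean(c(var(c(0.5, 1)),
                                           var(c(0.6, 0.9)))) * (1 / 2 + 1 / 2)))
  swapped <- responder_comparison(deltas,
                                  setNames(ifelse(resp == "good", "poor",
                                                  "good"), names(resp)))
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p_value, got$p_value)
  expect_equal(responder_comparison(c(P1 = 1, P2 = 1, P3 = 1, P4 = 1),
                                    resp)$p_value, 1)
  expect_error(responder_comparison(deltas[1:3], resp[1:3]), "at least 2")
})

test_that("dm_analysis recovers an injected effect at cohort scale", {
  d <- cohort_design(n_patients = 8, n_cores = 400, n_target_genes = 8,
                     treatment_logfc = c(core00001 = 0.87), seed = 23)
  sim <- simulate_methylation_counts(d)
  dm <- dm_analysis(sim$counts, sim$cores, sim$meta)
  top <- dm[1, ]
  expect_equal(top$core_id, "core00001")
  expect_lt(top$fdr, 0.1)
  expect_lt(abs(top$logFC - 0.87), 0.35)
  expect_true(all(is.na(dm$fdr[!dm$is_target])))
  # grouped design also finds the effect, with wider uncertainty
  dm2 <- dm_analysis(sim$counts, sim$cores, sim$meta,
                     design_type = "grouped")
  expect_equal(dm2$core_id[1], "core00001")
})
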