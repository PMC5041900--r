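test_that("homopolymer run detection finds maximal runs", {
  expect_equal(nrow(detect_homopolymer_runs("ACGT")), 0L)
  runs <- detect_homopolymer_runs("AAAACGGGG")
  expect_equal(runs$start, c(1L, 6L))
  expect_equal(runs$end, c(4L, 9L))
  expect_equal(runs$base, c("A", "G"))
  expect_equal(detect_homopolymer_runs("AAAAA"),
               data.frame(start = 1L, end = 5L, base = "A"))
  expect_equal(nrow(detect_homopolymer_runs("NNNNN")), 0L)
  expect_error(detect_homopolymer_runs("ACGX"), "non-IUPAC")
})

test_that("quality filters use the documented thresholds", {
  base <- make_calls("P01_Bx")
  low_gq <- base; low_gq$GQ <- 59
  low_vaf <- base; low_vaf$VAF <- 0.09
  at_gq <- base; at_gq$GQ <- 60
  at_vaf <- base; at_vaf$VAF <- 0.10
  calls <- rbind(base, low_gq, low_vaf, at_gq, at_vaf)
  kept <- filter_variants(calls)
  expect_equal(nrow(kept), 3L)           # base + the two boundary calls
  expect_equal(attr(kept, "removed")[["gq"]], 1L)
  expect_equal(attr(kept, "removed")[["vaf"]], 1L)
  # empty input passes through
  expect_equal(nrow(filter_variants(calls[0, ])), 0L)
  # missing context is an explicit error, never silently kept
  miss <- base; miss$flank_seq <- NA
  expect_error(filter_variants(miss), "context unavailable")
})

test_that("homopolymer exclusion matches a brute-force scan of placements", {
  # SNV in a 21 bp window; slide a GGGG run across every placement
  for (run_start in 1:17) {
    chars <- rep(c("A", "C"), length.out = 21)  # tie-free background
    chars[run_start:(run_start + 3)] <- "G"
    chars[11] <- "T"                            # the variant ref base
    flank <- paste(chars, collapse = "")
    call <- make_calls("P01_Bx")
    call$ref <- "T"; call$alt <- "A"
    call$flank_seq <- flank
    d_oracle <- brute_force_hp_distance(flank, c(11, 11))
    kept <- filter_variants(call)
    expect_equal(nrow(kept) == 1L, d_oracle > 1,
                 label = paste("run at", run_start))
  }
  # a run ending 1 bp before the variant excludes; 2 bp before keeps
  f_excl <- paste0("CACACA", "GGGG", "T", strrep("CA", 5))   # run 7-10, var 11
  f_keep <- paste0("CACAC", "GGGG", "A", "T", strrep("CA", 5)) # run 6-9, var 11
  for (f in list(c(f_excl, FALSE), c(f_keep, TRUE))) {
    call <- make_calls("P01_Bx"); call$ref <- "T"; call$alt <- "G"
    call$flank_seq <- f[1]
    expect_equal(nrow(filter_variants(call)) == 1L, as.logical(f[2]))
  }
})

test_that("filtering is idempotent", {
  d <- cohort_design(n_patients = 4, seed = 77)
  calls <- simulate_variants(d)$calls
  once <- filter_variants(calls)
  twice <- filter_variants(once)
  expect_equal(nrow(once), nrow(twice))
  expect_identical(once$pos, twice$pos)
  expect_lt(nrow(once), nrow(calls))     # violators were injected
})

test_that("sharing classification matches the definitions for every carrier pattern", {
  for (k in 2:5) {
    meta <- make_meta(k_tumor = k)
    tumors <- meta$sample_id[meta$tissue != "normal"]
    normal <- meta$sample_id[meta$tissue == "normal"]
    for (with_normal in c(FALSE, TRUE)) {
      for (pattern in seq_len(2^k - 1)) {
        carry <- tumors[as.logical(bitwAnd(pattern, 2^(seq_len(k) - 1)))]
        if (with_normal) carry <- c(normal, carry)
        calls <- make_calls(carry)
        got <- classify_sharing(calls, meta)
        expect_equal(got$category,
                     brute_force_sharing(with_normal,
                                         sum(carry %in% tumors), k),
                     label = paste("k", k, "pattern", pattern, with_normal))
        expect_equal(got$tumor_specific, !with_normal)
      }
    }
  }
})

test_that("sharing classes and private counts round-trip simulator truth", {
  d <- cohort_design(n_patients = 8, seed = 19,
                     filter_violation_frac = c(gq = 0, vaf = 0,
                                               homopolymer = 0))
  v <- simulate_variants(d)
  meta <- sample_metadata(d)
  kept <- filter_variants(v$calls)
  expect_equal(nrow(kept), nrow(v$calls))   # nothing violates by design
  sharing <- classify_sharing(kept, meta)
  key_s <- paste(sharing$patient_id, sharing$chrom, sharing$pos,
                 sharing$ref, sharing$alt)
  key_t <- paste(v$truth$patient_id, v$truth$chrom, v$truth$pos,
                 v$truth$ref, v$truth$alt)
  expect_setequal(key_s, key_t)
  expect_equal(sharing$category[match(key_t, key_s)], v$truth$class)

  priv <- count_private_mutations(sharing, meta)
  truth_priv <- v$truth[v$truth$class == "private", ]
  for (p in priv$patient_id) {
    carriers <- truth_priv$carriers[truth_priv$patient_id == p]
    bx <- sum(grepl("_Bx$", carriers))
    expect_equal(priv$biopsy_private[priv$patient_id == p], bx)
  }
  # a shared variant never contributes to a private count
  per_sample <- attr(priv, "per_sample")
  expect_equal(sum(per_sample$private_count),
               nrow(truth_priv))
})

test_that("a patient without a normal is classified against the cohort panel", {
  meta <- rbind(make_meta(3, "P01"), make_meta(3, "P02"))
  meta <- meta[!(meta$patient_id == "P02" & meta$tissue == "normal"), ]
  calls <- rbind(make_calls(c("P02_Bx", "P02_Nx1", "P02_Nx2"), "P02"),
                 make_calls("P01_N", "P01", pos = 100L))  # also in P01 normal
  got <- classify_sharing(calls, meta)
  p2 <- got[got$patient_id == "P02", ]
  expect_equal(p2$category, "truncal")       # never germline without a normal
  expect_false(p2$tumor_specific)            # seen in a cohort normal
})

test_that("candidate driver rules follow the consequence vocabulary", {
  v <- data.frame(consequence = c("stop_gained", "missense", "missense",
                                  "synonymous", "frameshift",
                                  "splice_donor"),
                  sift_label = c(NA, "tolerated", "tolerated", NA, NA, NA),
                  polyphen_label = c(NA, "benign", "possibly_damaging",
                                     NA, NA, NA),
                  stringsAsFactors = FALSE)
  got <- call_candidate_drivers(v)
  expect_equal(got$is_candidate_driver,
               c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(got$rationale) == !got$is_candidate_driver))
  bad <- data.frame(consequence = "weird", sift_label = NA,
                    polyphen_label = NA)
  expect_error(call_candidate_drivers(bad), "unknown consequence")
  expect_false(call_candidate_drivers(bad, strict = FALSE)$is_candidate_driver)
})

test_that("exact Wilcoxon matches full enumeration and the classic example", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:4, n1, replace = TRUE)   # ties on purpose
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 brute_force_wilcoxon(x, y))
  }
  # tie-free case agrees with the standard exact test
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.7, 4.4, 6.2)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # large groups switch to the normal approximation
  expect_equal(wilcoxon_rank_sum(rnorm(15), rnorm(15))$method,
               "normal_approx")
})

test_that("driver-count comparison is order invariant and handles absent genes", {
  meta <- rbind(make_meta(4, "P01"), make_meta(4, "P02"))
  drv <- data.frame(patient_id = c("P01", "P02"), gene = c("VHL", "VHL"),
                    chrom = "chr1", pos = c(1, 2), ref = "A", alt = "G",
                    carriers = c("P01_Bx", "P02_Nx1,P02_Nx2"),
                    is_candidate_driver = TRUE, stringsAsFactors = FALSE)
  t1 <- compare_driver_counts(drv, meta, genes = c("VHL", "ABSENT"))
  expect_true(is.na(t1$p_value[t1$gene == "ABSENT"]))
  t2 <- compare_driver_counts(drv[2:1, ], meta[nrow(meta):1, ],
                              genes = c("VHL", "ABSENT"))
  expect_equal(t1$p_value, t2$p_value)
})

test_that("private-count comparison reproduces the pooled-variance t", {
  tab <- data.frame(patient_id = sprintf("P%02d", 1:4),
                    biopsy_private = c(1, 2, 3, 4),
                    median_nephrectomy_private = c(2, 3, 4, 5))
  got <- compare_private_counts(tab)
  expect_equal(got$t, -1.0954, tolerance = 1e-4)
  expect_equal(got$df, 6)
  expect_equal(got$p_value, 0.3153, tolerance = 1e-3)
  expect_equal(sum(got$split), 4)
  same <- tab; same$median_nephrectomy_private <- same$biopsy_private
  got2 <- compare_private_counts(same)
  expect_equal(got2$p_value, 1)
  expect_equal(unname(got2$split["equal"]), 4L)
})
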