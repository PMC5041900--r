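#' Run configuration for the end-to-end pipeline
#'
#' Bundles the cohort design, the stage toggles and numeric parameters of
#' every stage.  The full configuration is serialized into the output
#' directory as a reproducibility manifest.
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param stages character subset of
#'   `c("variants", "cnv_loh", "phylo", "methylome")`.
#' @param design_type `"blocked"` or `"grouped"` (see [dm_analysis()]).
#' @param loh_min_snps,loh_deviation_threshold,loh_alpha LOH segmentation
#'   parameters ([segment_loh()]).
#' @param cnv_loss_threshold,cnv_gain_threshold CNV state thresholds.
#' @param top_k loci used for the methylome dendrogram.
#' @return an object of class `run_config`.
#' @export
run_config <- function(design = cohort_design(),
                       out_dir = NULL,
                       stages = c("variants", "cnv_loh", "phylo",
                                  "methylome"),
                       design_type = c("blocked", "grouped"),
                       loh_min_snps = 10L,
                       loh_deviation_threshold = 0.15,
                       loh_alpha = 0.01,
                       cnv_loss_threshold = -0.4,
                       cnv_gain_threshold = 0.3,
                       top_k = 1000L) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(design = design, out_dir = out_dir, stages = stages,
              design_type = match.arg(design_type),
              loh_min_snps = loh_min_snps,
              loh_deviation_threshold = loh_deviation_threshold,
              loh_alpha = loh_alpha,
              cnv_loss_threshold = cnv_loss_threshold,
              cnv_gain_threshold = cnv_gain_threshold,
              top_k = as.integer(top_k))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> variants -> cnv/loh -> phylo -> methylome ->
#' report.  Idempotent for a given configuration (the design seed drives
#' every stage through fixed offsets); any stage failure aborts with the
#' stage name.
#'
#' @param config a [run_config()].
#' @param response optional named character vector patient -> `"good"` /
#'   `"poor"`; by default the first half of the patients is labelled
#'   good.
#' @return a `summary_report` list (see [write_report()]); stage outputs
#'   are attached in the `stages` element.
#' @export
run_pipeline <- function(config = run_config(), response = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  report <- list(seed = design$seed, cohort = design$cohort,
                 n_patients = design$n_patients)
  stage_out <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- run_stage("simulate", {
    list(meth = simulate_methylation_counts(design),
         var = simulate_variants(design),
         baf = simulate_baf(design),
         cov = simulate_target_coverage(design))
  })
  meta <- sample_metadata(design)
  stage_out$sim <- sim

  if ("variants" %in% config$stages) {
    vres <- run_stage("variants", {
      kept <- filter_variants(sim$var$calls)
      sharing <- classify_sharing(kept, meta)
      drivers <- call_candidate_drivers(sharing_annotate(sharing, kept))
      priv <- count_private_mutations(sharing, meta)
      list(filtered = kept, sharing = sharing, drivers = drivers,
           private = priv,
           private_test = compare_private_counts(priv),
           driver_tests = compare_driver_counts(drivers, meta))
    })
    stage_out$variants <- vres
    report$private_mutations <- list(
      split = as.list(vres$private_test$split),
      t = vres$private_test$t, p_value = vres$private_test$p_value)
    report$driver_tests <- list(
      n_genes = nrow(vres$driver_tests),
      min_p = suppressWarnings(min(vres$driver_tests$p_value,
                                   na.rm = TRUE)))
  }

  if ("cnv_loh" %in% config$stages) {
    cres <- run_stage("cnv_loh", {
      loh <- list(); cnv_counts <- list(); cnv_calls <- list()
      for (p in unique(meta$patient_id)) {
        pm <- meta[meta$patient_id == p, ]
        normal <- pm$sample_id[pm$tissue == "normal"]
        if (!length(normal)) next
        nb <- sim$baf[sim$baf$sample_id == normal, ]
        het <- suppressWarnings(select_het_snps(nb))
        sites <- paste(het$chrom, het$pos)
        tumors <- pm$sample_id[pm$tissue != "normal"]
        for (s in tumors) {
          tb <- sim$baf[sim$baf$sample_id == s, ]
          tb <- tb[paste(tb$chrom, tb$pos) %in% sites, ]
          loh[[s]] <- segment_loh(tb, config$loh_min_snps,
                                  config$loh_deviation_threshold,
                                  config$loh_alpha)
        }
        ncov <- sim$cov[sim$cov$sample_id == normal, ]
        pre <- post <- c()
        for (s in tumors) {
          tcov <- sim$cov[sim$cov$sample_id == s, ]
          cc <- call_cnv(tcov, ncov, config$cnv_loss_threshold,
                         config$cnv_gain_threshold)
          cc$sample_id <- s
          cnv_calls[[s]] <- cc
          n_cnv <- sum(cc$state != "neutral")
          if (pm$tissue[pm$sample_id == s] == "biopsy") pre <- c(pre, n_cnv)
          else post <- c(post, n_cnv)
        }
        cnv_counts[[p]] <- data.frame(patient_id = p, pre = mean(pre),
                                      post = mean(post))
      }
      counts_df <- do.call(rbind, cnv_counts)
      list(loh = loh, cnv_calls = do.call(rbind, cnv_calls),
           cnv_counts = counts_df,
           cnv_test = compare_cnv_counts(counts_df))
    })
    stage_out$cnv_loh <- cres
    report$cnv <- list(
      n_loh_segments = sum(vapply(cres$loh, function(s) sum(s$is_loh),
                                  numeric(1))),
      paired_t = cres$cnv_test$t, p_value = cres$cnv_test$p_value)
  }

  if ("phylo" %in% config$stages && "variants" %in% config$stages) {
    pres <- run_stage("phylo", {
      sharing <- stage_out$variants$sharing
      drivers <- stage_out$variants$drivers
      cnv <- if (!is.null(stage_out$cnv_loh))
        stage_out$cnv_loh$cnv_calls else NULL
      profiles <- mutation_profiles(sharing, meta, cnv)
      trees <- list()
      for (p in unique(meta$patient_id)) {
        pm <- meta[meta$patient_id == p & meta$tissue != "normal", ]
        if (nrow(pm) < 3L) next
        pr <- profiles[pm$sample_id, , drop = FALSE]
        pr <- pr[, colSums(pr) > 0, drop = FALSE]
        if (!ncol(pr)) next
        tree <- bionj_tree(manhattan_distance(pr))
        dr <- drivers[drivers$patient_id == p &
                        drivers$is_candidate_driver, , drop = FALSE]
        presence <- lapply(seq_len(nrow(dr)), function(i)
          intersect(strsplit(dr$carriers[i], ",")[[1]], pm$sample_id))
        names(presence) <- paste(dr$gene, dr$chrom, dr$pos, sep = ":")
        trees[[p]] <- label_branches(tree, presence)
      }
      hc <- cohort_dendrogram(profiles, metric = "manhattan")
      conc <- score_concordance(hc, meta)
      list(trees = trees, dendrogram = hc, concordance = conc)
    })
    stage_out$phylo <- pres
    report$mutation_clustering <- as.list(
      table(factor(pres$concordance$verdict,
                   levels = c("complete", "partial", "none"))))
    report$n_trees <- length(pres$trees)
  }

  if ("methylome" %in% config$stages) {
    mres <- run_stage("methylome", {
      dm <- dm_analysis(sim$meth$counts, sim$meth$cores, sim$meth$meta,
                        design_type = config$design_type)
      yq <- attr(dm, "normalized")
      hc <- top_variance_clustering(yq, k = config$top_k)
      conc <- score_concordance(hc, sim$meth$meta)
      targets <- dm[dm$is_target, ]
      top_core <- targets$core_id[1]
      cats <- categorize_region(yq[top_core, ], sim$meth$meta)
      if (is.null(response)) {
        pats <- unique(meta$patient_id)
        response <- stats::setNames(
          rep(c("good", "poor"), length.out = length(pats)), pats)
      }
      deltas <- stats::setNames(cats$table$post_value -
                                  cats$table$pre_value,
                                cats$table$patient_id)
      resp <- if (design$n_patients >= 4L)
        responder_comparison(deltas, response) else NULL
      list(dm = dm, dendrogram = hc, concordance = conc,
           top_core = top_core, categories = cats, responder = resp)
    })
    stage_out$methylome <- mres
    targets <- mres$dm[mres$dm$is_target, ]
    report$differential_methylation <- list(
      n_targets = nrow(targets),
      n_significant = sum(targets$fdr < 0.1, na.rm = TRUE),
      top_core = mres$top_core,
      top_gene = targets$gene[1],
      top_logFC = targets$logFC[1],
      top_p = targets$p_value[1],
      top_fdr = targets$fdr[1])
    report$methylome_clustering <- as.list(
      table(factor(mres$concordance$verdict,
                   levels = c("complete", "partial", "none"))))
    report$hypermethylation <- as.list(mres$categories$summary)
    if (!is.null(mres$responder))
      report$responder <- list(t = mres$responder$t,
                               p_value = mres$responder$p_value)
  }

  report$stages_run <- config$stages
  out <- structure(report, class = "summary_report")
  attr(out, "stages") <- stage_out
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(out, config$out_dir)
    manifest <- config
    manifest$design <- unclass(design)
    jsonlite::write_json(unclass(manifest[names(manifest) != "out_dir"]),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
  }
  out
}

# attach consequence/annotation columns from calls onto sharing rows
sharing_annotate <- function(sharing, calls) {
  key_s <- paste(sharing$patient_id, sharing$chrom, sharing$pos,
                 sharing$ref, sharing$alt)
  key_c <- paste(calls$patient_id, calls$chrom, calls$pos, calls$ref,
                 calls$alt)
  idx <- match(key_s, key_c)
  sharing$consequence <- calls$consequence[idx]
  sharing$sift_label <- calls$sift_label[idx]
  sharing$polyphen_label <- calls$polyphen_label[idx]
  sharing
}

#' Write a summary report as JSON and/or markdown
#'
#' The JSON form is schema-checked (required sections for the stages
#' run); the markdown form mirrors the results ordering: clustering
#' concordance, differential methylation, hypermethylation categories,
#' mutation-count comparisons, CNV.
#'
#' @param report a `summary_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @param format any of `"json"`, `"markdown"`.
#' @return (invisibly) the written paths.
#' @export
write_report <- function(report, out_dir, format = c("json", "markdown")) {
  stopifnot(inherits(report, "summary_report"))
  format <- match.arg(format, several.ok = TRUE)
  required <- c("seed", "cohort", "n_patients", "stages_run")
  if ("methylome" %in% report$stages_run)
    required <- c(required, "differential_methylation",
                  "methylome_clustering", "hypermethylation")
  if ("variants" %in% report$stages_run)
    required <- c(required, "private_mutations")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("report is missing required fields: ",
         paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("json" %in% format) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% format) {
    p <- file.path(out_dir, "report.md")
    lines <- c(sprintf("# Cohort analysis report (%s, %d patients, seed %d)",
                       report$cohort, report$n_patients, report$seed), "")
    if (!is.null(report$methylome_clustering))
      lines <- c(lines, "## Methylome clustering concordance",
                 sprintf("- %s: %s", names(report$methylome_clustering),
                         unlist(report$methylome_clustering)), "")
    if (!is.null(report$mutation_clustering))
      lines <- c(lines, "## Mutational clustering concordance",
                 sprintf("- %s: %s", names(report$mutation_clustering),
                         unlist(report$mutation_clustering)), "")
    if (!is.null(report$differential_methylation)) {
      dmt <- report$differential_methylation
      lines <- c(lines, "## Differential methylation (targets)",
                 sprintf("- significant at FDR < 0.1: %d of %d",
                         dmt$n_significant, dmt$n_targets),
                 sprintf("- top target %s (%s): logFC %.4f, P %.3g, FDR %.3g",
                         dmt$top_gene, dmt$top_core, dmt$top_logFC,
                         dmt$top_p, dmt$top_fdr), "")
    }
    if (!is.null(report$hypermethylation))
      lines <- c(lines, "## Hypermethylation (top target region)",
                 sprintf("- pre-treatment: %.0f%% of patients",
                         report$hypermethylation$pct_hyper_pre),
                 sprintf("- post-treatment: %.0f%% of patients",
                         report$hypermethylation$pct_hyper_post), "")
    if (!is.null(report$private_mutations)) {
      pm <- report$private_mutations
      lines <- c(lines, "## Private mutations",
                 sprintf("- split (biopsy/nephrectomy/equal): %s/%s/%s",
                         pm$split$biopsy, pm$split$nephrectomy,
                         pm$split$equal),
                 sprintf("- unpaired t-test: t = %.3f, P = %.3g",
                         pm$t, pm$p_value), "")
    }
    if (!is.null(report$cnv))
      lines <- c(lines, "## Copy number / LOH",
                 sprintf("- LOH segments called: %d",
                         report$cnv$n_loh_segments),
                 sprintf("- paired t-test on CNV counts: P = %.3g",
                         report$cnv$p_value), "")
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
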