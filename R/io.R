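#' @name ithmeth-io
#' @title Plain-text readers and writers for the pipeline's interchange files
#'
#' @description
#' All on-disk formats are plain text: count matrix TSV (rows = core IDs),
#' core definitions BED (0-based half-open on disk, converted to the
#' package's 1-based inclusive convention at the boundary), multi-sample
#' VCF 4.2 for variant calls, BAF and metadata TSV, and truth/report JSON.
NULL

#' Write / read a methylation count matrix as TSV
#'
#' @param counts integer matrix, cores x samples.
#' @param path file path.
#' @return `read_counts_tsv` returns the matrix (rownames = core IDs).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(core_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read methylation core definitions as BED
#'
#' On disk: BED5+ with 0-based half-open coordinates
#' (`chrom, start-1, end, core_id, promoter_flag, gene`).  In memory the
#' package uses 1-based inclusive coordinates.
#'
#' @param cores core annotation `data.frame` (see [core_table()]).
#' @param path file path.
#' @export
write_cores_bed <- function(cores, path) {
  bed <- data.frame(chrom = cores$chrom, start = cores$start - 1L,
                    end = cores$end, name = cores$core_id,
                    promoter = as.integer(cores$promoter),
                    gene = ifelse(is.na(cores$gene), ".", cores$gene))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cores_bed
#' @export
read_cores_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "core_id", "promoter", "gene")
  data.frame(core_id = bed$core_id, chrom = bed$chrom,
             start = bed$start + 1L, end = bed$end,
             promoter = bed$promoter == 1L,
             gene = ifelse(bed$gene == ".", NA, bed$gene),
             stringsAsFactors = FALSE)
}

#' Write / read a generic TSV (sample metadata, BAF records, coverage)
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write variant calls as a multi-sample VCF 4.2
#'
#' One row per unique (chrom, pos, ref, alt); per-sample genotype fields
#' `GT:GQ:AD`, variant-level annotations in INFO
#' (`GENE/CONSEQ/SIFT/PPH/FLANK`).  Samples not carrying the variant get
#' `./.`.
#'
#' @param calls long-format calls as produced by [simulate_variants()].
#' @param meta sample metadata (defines the sample column order).
#' @param path output path (plain text, not bgzipped).
#' @export
write_variants_vcf <- function(calls, meta, path) {
  samples <- meta$sample_id
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  vars <- calls[!duplicated(key), c("chrom", "pos", "ref", "alt", "gene",
                                    "consequence", "sift_label",
                                    "polyphen_label", "flank_seq")]
  vkey <- key[!duplicated(key)]
  ord <- order(vars$chrom, vars$pos, vars$ref, vars$alt)
  vars <- vars[ord, ]; vkey <- vkey[ord]

  gt <- matrix("./.", nrow(vars), length(samples),
               dimnames = list(vkey, samples))
  fmt <- sprintf("%s:%.0f:%d,%d", calls$genotype, calls$GQ,
                 calls$ref_depth, calls$alt_depth)
  gt[cbind(match(key, vkey), match(calls$sample_id, samples))] <- fmt

  info <- sprintf("GENE=%s;CONSEQ=%s;SIFT=%s;PPH=%s;FLANK=%s",
                  vars$gene, vars$consequence,
                  ifelse(is.na(vars$sift_label), ".", vars$sift_label),
                  ifelse(is.na(vars$polyphen_label), ".",
                         vars$polyphen_label),
                  vars$flank_seq)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ithmeth",
    paste0("##INFO=<ID=GENE,Number=1,Type=String,",
           "Description=\"Gene symbol\">"),
    paste0("##INFO=<ID=CONSEQ,Number=1,Type=String,",
           "Description=\"Consequence\">"),
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT label\">",
    "##INFO=<ID=PPH,Number=1,Type=String,Description=\"PolyPhen label\">",
    paste0("##INFO=<ID=FLANK,Number=1,Type=String,",
           "Description=\"Reference context, 10bp either side of REF\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Float,",
           "Description=\"Genotype quality\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allele depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(vars$chrom, vars$pos, ".", vars$ref, vars$alt, ".", "PASS",
                info, "GT:GQ:AD",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF written by [write_variants_vcf()] back into long format
#'
#' Uses `vcfR` for parsing; patient assignment comes from `meta`.
#'
#' @param path VCF path.
#' @param meta sample metadata.
#' @return long-format calls `data.frame` (one row per carrying sample).
#' @export
read_variants_vcf <- function(path, meta) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, "GENE")
  cons <- vcfR::extract.info(v, "CONSEQ")
  sift <- vcfR::extract.info(v, "SIFT")
  pph <- vcfR::extract.info(v, "PPH")
  flank <- vcfR::extract.info(v, "FLANK")
  gt <- vcfR::extract.gt(v, "GT")
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  rows <- list()
  for (j in seq_len(ncol(gt))) {
    s <- colnames(gt)[j]
    present <- !is.na(gt[, j]) & gt[, j] != "./."
    if (!any(present)) next
    adm <- do.call(rbind, strsplit(ad[present, j], ",", fixed = TRUE))
    rd <- as.integer(adm[, 1]); altd <- as.integer(adm[, 2])
    rows[[s]] <- data.frame(
      patient_id = meta$patient_id[match(s, meta$sample_id)],
      sample_id = s,
      chrom = fix$CHROM[present], pos = as.integer(fix$POS[present]),
      ref = fix$REF[present], alt = fix$ALT[present],
      gene = info[present], genotype = gt[present, j],
      GQ = gq[present, j], ref_depth = rd, alt_depth = altd,
      VAF = altd / (rd + altd), flank_seq = flank[present],
      consequence = cons[present],
      sift_label = ifelse(sift[present] == ".", NA, sift[present]),
      polyphen_label = ifelse(pph[present] == ".", NA, pph[present]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write simulation ground truth (or any list) as JSON
#'
#' @param x list / data.frame.
#' @param path file path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
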