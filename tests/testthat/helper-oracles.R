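# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Brute-force Benjamini-Hochberg from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force homopolymer distance: scan every position of the flank for
# runs of >= min_len identical bases, then take the minimum gap to the
# affected reference span (positions span[1]..span[2]); 0 means overlap.
brute_force_hp_distance <- function(flank, span, min_len = 4L) {
  chars <- strsplit(flank, "")[[1]]
  best <- Inf
  for (s in seq_along(chars)) {
    for (e in s:length(chars)) {
      if (length(unique(chars[s:e])) > 1L) break
      if (chars[s] == "N") break
      if (e - s + 1L >= min_len) {
        gap <- max(0, max(s - span[2], span[1] - e))
        best <- min(best, gap)
      }
    }
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p by enumerating index subsets
# (positions, not values), doubling the smaller tail.
brute_force_wilcoxon <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(r), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

# Sharing category straight from the definitions, given the carrier
# pattern over a patient's samples.
brute_force_sharing <- function(in_normal, n_tumor_carrying, n_tumor_total) {
  if (in_normal) return("germline")
  if (n_tumor_carrying == n_tumor_total) return("truncal")
  if (n_tumor_carrying == 1L) return("private")
  "shared"
}

# Build a minimal long-format call table for one variant over the given
# carrier samples of a small cohort.
make_calls <- function(carriers, patient = "P01", chrom = "chr1",
                       pos = 100L, ref = "A", alt = "G") {
  data.frame(patient_id = patient, sample_id = carriers, chrom = chrom,
             pos = pos, ref = ref, alt = alt, gene = "VHL",
             genotype = "0/1", GQ = 90, ref_depth = 50L, alt_depth = 50L,
             VAF = 0.5, flank_seq = paste0(strrep("ACGT", 2), "AC", ref,
                                           strrep("TGCA", 2), "TG"),
             consequence = "missense", sift_label = "damaging",
             polyphen_label = "benign", stringsAsFactors = FALSE)
}

# Metadata for one patient with a normal, a biopsy and k-1 nephrectomies.
make_meta <- function(k_tumor = 4L, patient = "P01") {
  data.frame(
    sample_id = c(paste0(patient, "_N"), paste0(patient, "_Bx"),
                  sprintf("%s_Nx%d", patient, seq_len(k_tumor - 1L))),
    patient_id = patient,
    tissue = c("normal", "biopsy", rep("nephrectomy", k_tumor - 1L)),
    timepoint = c(NA, "pre", rep("post", k_tumor - 1L)),
    cohort = "sunitinib", stringsAsFactors = FALSE)
}
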