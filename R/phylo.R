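#' Manhattan distance matrix over binary mutation profiles
#'
#' `d(i, j) = sum_k |x_ik - x_jk|` over the feature keys where both
#' profiles are observed; pairs with missing entries are rescaled by
#' `(total keys / observed keys)` so distances stay comparable.
#'
#' @param profiles numeric matrix, samples x features (entries 0/1, NA
#'   allowed), with rownames as sample ids.
#' @return symmetric labelled distance matrix with zero diagonal.
#' @export
manhattan_distance <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  n <- nrow(profiles); p <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(profiles[i, ]) & !is.na(profiles[j, ])
    if (!any(ok)) stop("no shared observed keys between ",
                       rownames(profiles)[i], " and ",
                       rownames(profiles)[j])
    d[i, j] <- d[j, i] <- sum(abs(profiles[i, ok] - profiles[j, ok])) *
      p / sum(ok)
  }
  d
}

#' BioNJ phylogenetic tree from a distance matrix
#'
#' Neighbor joining with the BioNJ first-order variance-weighted
#' distance reduction: at each step the pair minimising the Q criterion
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` is joined, branch lengths follow
#' the standard NJ two-point formulas, and the reduced distances use the
#' weight `lambda` that minimises the variance of the new distances under
#' the model `Var(d) ~ d` (clamped to `[0, 1]`).  Ties on Q are broken by
#' the lexicographically smallest pair of subtree labels, making the
#' result deterministic.  Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sibling branch, preserving
#' the joined pair's distance.
#'
#' @param d symmetric non-negative distance matrix (labelled), `n >= 3`.
#' @return an unrooted `ape::phylo` tree (root trifurcation).
#' @export
bionj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))

  D <- d; V <- d
  node <- labels                 # Newick fragment per active node
  rep_label <- labels            # smallest tip label per subtree (ties)

  fmt <- function(x) sprintf("%.15g", x)
  clamp2 <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }

  while (nrow(D) > 3L) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      lr <- sort(c(rep_label[ij[1]], rep_label[ij[2]]))
      paste(lr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    b <- clamp2(bi, bj)

    others <- setdiff(seq_len(n), c(i, j))
    lambda <- 0.5
    if (V[i, j] > 0 && n > 3)
      lambda <- 0.5 + sum(V[j, others] - V[i, others]) /
        (2 * (n - 2) * V[i, j])
    lambda <- min(1, max(0, lambda))

    newD <- lambda * (D[i, others] - b[1]) +
      (1 - lambda) * (D[j, others] - b[2])
    newV <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
      lambda * (1 - lambda) * V[i, j]
    new_node <- paste0("(", node[i], ":", fmt(b[1]), ",",
                       node[j], ":", fmt(b[2]), ")")
    new_rep <- min(rep_label[i], rep_label[j])

    keep <- others
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD),
               c(newD, 0))
    V <- rbind(cbind(V[keep, keep, drop = FALSE], newV),
               c(newV, 0))
    node <- c(node[keep], new_node)
    rep_label <- c(rep_label[keep], new_rep)
  }

  # final three nodes: three-point formulas around the central node
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", node[1], ":", fmt(max(la, 0)), ",",
                   node[2], ":", fmt(max(lb, 0)), ",",
                   node[3], ":", fmt(max(lc, 0)), ");")
  ape::read.tree(text = newick)
}

# Leaf set below the child node of every edge of a phylo tree.
edge_leafsets <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(e) sort(below[[tree$edge[e, 2]]]))
}

#' Label tree branches with consistent candidate driver mutations
#'
#' A driver labels branch `e` when its carrier (presence) set equals the
#' leaf set on one side of `e`.  Drivers present in every leaf are
#' truncal: on a tree that contains a normal/outgroup leaf they label the
#' edge separating it from the tumor clade, otherwise they are returned
#' in the `truncal` element.  Drivers whose presence set matches no edge
#' bipartition are returned as `inconsistent` (homoplasy).
#'
#' @param tree an `ape::phylo` tree.
#' @param presence named list: driver id -> character vector of carrier
#'   leaf labels.
#' @param outgroup optional leaf label of a non-tumor outgroup.
#' @return list with `edge_labels` (character vector per edge, collapsed
#'   with `","`), `truncal`, `inconsistent`; the tree is returned in
#'   `tree` with `edge_labels` attached as `tree$edge.label`.
#' @export
label_branches <- function(tree, presence, outgroup = NULL) {
  leaves <- sort(tree$tip.label)
  for (nm in names(presence)) {
    bad <- setdiff(presence[[nm]], leaves)
    if (length(bad))
      stop("presence set of ", nm, " has leaves absent from tree: ",
           paste(bad, collapse = ", "))
  }
  sets <- edge_leafsets(tree)
  edge_labels <- rep("", nrow(tree$edge))
  truncal <- character(); inconsistent <- character()
  tumor_leaves <- setdiff(leaves, outgroup)
  for (nm in names(presence)) {
    pset <- sort(unique(presence[[nm]]))
    if (identical(pset, sort(tumor_leaves))) {
      truncal <- c(truncal, nm)
      next
    }
    hit <- FALSE
    for (e in seq_along(sets)) {
      side <- sets[[e]]
      if (identical(pset, side) ||
          identical(pset, sort(setdiff(leaves, side)))) {
        edge_labels[e] <- if (edge_labels[e] == "") nm
                          else paste(edge_labels[e], nm, sep = ",")
        hit <- TRUE
        break
      }
    }
    if (!hit) inconsistent <- c(inconsistent, nm)
  }
  if (!is.null(outgroup)) {
    # truncal drivers sit on the edge separating the outgroup
    og_edge <- which(vapply(sets, function(s)
      identical(s, sort(tumor_leaves)) || identical(s, outgroup),
      logical(1)))[1]
    if (!is.na(og_edge) && length(truncal)) {
      lab <- paste(truncal, collapse = ",")
      edge_labels[og_edge] <- if (edge_labels[og_edge] == "") lab
        else paste(edge_labels[og_edge], lab, sep = ",")
    }
  }
  tree$edge.label <- edge_labels
  list(tree = tree, edge_labels = edge_labels, truncal = truncal,
       inconsistent = inconsistent)
}

#' Agglomerative hierarchical clustering of cohort samples
#'
#' Complete-linkage clustering: Euclidean distance for methylation
#' matrices, missing-aware Manhattan distance ([manhattan_distance()])
#' for binary mutation profiles.
#'
#' @param x samples x features numeric matrix (rownames = sample ids), or
#'   a precomputed distance matrix / `dist`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param linkage linkage method for [stats::hclust()].
#' @return an `hclust` object.
#' @export
cohort_dendrogram <- function(x, metric = c("euclidean", "manhattan"),
                              linkage = "complete") {
  metric <- match.arg(metric)
  if (inherits(x, "dist")) {
    d <- x
  } else if (is.matrix(x) && isTRUE(all.equal(unname(x), unname(t(x)))) &&
             all(diag(x) == 0) && nrow(x) == ncol(x)) {
    d <- stats::as.dist(x)
  } else {
    stopifnot(is.matrix(x), nrow(x) >= 2L)
    if (stats::sd(as.numeric(x), na.rm = TRUE) == 0)
      stop("constant matrix: zero variance everywhere")
    d <- if (metric == "euclidean") stats::dist(x, method = "euclidean")
         else stats::as.dist(manhattan_distance(x))
  }
  stats::hclust(d, method = linkage)
}

#' Score per-patient clustering concordance on a cohort dendrogram
#'
#' For each patient: `complete` when some dendrogram node's leaf set
#' equals exactly the patient's tumor-sample set; `partial` when some
#' node's leaf set is a proper subset (size >= 2) of the patient's
#' samples (and complete does not hold); `none` otherwise.  A patient
#' with a single sample is trivially complete and flagged.
#'
#' @param hc an `hclust` over tumor samples.
#' @param meta sample metadata mapping every leaf to a patient.
#' @return `data.frame(patient_id, n_samples, verdict, flagged)`.
#' @export
score_concordance <- function(hc, meta) {
  leaves <- hc$labels
  if (any(!leaves %in% meta$sample_id))
    stop("dendrogram leaves missing from metadata")
  patient <- meta$patient_id[match(leaves, meta$sample_id)]

  # leaf sets of all internal nodes of the dendrogram
  n <- length(leaves)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) leaves[-v] else sets[[v]]
    sets[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
  }

  res <- lapply(unique(patient), function(p) {
    own <- sort(leaves[patient == p])
    flagged <- length(own) == 1L
    verdict <- if (flagged) "complete"
    else if (any(vapply(sets, identical, logical(1), y = own))) "complete"
    else if (any(vapply(sets, function(s)
      length(s) >= 2L && length(s) < length(own) && all(s %in% own),
      logical(1)))) "partial"
    else "none"
    data.frame(patient_id = p, n_samples = length(own), verdict = verdict,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build per-sample binary mutation profiles from classified variants
#'
#' Feature keys are somatic variant alleles (`chrom:pos:ref:alt`) and,
#' optionally, gene-level CNV states (`gene:state`); entries are 0/1
#' presence calls per tumor sample.
#'
#' @param sharing classified variants ([classify_sharing()]), germline
#'   excluded automatically.
#' @param meta sample metadata.
#' @param cnv optional per-sample CNV calls
#'   (`data.frame(sample_id, gene, state)`), non-neutral states become
#'   features.
#' @return samples x features 0/1 matrix (tumor samples only).
#' @export
mutation_profiles <- function(sharing, meta, cnv = NULL) {
  som <- sharing[sharing$category != "germline", , drop = FALSE]
  tum <- meta[meta$tissue != "normal", , drop = FALSE]
  keys <- unique(paste(som$chrom, som$pos, som$ref, som$alt, sep = ":"))
  cnv_keys <- character()
  if (!is.null(cnv)) {
    cnv <- cnv[cnv$state != "neutral", , drop = FALSE]
    cnv_keys <- unique(paste(cnv$gene, cnv$state, sep = ":"))
  }
  m <- matrix(0L, nrow(tum), length(keys) + length(cnv_keys),
              dimnames = list(tum$sample_id, c(keys, cnv_keys)))
  for (i in seq_len(nrow(som))) {
    k <- paste(som$chrom[i], som$pos[i], som$ref[i], som$alt[i], sep = ":")
    carriers <- intersect(strsplit(som$carriers[i], ",")[[1]],
                          tum$sample_id)
    m[carriers, k] <- 1L
  }
  if (!is.null(cnv) && nrow(cnv)) {
    for (i in seq_len(nrow(cnv))) {
      k <- paste(cnv$gene[i], cnv$state[i], sep = ":")
      if (cnv$sample_id[i] %in% rownames(m)) m[cnv$sample_id[i], k] <- 1L
    }
  }
  m
}
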