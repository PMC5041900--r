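test_that("Manhattan distances: hand cases, metric property, missing rescale", {
  m <- rbind(a = c(1, 0, 1), b = c(0, 0, 1), c = c(1, 1, 0))
  d <- manhattan_distance(m)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 2)
  expect_equal(d, t(d))
  set.seed(2)
  r <- matrix(rbinom(60, 1, 0.5), nrow = 6,
              dimnames = list(letters[1:6], NULL))
  dr <- manhattan_distance(r)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(dr[i, j], dr[i, k] + dr[k, j] + 1e-12)
  # a pair observed on half the keys is rescaled by 2
  mm <- rbind(a = c(1, 0, NA, NA), b = c(0, 0, 1, 1))
  expect_equal(manhattan_distance(mm)["a", "b"], 1 * 4 / 2)
  expect_error(manhattan_distance(rbind(a = c(NA, 1), b = c(1, NA))),
               "no shared")
})

test_that("three-taxon trees use the three-point formulas", {
  d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["A"]), (3 + 8 - 9) / 2)
  expect_equal(unname(len["B"]), (3 + 9 - 8) / 2)
  expect_equal(unname(len["C"]), (8 + 9 - 3) / 2)
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    gen$node.label <- NULL
    D <- ape::cophenetic.phylo(gen)
    rec <- bionj_tree(D)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)]
                      - D)), 1e-9)
  }
})

test_that("BioNJ agrees with plain NJ on ultrametric matrices", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    # ultrametric tree via coalescent
    gen <- ape::rcoal(n)
    D <- ape::cophenetic.phylo(gen)
    expect_equal(phangorn::RF.dist(bionj_tree(D), ape::nj(D)), 0)
  }
})

test_that("degenerate or invalid matrices are rejected; ties deterministic", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(bionj_tree(matrix(0, 2, 2)), "3 taxa")
  m <- matrix(1, 4, 4); diag(m) <- 0
  m2 <- m; m2[1, 2] <- -1; m2[2, 1] <- -1
  expect_error(bionj_tree(m2), "negative")
  m3 <- m; m3[1, 2] <- 2
  expect_error(bionj_tree(m3), "symmetric")
  dimnames(m) <- list(letters[1:4], letters[1:4])
  expect_equal(ape::write.tree(bionj_tree(m)),
               ape::write.tree(bionj_tree(m)))
})

test_that("Newick round-trip preserves topology and branch lengths", {
  set.seed(3)
  gen <- ape::rtree(8, br = function(k) runif(k, 0.05, 1.5))
  D <- ape::cophenetic.phylo(gen)
  tr <- bionj_tree(D)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_lt(max(abs(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label]
                    - ape::cophenetic.phylo(tr))), 1e-6)
})

test_that("branch labelling places drivers on consistent edges only", {
  # fixed 4-leaf tree ((A,B),(C,D))
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr <- ape::unroot(tr)
  presence <- list(trunk = c("A", "B", "C", "D"), solo = "B",
                   clade = c("A", "B"), cross = c("A", "C"))
  got <- label_branches(tr, presence)
  expect_equal(got$truncal, "trunk")
  expect_equal(got$inconsistent, "cross")
  # solo labels B's pendant edge
  b_edge <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
  expect_match(got$edge_labels[b_edge], "solo")
  # clade labels an internal edge
  expect_true(any(grepl("clade", got$edge_labels)))
  # every 2-leaf subset that is not a clade of this tree is inconsistent
  pairs <- combn(c("A", "B", "C", "D"), 2, simplify = FALSE)
  for (pr in pairs) {
    res <- label_branches(tr, setNames(list(pr), "x"))
    is_clade <- identical(sort(pr), c("A", "B")) ||
      identical(sort(pr), c("C", "D"))
    expect_equal(length(res$inconsistent) == 0, is_clade,
                 label = paste(pr, collapse = ","))
  }
  expect_error(label_branches(tr, list(bad = c("A", "Z"))), "absent")
})

test_that("truncal drivers label the edge to the tumor clade given an outgroup", {
  tr <- ape::unroot(ape::read.tree(
    text = "(((T1:1,T2:1):1,T3:1):2,N:3);"))
  got <- label_branches(tr, list(drv = c("T1", "T2", "T3")),
                        outgroup = "N")
  expect_equal(got$truncal, "drv")
  n_edge <- which(tr$edge[, 2] == which(tr$tip.label == "N"))
  labelled <- which(got$edge_labels != "")
  expect_true(length(labelled) == 1)
})

test_that("complete-linkage dendrogram has the documented merge heights", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cohort_dendrogram(d)
  expect_equal(hc$height, c(1, 10))
  expect_false(is.unsorted(hc$height))
  # two samples: a single merge at their distance
  m2 <- rbind(a = c(0, 1), b = c(1, 1))
  hc2 <- cohort_dendrogram(m2, metric = "manhattan")
  expect_equal(length(hc2$height), 1L)
  expect_equal(hc2$height, 1)
  expect_error(cohort_dendrogram(matrix(1, 3, 4)), "constant")
})

test_that("concordance verdicts follow the node-leafset rules", {
  meta <- data.frame(
    sample_id = c("P1a", "P1b", "P1c", "P2a"),
    patient_id = c("P1", "P1", "P1", "P2"),
    tissue = "nephrectomy", stringsAsFactors = FALSE)
  # force dendrogram ((P1a,P1b),(P1c,P2a))
  d <- matrix(10, 4, 4,
              dimnames = list(meta$sample_id, meta$sample_id))
  diag(d) <- 0
  d["P1a", "P1b"] <- d["P1b", "P1a"] <- 1
  d["P1c", "P2a"] <- d["P2a", "P1c"] <- 2
  hc <- cohort_dendrogram(d)
  got <- score_concordance(hc, meta)
  expect_equal(got$verdict[got$patient_id == "P1"], "partial")
  expect_equal(got$verdict[got$patient_id == "P2"], "complete")
  expect_true(got$flagged[got$patient_id == "P2"])
  # single-patient cohort is complete
  one <- meta[meta$patient_id == "P1", ]
  d1 <- d[one$sample_id, one$sample_id]
  expect_equal(score_concordance(cohort_dendrogram(d1), one)$verdict,
               "complete")
  # verdicts invariant to leaf order
  perm <- c(3, 1, 4, 2)
  hc2 <- cohort_dendrogram(d[perm, perm])
  got2 <- score_concordance(hc2, meta)
  expect_equal(got2$verdict[match(got$patient_id, got2$patient_id)],
               got$verdict)
})

test_that("tree total length is invariant under leaf relabeling", {
  set.seed(5)
  gen <- ape::rtree(7, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(gen)
  perm <- sample(nrow(D))
  t1 <- bionj_tree(D)
  t2 <- bionj_tree(D[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
})
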