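# Single-linkage clustering of unit cells, threshold cutting, summaries and
# tree export.

dist_from_vec <- function(v, n) {
  d <- numeric(n * (n - 1) / 2)
  d[] <- v
  attr(d, "Size") <- n
  class(d) <- "dist"
  d
}

test_that("single linkage merges at the minimum inter-cluster distance", {
  # d(1,2)=1, d(1,3)=10, d(2,3)=10
  hc <- single_linkage(dist_from_vec(c(1, 10, 10), 3))
  expect_equal(hc$height, c(1, 10))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # chain: second merge at 2, not at the complete-linkage 100
  hc2 <- single_linkage(dist_from_vec(c(1, 100, 2), 3))
  expect_equal(hc2$height, c(1, 2))

  expect_error(single_linkage(dist(matrix(1, 1, 2))), "at least two")
})

test_that("merge heights match the naive rescan oracle on random instances", {
  set.seed(201)
  for (trial in 1:150) {
    n <- sample(3:20, 1)
    D <- dist_from_vec(runif(n * (n - 1) / 2, 0, 100), n)
    hc <- single_linkage(D)
    expect_equal(hc$height, naive_single_linkage_heights(D), tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= 0))
  }
})

test_that("threshold cut is strict and flags singletons", {
  hc <- single_linkage(dist_from_vec(c(1, 10, 10), 3))
  # below the first merge: all singletons
  a0 <- cut_threshold(hc, 0.5)
  expect_equal(length(unique(a0$cluster)), 3)
  expect_true(all(a0$singleton))
  # above the last merge: one cluster
  a1 <- cut_threshold(hc, 11)
  expect_equal(unique(a1$cluster), 1L)
  # a merge exactly at the threshold does not join
  a2 <- cut_threshold(hc, 10)
  expect_equal(length(unique(a2$cluster)), 2)
  expect_error(cut_threshold(hc, -1), "positive")
})

test_that("pairwise distance matrix entries match per-pair metric calls", {
  set.seed(202)
  cells <- t(vapply(1:8, function(i) random_cell(), numeric(6)))
  for (metric in c("euclidean", "ncdist")) {
    D <- as.matrix(cell_distance_matrix(as_cells_tbl(cells), metric = metric))
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(D[i, j], cell_distance(cells[i, ], cells[j, ], metric = metric),
                   tolerance = 1e-8, label = sprintf("%s pair (%d,%d)", metric, i, j))
    }
  }
  # identical and near-identical cells
  two <- as_cells_tbl(rbind(unit_cell(10, 11, 12), unit_cell(10, 11, 12)))
  expect_equal(as.numeric(cell_distance_matrix(two)), 0)
  three <- as_cells_tbl(rbind(unit_cell(10, 11, 12), unit_cell(10, 11, 12),
                              unit_cell(30, 31, 32)))
  expect_equal(sum(as.numeric(cell_distance_matrix(three)) == 0), 1)
})

test_that("two synthetic populations separate exactly at the 5000 A^2 threshold", {
  ds <- generate_frames(two_form_config(seed = 301, misindex_fraction = 0))
  cl <- cluster_cells(ds$frames, threshold = 5000)
  expect_equal(sum(!cl$summary$singleton), 2)
  # zero cross-assignments: cluster label is a function of the true population
  tb <- tidy(cl)
  expect_equal(tb$frame_id, ds$truth$frame_id)
  expect_equal(length(unique(paste(tb$cluster, ds$truth$population))), 2)
})

test_that("cluster summaries recover medians and spreads", {
  # single-member cluster: median = the cell, MAD = 0
  one <- as_cells_tbl(matrix(unit_cell(10, 11, 12), 1, 6, byrow = TRUE))
  s1 <- summarize_clusters(one, tibble::tibble(cluster = 1L, singleton = TRUE))
  expect_equal(s1$a, 10); expect_equal(s1$mad_a, 0)
  expect_true(s1$singleton)

  # symmetric jitter around a center on 3 members: median = center
  center <- unit_cell(20, 25, 30)
  mat <- rbind(center, center + c(0.3, 0, 0, 0, 0, 0), center - c(0.3, 0, 0, 0, 0, 0))
  s3 <- summarize_clusters(as_cells_tbl(mat),
                           tibble::tibble(cluster = rep(1L, 3), singleton = FALSE))
  expect_equal(s3$a, 20, tolerance = 1e-12)
  expect_equal(s3$n_members, 3L)

  # member counts sum to n and medians recover generator medians
  ds <- generate_frames(two_form_config(seed = 302))
  cl <- cluster_cells(ds$frames)
  expect_equal(sum(cl$summary$n_members), nrow(ds$frames))
  big <- cl$summary[order(-cl$summary$n_members), ][1:2, ]
  gen <- rbind(c(69, 169, 288), c(69, 146, 170))
  for (k in 1:2) {
    n_k <- big$n_members[k]
    tol <- 3 * 0.5 / sqrt(n_k) * 1.5   # 3 sigma of a median of n_k jittered edges
    expect_equal(unlist(big[k, c("a", "b", "c")]), gen[k, ],
                 tolerance = tol / min(gen[k, ]), ignore_attr = TRUE)
  }
})

test_that("permuting frame order permutes labels but preserves the partition", {
  ds <- generate_frames(two_form_config(n_frames = 30, seed = 303))
  cl1 <- cluster_cells(ds$frames)
  set.seed(304)
  perm <- sample(nrow(ds$frames))
  cl2 <- cluster_cells(ds$frames[perm, ])
  part <- function(cl) {
    unname(lapply(split(tidy(cl)$frame_id, tidy(cl)$cluster), sort))
  }
  expect_setequal(part(cl1), part(cl2))
})

test_that("Newick export round-trips topology and heights through ape", {
  skip_if_not_installed("ape")
  # two leaves merged at h: "(A:h,B:h);" shape
  hc <- single_linkage(dist_from_vec(5, 2))
  hc$labels <- c("A", "B")
  expect_match(dendrogram_to_newick(hc), "^\\(A:5,B:5\\);$|^\\(B:5,A:5\\);$")

  set.seed(205)
  for (trial in 1:5) {
    n <- 15
    D <- dist_from_vec(runif(n * (n - 1) / 2, 1, 50), n)
    hc <- single_linkage(D)
    hc$labels <- sprintf("t%02d", 1:n)
    tree <- ape::read.tree(text = dendrogram_to_newick(hc))
    coph_ape <- ape::cophenetic.phylo(tree) / 2      # path length = 2 x height
    coph_hc <- as.matrix(stats::cophenetic(hc))
    expect_equal(coph_ape[rownames(coph_hc), colnames(coph_hc)], coph_hc,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("clustering log and glance agree on the counts", {
  ds <- generate_frames(two_form_config(n_frames = 40, seed = 306))
  cl <- cluster_cells(ds$frames)
  path <- withr::local_tempfile(fileext = ".txt")
  write_clustering_log(cl, path)
  log <- readLines(path)
  g <- glance(cl)
  expect_true(any(grepl(sprintf("frames: %d", g$n_frames), log)))
  expect_true(any(grepl(sprintf("clusters: %d", g$n_clusters), log)))
  expect_equal(sum(grepl("^cluster ", log)), g$n_clusters)
})
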