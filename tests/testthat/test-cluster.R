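toy_features <- function() {
  tibble::tibble(
    neuron_id = sprintf("n%02d", 1:6),
    label = c("I", "I", "II", "III", "Others", "III"),
    excluded = FALSE,
    ih_140 = c(1.5, 1.4, 0.6, 0.1, 3.2, NA),
    sag_80 = c(6, 7, 10, 0, 0, 0.2),
    rebound_80 = c(0, 0, 5, 0, 0, 0),
    mfr_step = c(450, 400, 200, 350, 750, 300),
    fsl_10 = c(110, 95, 40, 76, NA, 80),
    first_isi_40 = c(65, 70, 17, 55, NA, 60))
}

test_that("feature matrices drop incomplete rows and Others for the six-set", {
  f <- toy_features()
  m3 <- build_feature_matrix(f, "three")
  expect_equal(nrow(m3), 5)           # n06 lacks ih_140
  expect_equal(attr(m3, "dropped"), "n06")
  expect_named(m3, c("neuron_id", "ih_140", "sag_80", "rebound_80"))
  m6 <- build_feature_matrix(f, "six")
  expect_false("n05" %in% m6$neuron_id)  # Others removed a priori
  expect_equal(nrow(m6), 4)
  complete <- dplyr::filter(f, !is.na(ih_140))
  expect_equal(nrow(build_feature_matrix(complete, "three")), nrow(complete))
  expect_error(build_feature_matrix(f["neuron_id"], "three"), "lacks")
})

test_that("standardization is an invertible z-score and rejects constants", {
  m <- build_feature_matrix(toy_features(), "three")
  z <- standardize(m)
  for (cn in c("ih_140", "sag_80", "rebound_80")) {
    expect_lt(abs(mean(z[[cn]])), 1e-12)
    expect_lt(abs(sd(z[[cn]]) - 1), 1e-12)
  }
  back <- unstandardize(z)
  expect_equal(back$sag_80, m$sag_80, tolerance = 1e-10)
  bad <- m; bad$rebound_80 <- 1
  expect_error(standardize(bad), "rebound_80")
})

test_that("ward linkage base cases follow the ward.D2 convention", {
  # n = 2: single merge at the Euclidean distance
  x <- matrix(c(0, 3, 4, 0), 2, 2)
  tr <- ward_linkage(x, scale = FALSE)
  expect_equal(tr$height, 5)
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))
  # identical rows merge at height zero first
  y <- rbind(c(1, 1), c(1, 1), c(5, 9))
  tr2 <- ward_linkage(y, scale = FALSE)
  expect_equal(tr2$height[1], 0)
  expect_equal(sort(tr2$merge[1, ]), c(-2, -1))
  # 1D points {0, 1, 10, 11}: pairs first, then the top join
  z <- matrix(c(0, 1, 10, 11), 4, 1)
  tr3 <- ward_linkage(z, scale = FALSE)
  expect_equal(sort(tr3$merge[1, ]), c(-2, -1))
  expect_equal(sort(tr3$merge[2, ]), c(-4, -3))
  orc <- oracle_ward(z)
  expect_equal(tr3$height, orc$height)
  expect_error(ward_linkage(matrix(1, 1, 1)), "2 rows")
})

test_that("merge sequence and heights equal the exhaustive oracle", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    tr <- ward_linkage(x, scale = FALSE)
    orc <- oracle_ward(x)
    expect_equal(tr$merge, orc$merge)
    expect_equal(tr$height, orc$height, tolerance = 1e-9)
  }
})

test_that("heights agree with stats::hclust ward.D2 and survive permutation", {
  set.seed(7)
  x <- matrix(rnorm(20 * 4), 20, 4)
  tr <- ward_linkage(x, scale = FALSE)
  hc <- stats::hclust(dist(x), method = "ward.D2")
  expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-9)
  perm <- sample(20)
  tr_p <- ward_linkage(x[perm, ], scale = FALSE)
  expect_equal(sort(tr_p$height), sort(tr$height), tolerance = 1e-9)
})

test_that("tree cuts partition rows and agreement reports purity", {
  set.seed(1)
  x <- rbind(matrix(rnorm(10, 0, .2), 5, 2),
             matrix(rnorm(10, 5, .2), 5, 2))
  rownames(x) <- sprintf("n%02d", 1:10)
  tr <- ward_linkage(x, scale = FALSE)
  expect_equal(nrow(cut_clusters(tr, 10)), 10)
  expect_equal(dplyr::n_distinct(cut_clusters(tr, 10)$cluster), 10)
  expect_equal(dplyr::n_distinct(cut_clusters(tr, 1)$cluster), 1)
  cl <- cut_clusters(tr, 2)
  labs <- tibble::tibble(neuron_id = rownames(x),
                         label = rep(c("A", "B"), each = 5))
  ag <- cluster_agreement(cl, labs)
  expect_equal(nrow(ag$purity), 2)
  expect_true(all(ag$purity$purity >= 0 & ag$purity$purity <= 1))
  expect_equal(ag$overall, 1)
  expect_setequal(ag$purity$majority_label, c("A", "B"))
  td <- tidy(ag)
  expect_equal(td, ag$purity)
})

test_that("newick export round-trips the topology", {
  # 2-leaf tree: "(a:h/2,b:h/2);"
  x <- matrix(c(0, 3, 4, 0), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  tr <- ward_linkage(x, scale = FALSE)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(tr, path)
  txt <- readLines(path)
  expect_match(txt, "^\\([ab]:2.5,[ab]:2.5\\);$")
  # larger tree parses back to the same topology
  set.seed(3)
  y <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(letters[1:8], NULL))
  tr2 <- ward_linkage(y, scale = FALSE)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(tr2, path2)
  phy <- ape::read.tree(path2)
  expect_equal(sort(phy$tip.label), sort(letters[1:8]))
  expect_true(ape::all.equal.phylo(phy, ape::as.phylo(tr2),
                                   use.edge.length = FALSE))
})

test_that("heatmap TSV rows follow the dendrogram leaf order", {
  m <- build_feature_matrix(toy_features(), "three")
  tr <- ward_linkage(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_heatmap(standardize(m), tr,
                        toy_features()[c("neuron_id", "label")], path)
  expect_true(file.exists(path))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$neuron_id, tr$labels[tr$order])
  expect_equal(out$neuron_id, tr$labels[tr$order])
})

test_that("3D scatter export keeps raw values and complete rows only", {
  f <- tibble::tibble(neuron_id = c("a", "b", "c"),
                      evoked_60 = c(8, 10, NA),
                      rebound_80 = c(0, 5, 1),
                      sag_80 = c(6.2, 10.1, 3))
  sc <- scatter3d_export(f, tibble::tibble(neuron_id = c("a", "b", "c"),
                                           label = c("I", "II", "I")))
  expect_equal(nrow(sc), 2)
  expect_equal(sc$sag_80, c(6.2, 10.1))  # unscaled raw values
  expect_named(sc, c("neuron_id", "evoked_60", "rebound_80", "sag_80",
                     "label"))
  empty <- scatter3d_export(f[0, ])
  expect_equal(nrow(empty), 0)
})
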