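test_that("C-alpha distances are plain Euclidean distances", {
  m <- mapped_from_points(rbind(c(0, 0, 0), c(3, 4, 0)))
  dm <- distance_matrix(m)
  expect_equal(dm$d[1, 2], 5.0)
  expect_equal(diag(dm$d), c(0, 0), ignore_attr = TRUE)

  single <- mapped_from_points(matrix(c(1, 2, 3), nrow = 1))
  dm1 <- distance_matrix(single)
  expect_equal(dim(dm1$d), c(1L, 1L))
  expect_equal(dm1$d[1, 1], 0)

  dup <- mapped_from_points(rbind(c(0, 0, 0), c(1, 0, 0)),
                            labels = c("X1Y (A)", "X1Y (A)"))
  expect_error(distance_matrix(dup), "duplicate")

  set.seed(11)
  pts <- matrix(runif(5 * 3, 0, 50), ncol = 3)
  dm5 <- distance_matrix(mapped_from_points(pts))
  brute <- outer(seq_len(5), seq_len(5),
                 Vectorize(function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))))
  expect_equal(unname(dm5$d), brute, tolerance = 1e-12)
})

test_that("the worked collinear example merges at heights 1, 2 and 10.5", {
  m <- mapped_from_points(cbind(c(0, 1, 10, 12), 0, 0),
                          labels = c("a (A)", "b (A)", "c (A)", "d (A)"))
  tree <- average_linkage(distance_matrix(m))
  heights <- vapply(tree$merges, `[[`, numeric(1), "height")
  expect_equal(heights, c(1, 2, 10.5))
  expect_setequal(tree$merges[[3]]$members_a, c("a (A)", "b (A)"))
  expect_setequal(tree$merges[[3]]$members_b, c("c (A)", "d (A)"))
  cut <- cut_tree(tree, 5)
  expect_equal(nrow(cut$clusters), 2L)
  expect_equal(sort(cut$clusters$members),
               c("a (A), b (A)", "c (A), d (A)"))
})

test_that("merge heights agree with a brute-force cross-pair-mean oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    pts <- matrix(runif(n * 3, 0, 50), ncol = 3)
    m <- mapped_from_points(pts)
    dm <- distance_matrix(m)
    tree <- average_linkage(dm)
    got <- vapply(tree$merges, `[[`, numeric(1), "height")
    want <- oracle_average_linkage(dm$d, dm$labels)
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(all(diff(got) >= -1e-9))
  }
})

test_that("merge heights match stats::hclust average linkage", {
  set.seed(7)
  pts <- matrix(runif(10 * 3, 0, 50), ncol = 3)
  dm <- distance_matrix(mapped_from_points(pts))
  tree <- average_linkage(dm)
  hc <- stats::hclust(stats::as.dist(dm$d), method = "average")
  expect_equal(vapply(tree$merges, `[[`, numeric(1), "height"), hc$height,
               tolerance = 1e-9)
  expect_equal(stats::cutree(stats::as.hclust(tree), h = 15),
               stats::cutree(hc, h = 15), ignore_attr = TRUE)
})

test_that("two points merge once at their distance; trivial cuts behave", {
  m <- mapped_from_points(rbind(c(0, 0, 0), c(0, 0, 7)),
                          labels = c("p (A)", "q (A)"))
  tree <- average_linkage(distance_matrix(m))
  expect_length(tree$merges, 1L)
  expect_equal(tree$merges[[1]]$height, 7)
  below <- cut_tree(tree, 1)
  expect_equal(nrow(below$clusters), 0L)
  expect_length(below$singletons, 2L)
  above <- cut_tree(tree, 100)
  expect_equal(above$clusters$size, 2L)
})

test_that("cut partitions are invariant under input permutation", {
  set.seed(99)
  pts <- matrix(runif(7 * 3, 0, 40), ncol = 3)
  labels <- sprintf("V%d (A)", 1:7)
  base <- cut_tree(average_linkage(distance_matrix(
    mapped_from_points(pts, labels))), 15)
  perm <- sample(7)
  shuffled <- cut_tree(average_linkage(distance_matrix(
    mapped_from_points(pts[perm, ], labels[perm]))), 15)
  part <- function(cut) {
    groups <- split(names(cut$assignment), cut$assignment)
    sort(vapply(groups[names(groups) != "0"],
                function(g) paste(sort(g), collapse = "|"), character(1)))
  }
  expect_equal(unname(part(base)), unname(part(shuffled)))
  expect_setequal(base$singletons, shuffled$singletons)
})

test_that("consecutive helix residues sit at the generator spacing and cluster first", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  make_helix(12, path = pdb)
  s <- load_structure(pdb)
  v <- data.frame(gene = "TOY", wt = "A", pos = c(3L, 4L, 10L), mut = "G",
                  chrom = NA, genomic_pos = NA, ref = NA, alt = NA, pdb = NA,
                  source_line = 1:3)
  m <- map_variants(v, s)
  dm <- distance_matrix(m)
  expect_equal(dm$d["A3G (A)", "A4G (A)"], helix_ca_spacing(), tolerance = 2e-3)
  tree <- average_linkage(dm)
  expect_setequal(c(tree$merges[[1]]$members_a, tree$merges[[1]]$members_b),
                  c("A3G (A)", "A4G (A)"))
})

test_that("average linkage produces no inversions on random instances", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    pts <- matrix(runif(n * 3, 0, 50), ncol = 3)
    tree <- average_linkage(distance_matrix(mapped_from_points(pts)))
    h <- vapply(tree$merges, `[[`, numeric(1), "height")
    expect_true(all(diff(h) >= -1e-9))
  }
})

test_that("trees serialize to Newick for external dendrogram viewers", {
  skip_if_not_installed("ape")
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0))
  tree <- average_linkage(distance_matrix(
    mapped_from_points(pts, labels = c("a (A)", "b (A)", "c (A)"))))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, c("a_A_", "b_A_", "c_A_"))
})
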