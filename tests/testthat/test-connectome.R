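test_that("read/write round-trips a connectome exactly", {
  sc <- toy_connectome()
  dir <- withr::local_tempdir()
  paths <- write_connectome(sc, dir)
  back <- read_connectome(paths["weights"], paths["lengths"], paths["labels"],
                          subject_id = "toy")
  expect_identical(back$weights, sc$weights)
  expect_identical(back$lengths, sc$lengths)
  expect_identical(back$labels, sc$labels)
  expect_identical(back$roles, sc$roles)
  expect_equal(back$n_regions, 3)

  sc10 <- random_connectome(n = 10, seed = 3)
  paths <- write_connectome(sc10, withr::local_tempdir())
  back10 <- read_connectome(paths["weights"], paths["lengths"], paths["labels"])
  expect_identical(back10$weights, sc10$weights)
  expect_identical(back10$lengths, sc10$lengths)
})

test_that("comma-delimited matrices are sniffed", {
  sc <- toy_connectome()
  dir <- withr::local_tempdir()
  wp <- file.path(dir, "w.csv"); lp <- file.path(dir, "l.csv")
  write.table(sc$weights, wp, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(sc$lengths, lp, sep = ",", row.names = FALSE, col.names = FALSE)
  writeLines(paste(sc$labels, sc$roles, sep = ","), file.path(dir, "lab.csv"))
  back <- read_connectome(wp, lp, file.path(dir, "lab.csv"))
  expect_equal(back$weights, sc$weights, ignore_attr = TRUE)
})

test_that("validation rejects malformed connectomes", {
  sc <- toy_connectome()
  w_neg <- sc$weights; w_neg[1, 2] <- w_neg[2, 1] <- -1
  expect_error(structural_connectome(w_neg, sc$lengths, sc$labels, sc$roles),
               "negative weight")
  expect_error(structural_connectome(sc$weights, sc$lengths,
                                     c("a", "a", "b"), sc$roles),
               "duplicate")
  expect_error(structural_connectome(sc$weights, sc$lengths, sc$labels,
                                     c("cortical", "cortical", "spinal")),
               "unknown role")
  w_asym <- sc$weights; w_asym[1, 2] <- w_asym[1, 2] + 0.5
  expect_error(structural_connectome(w_asym, sc$lengths, sc$labels, sc$roles),
               "asymmetric")
  # asymmetry within tolerance is symmetrized silently
  w_tiny <- sc$weights; w_tiny[1, 2] <- w_tiny[1, 2] + 1e-12
  expect_silent(structural_connectome(w_tiny, sc$lengths, sc$labels, sc$roles))
  blocked <- withr::local_tempfile()
  file.create(blocked)  # a plain file where the output directory should go
  expect_error(write_connectome(sc, blocked), "unwritable")
})

test_that("an empty connectome is rejected", {
  expect_error(structural_connectome(matrix(0, 0, 0), matrix(0, 0, 0),
                                     character(0), character(0)),
               "at least one region")
})

test_that("a 148-region bundle reads back with 148 regions", {
  set.seed(42)
  sc <- generate_connectome(connectome_gen_spec(
    n_cortical = 120, n_driver = 14, n_other = 14, seed = 9))
  expect_equal(sc$n_regions, 148)
  paths <- write_connectome(sc, withr::local_tempdir())
  expect_length(readLines(paths["labels"]), 148)
  back <- read_connectome(paths["weights"], paths["lengths"], paths["labels"])
  expect_equal(back$n_regions, 148)
})

test_that("variant construction follows the parceled/single/removed contracts", {
  sc <- random_connectome(n = 12, n_driver = 3, seed = 5)
  expect_identical(build_variant(sc, "thalamic", "parceled"), sc)
  rem <- build_variant(sc, "thalamic", "removed")
  expect_equal(rem$n_regions, 9)
  expect_false(any(rem$roles == "thalamic"))
  sng <- build_variant(sc, "thalamic", "single")
  expect_equal(sng$n_regions, 10)
  expect_equal(sum(sng$roles == "thalamic"), 1)
  expect_error(build_variant(sc, "cerebellar", "removed"), "no region")
})

test_that("merging two nuclei with weights 3 and 5 gives merged weight 8", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 3
  w[1, 3] <- w[3, 1] <- 5
  l <- matrix(0, 3, 3)
  l[1, 2] <- l[2, 1] <- 10
  l[1, 3] <- l[3, 1] <- 30
  sc <- structural_connectome(w, l, c("cx", "th1", "th2"),
                              c("cortical", "thalamic", "thalamic"))
  sng <- build_variant(sc, "thalamic", "single")
  expect_equal(sng$weights[1, 2], 8)
  # weight-weighted mean length: (3*10 + 5*30) / 8
  expect_equal(sng$lengths[1, 2], (3 * 10 + 5 * 30) / 8)
})

test_that("merging conserves driver-to-region streamline mass (brute force)", {
  for (seed in 1:5) {
    sc <- random_connectome(n = 10, n_driver = 3, seed = seed)
    drv <- which(sc$roles == "thalamic")
    keep <- setdiff(seq_len(sc$n_regions), drv)
    sng <- build_variant(sc, "thalamic", "single")
    merged_idx <- which(sng$roles == "thalamic")
    for (k in seq_along(keep)) {
      mass_before <- sum(sc$weights[drv, keep[k]])
      expect_equal(sng$weights[merged_idx, k], mass_before)
    }
  }
})

test_that("single-then-removed equals removed directly", {
  sc <- random_connectome(n = 11, n_driver = 4, seed = 7)
  a <- build_variant(build_variant(sc, "thalamic", "single"),
                     "thalamic", "removed")
  b <- build_variant(sc, "thalamic", "removed")
  expect_equal(a$weights, b$weights)
  expect_equal(a$lengths, b$lengths)
  expect_identical(a$labels, b$labels)
})

test_that("graph metrics match closed forms on canonical graphs", {
  # complete graph with unit weights: all normalized degrees 1, path lengths 1
  n <- 4
  w <- matrix(1, n, n); diag(w) <- 0
  l <- matrix(10, n, n); diag(l) <- 0
  k4 <- structural_connectome(w, l, letters[1:4], rep("cortical", 4))
  gm <- graph_metrics(k4)
  expect_equal(gm$per_region$degree, rep(1, 4))
  expect_equal(gm$per_region$path_length, rep(1, 4))
  expect_true(gm$connected)

  # 5-leaf star: all 10 leaf pairs route through the center, so the center's
  # normalized betweenness is 10 / ((n-1)(n-2)/2) = 1, the maximum
  ws <- matrix(0, 6, 6); ws[1, 2:6] <- ws[2:6, 1] <- 1
  ls <- ws * 10
  star <- structural_connectome(ws, ls, sprintf("s%d", 1:6),
                                rep("cortical", 6))
  gs <- graph_metrics(star)
  expect_equal(gs$per_region$betweenness[1], choose(5, 2) / (5 * 4 / 2))
  expect_true(all(gs$per_region$betweenness[1] >
                    gs$per_region$betweenness[-1]))
  expect_equal(gs$per_region$betweenness[-1], rep(0, 5))
  # leaf path length: 1 hop to center, 2 to each of 4 leaves
  expect_equal(gs$per_region$path_length[2], (1 + 2 * 4) / 5)
})

test_that("graph metrics are invariant under region permutation", {
  sc <- random_connectome(n = 9, n_driver = 2, seed = 2)
  gm <- graph_metrics(sc)
  set.seed(1)
  perm <- sample(sc$n_regions)
  scp <- structural_connectome(sc$weights[perm, perm], sc$lengths[perm, perm],
                               sc$labels[perm], sc$roles[perm])
  gmp <- graph_metrics(scp)
  m <- match(sc$labels, gmp$per_region$region)
  for (col in c("degree", "strength", "betweenness", "path_length"))
    expect_equal(gmp$per_region[[col]][m], gm$per_region[[col]])
  expect_equal(gmp$global_average, gm$global_average)
})

test_that("disconnected graphs are flagged", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  l <- w * 10
  sc <- structural_connectome(w, l, letters[1:4], rep("cortical", 4))
  expect_warning(gm <- graph_metrics(sc), "disconnected")
  expect_false(gm$connected)
  expect_true(all(is.finite(gm$per_region$path_length)))
})

test_that("synthetic driver hubs have sub-global strength at near-global degree", {
  sc <- generate_connectome(connectome_gen_spec(seed = 4))
  gm <- graph_metrics(sc)
  expect_lt(gm$driver_average["strength"], gm$global_average["strength"])
})
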