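# Module scoring with binned expression-matched controls, donor averages,
# healthy-relative scores and gene-set clustering.

toy_matrix <- function(values, genes, cells = paste0("c", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  values
}

test_that("a constant matrix scores zero everywhere", {
  m <- toy_matrix(matrix(2, nrow = 8, ncol = 5), sprintf("g%d", 1:8))
  sc <- module_score(m, c("g1", "g2"), n_bins = 2, n_ctrl = 10, seed = 1)
  expect_equal(unname(sc), rep(0, 5), tolerance = 1e-12)
})

test_that("one target with a single-gene control pool gives the pair difference", {
  # 4 genes, 2 per bin; target g4 shares its (upper) bin only with g3
  m <- toy_matrix(rbind(c(1, 1), c(2, 2), c(10, 11), c(20, 30)),
                  c("g1", "g2", "g3", "g4"))
  sc <- module_score(m, "g4", n_bins = 2, n_ctrl = 5, seed = 1)
  expect_equal(unname(sc), c(20 - 10, 30 - 11), tolerance = 1e-12)
})

test_that("a block shifted by delta in one group scores ~delta higher there", {
  set.seed(41)
  n_cells <- 400
  healthy <- rep(c(TRUE, FALSE), each = n_cells / 2)
  delta <- 1
  bkg <- matrix(rnorm(180 * n_cells, mean = 2, sd = 0.5), nrow = 180)
  blk <- matrix(rnorm(20 * n_cells, mean = 2, sd = 0.5), nrow = 20)
  blk[, healthy] <- blk[, healthy] + delta
  m <- rbind(blk, bkg)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("c%03d", seq_len(n_cells)))
  sc <- module_score(m, sprintf("g%03d", 1:20), seed = 3)
  gap <- mean(sc[healthy]) - mean(sc[!healthy])
  expect_lt(abs(gap - delta), 0.2)
})

test_that("scores are invariant to adding a per-cell constant", {
  set.seed(2)
  m <- toy_matrix(matrix(rpois(300, 3), nrow = 30), sprintf("g%02d", 1:30))
  sc0 <- module_score(m, c("g01", "g05", "g09"), n_bins = 5, n_ctrl = 4, seed = 9)
  m2 <- sweep(m, 2, seq_len(ncol(m)), "+")
  sc1 <- module_score(m2, c("g01", "g05", "g09"), n_bins = 5, n_ctrl = 4, seed = 9)
  expect_equal(sc1, sc0, tolerance = 1e-10)
})

test_that("random gene sets have expected score zero", {
  co <- tiny_cohort()
  expr <- co$expression$matrix
  bkg <- grep("^BKG", rownames(expr), value = TRUE)
  set.seed(31)
  means <- vapply(1:200, function(i) {
    mean(module_score(expr, sample(bkg, 8), seed = i))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 0.01)
})

test_that("cluster averages equal the brute-force group-by mean", {
  scores <- data.frame(setA = 1:20 / 10)
  meta <- data.frame(cell_id = paste0("c", 1:20),
                     donor_id = rep(c("D1", "D2"), each = 10),
                     cluster_label = rep(c("DP_Tem", "other"), 10))
  avg <- cluster_average_scores(scores, meta, "DP_Tem")
  manual <- tapply(scores$setA[meta$cluster_label == "DP_Tem"],
                   meta$donor_id[meta$cluster_label == "DP_Tem"], mean)
  expect_equal(avg$score[avg$donor_id == "D1"], unname(manual["D1"]))
  expect_equal(avg$score[avg$donor_id == "D2"], unname(manual["D2"]))
})

test_that("donors absent from the cluster are flagged missing", {
  scores <- data.frame(setA = c(1, 2))
  meta <- data.frame(cell_id = c("c1", "c2"), donor_id = c("D1", "D2"),
                     cluster_label = c("DP_Tem", "other"))
  expect_warning(avg <- cluster_average_scores(scores, meta, "DP_Tem"),
                 "no cells")
  expect_true(is.na(avg$score[avg$donor_id == "D2"]))
})

test_that("relative scores have healthy mean exactly zero per set and dataset", {
  avg <- data.frame(
    donor_id = rep(c("H1", "H2", "P1", "P2"), 2),
    set = rep(c("s1", "s2"), each = 4),
    score = c(0.1, 0.3, 0.9, 1.1, -0.2, 0.0, 0.5, 0.7),
    dataset = "A")
  rel <- relative_module_score(avg, healthy_ids = c("H1", "H2"))
  for (s in c("s1", "s2")) {
    h <- rel$relative_score[rel$set == s & rel$donor_id %in% c("H1", "H2")]
    expect_equal(mean(h), 0, tolerance = 1e-12)
  }
  # dataset B has no healthy donors
  expect_error(relative_module_score(
    data.frame(donor_id = "P1", set = "s1", score = 1, dataset = "B"),
    healthy_ids = "H1"), "dataset")
})

test_that("single healthy donor maps to zero", {
  avg <- data.frame(donor_id = c("H1", "P1"), set = "s1", score = c(0.4, 1.0))
  rel <- relative_module_score(avg, "H1")
  expect_equal(rel$relative_score, c(0, 0.6), tolerance = 1e-12)
})

test_that("anti-correlated gene-set blocks separate at k = 2", {
  base <- sin(seq(0, 3 * pi, length.out = 12))
  m <- rbind(matrix(rep(base, 5), nrow = 5, byrow = TRUE),
             matrix(rep(-base, 5), nrow = 5, byrow = TRUE))
  rownames(m) <- paste0("set", 1:10)
  colnames(m) <- paste0("D", 1:12)
  gsc <- cluster_gene_sets(m, k = 2, healthy_ids = paste0("D", 1:6),
                           patient_ids = paste0("D", 7:12))
  expect_identical(length(unique(gsc[1:5])), 1L)
  expect_identical(length(unique(gsc[6:10])), 1L)
  expect_false(gsc[1] == gsc[6])
})

test_that("correlated blocks are recovered and labels order by patient elevation", {
  set.seed(5)
  n_d <- 20
  healthy <- paste0("H", 1:10); patient <- paste0("P", 1:10)
  block_effect <- c(2, 1, 0, -2)  # patient-minus-healthy elevation per block
  rows <- list()
  for (b in 1:4) {
    shared <- rnorm(n_d)
    # zero-mean each half so the block elevation is exactly block_effect
    shared[1:10] <- shared[1:10] - mean(shared[1:10])
    shared[11:20] <- shared[11:20] - mean(shared[11:20])
    for (i in 1:10) {
      v <- shared + rnorm(n_d, sd = 0.3)
      v[11:20] <- v[11:20] + block_effect[b]
      rows[[length(rows) + 1]] <- v
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("set%02d", 1:40)
  colnames(m) <- c(healthy, patient)
  gsc <- cluster_gene_sets(m, k = 4, healthy_ids = healthy, patient_ids = patient)
  truth <- rep(1:4, each = 10)
  expect_gte(mclust::adjustedRandIndex(as.integer(gsc), truth), 0.9)
  # GSC1 must be the most patient-elevated block
  expect_identical(as.character(unique(gsc[1:10])), "GSC1")
})

test_that("k larger than the number of sets errors; k equal gives singletons", {
  m <- matrix(rnorm(12), nrow = 3,
              dimnames = list(paste0("s", 1:3), paste0("D", 1:4)))
  expect_error(cluster_gene_sets(m, k = 5, healthy_ids = "D1", patient_ids = "D2"),
               "exceeds")
  gsc <- cluster_gene_sets(m, k = 3, healthy_ids = c("D1", "D2"),
                           patient_ids = c("D3", "D4"))
  expect_identical(length(unique(gsc)), 3L)
})

test_that("a fully absent gene set is an error naming the set", {
  m <- toy_matrix(matrix(1:12, nrow = 3), c("g1", "g2", "g3"))
  expect_error(module_score(m, c("nope1", "nope2")), "nope1")
})
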