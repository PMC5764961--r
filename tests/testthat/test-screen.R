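test_that("gene variation stats use the sample (n-1) SD", {
  tpm <- tpm_matrix(matrix(c(50, 50, 50, 40, 60, 50), nrow = 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
  st <- gene_variation_stats(tpm)
  expect_equal(nrow(st), 2)
  expect_equal(st$mean_tpm, c(50, 50))
  expect_equal(st$sd_tpm[1], 0)
  st2 <- gene_variation_stats(tpm_matrix(matrix(c(40, 60), 1,
    dimnames = list("a", c("s1", "s2")))))
  expect_equal(st2$sd_tpm, sqrt(200), tolerance = 1e-12)  # 14.142
  expect_error(gene_variation_stats(tpm_matrix(matrix(1, 2, 1,
    dimnames = list(c("a", "b"), "s1")))), class = "refstab_insufficient_data")
})

test_that("rank_candidates applies the strict mean floor and SD ordering", {
  st <- data.frame(gene = c("X", "Y", "Z"), mean_tpm = c(60, 40, 100),
                   sd_tpm = c(5, 1, 20), n_samples = 3)
  rk <- rank_candidates(st, 50)
  expect_equal(rk$gene, c("X", "Z"))
  expect_equal(rk$rank, 1:2)
  expect_false("Y" %in% rk$gene)

  # exactly at the floor is excluded (strict >)
  st_edge <- data.frame(gene = "E", mean_tpm = 50, sd_tpm = 1, n_samples = 3)
  expect_equal(nrow(suppressMessages(rank_candidates(st_edge, 50))), 0)

  # ties: by mean then id
  st_tie <- data.frame(gene = c("b", "a", "c"), mean_tpm = c(70, 70, 60),
                       sd_tpm = c(2, 2, 2), n_samples = 3)
  expect_equal(rank_candidates(st_tie, 50)$gene, c("c", "a", "b"))
})

test_that("rank_candidates matches a brute-force sort on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- sample(5:20, 1)
    m <- matrix(runif(g * 14, 0, 200), g, 14,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:14)))
    rk <- rank_candidates(tpm_matrix(m), 50)
    # brute force: filter then selection-sort by (sd, mean, gene)
    keep <- rownames(m)[rowMeans(m) > 50]
    keys <- lapply(keep, function(gn) c(naive_sd(m[gn, ]), mean(m[gn, ])))
    ord <- keep[order(sapply(keys, `[`, 1), sapply(keys, `[`, 2), keep)]
    expect_equal(rk$gene, ord)
    expect_equal(rk$sd_tpm, sort(rk$sd_tpm))
    expect_equal(rk$rank, seq_len(nrow(rk)))
  }
})

test_that("scaling one gene's TPM by c > 0 scales its SD by c", {
  set.seed(42)
  m <- matrix(runif(5 * 8, 60, 120), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  s1 <- gene_variation_stats(tpm_matrix(m))
  m2 <- m; m2["g3", ] <- m2["g3", ] * 3.7
  s2 <- gene_variation_stats(tpm_matrix(m2))
  expect_equal(s2$sd_tpm[3], 3.7 * s1$sd_tpm[3], tolerance = 1e-12)
  expect_equal(s2$sd_tpm[-3], s1$sd_tpm[-3])
})

test_that("dual ranking exposes genes shifted only in the excluded stage", {
  set.seed(1)
  base <- matrix(runif(6 * 5, 80, 120), 6, 5,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  base["g1", ] <- 100 + c(0.1, -0.1, 0.05, -0.05, 0)  # very stable...
  base["g1", "s1"] <- 600                              # ...except in s1
  dr <- dual_ranking(tpm_matrix(base), "s1")
  rank_with <- dr$with_all$rank[dr$with_all$gene == "g1"]
  rank_without <- dr$without_excluded$rank[dr$without_excluded$gene == "g1"]
  expect_lt(rank_without, rank_with)
  expect_equal(rank_without, 1)

  # empty exclusion -> identical rankings
  dr0 <- dual_ranking(tpm_matrix(base), character())
  expect_equal(dr0$with_all, dr0$without_excluded)

  expect_error(dual_ranking(tpm_matrix(base), "nope"),
               class = "refstab_config_error")
})

test_that("overlap_top intersects the top-n of both rankings", {
  mk <- function(genes) structure(
    data.frame(gene = genes, mean_tpm = 100, sd_tpm = seq_along(genes),
               rank = seq_along(genes), stringsAsFactors = FALSE),
    class = c("candidate_ranking", "data.frame"))
  ov <- overlap_top(mk(c("a", "b", "c")), mk(c("b", "c", "d")), 3)
  expect_setequal(ov$gene, c("b", "c"))
  expect_equal(ov$rank_a, c(2, 3))
  expect_equal(ov$rank_b, c(1, 2))
  expect_equal(nrow(overlap_top(mk(letters[1:5]), mk(letters[1:5]), 5)), 5)
  expect_equal(nrow(overlap_top(mk(c("a", "b")), mk(c("c", "d")), 2)), 0)
  expect_message(ov2 <- overlap_top(mk(c("a", "b")), mk(c("a", "b")), 10),
                 "truncated")
  expect_equal(nrow(ov2), 2)
})

test_that("select_homeolog keeps the better-ranked .L/.S copy", {
  rk <- structure(data.frame(
    gene = c("clta.L", "sub1.L", "clta.S", "ralb.S"),
    mean_tpm = 100, sd_tpm = 1:4, rank = 1:4, stringsAsFactors = FALSE),
    class = c("candidate_ranking", "data.frame"))
  out <- select_homeolog(rk)
  expect_equal(out$gene, c("clta.L", "sub1.L", "ralb.S"))
  expect_equal(out$rank, 1:3)  # renumbered without gaps
  # unsuffixed genes pass through untouched
  rk2 <- structure(data.frame(gene = c("odc1", "clta.S"), mean_tpm = 100,
                              sd_tpm = 1:2, rank = 1:2, stringsAsFactors = FALSE),
                   class = c("candidate_ranking", "data.frame"))
  expect_equal(select_homeolog(rk2)$gene, c("odc1", "clta.S"))
})

test_that("screening recovers the designed ranking from simulated TPM", {
  sds <- seq(2, 40, length.out = 30)
  sim <- simulate_tpm_matrix(n_genes = 30, n_samples = 14,
                             mean_range = c(150, 400), sd_profile = sds,
                             seed = 11)
  rk <- rank_candidates(sim$tpm, 50)
  expect_equal(rk$gene, sim$truth$ranking_with_all)
  expect_equal(rk$gene, rownames(sim$tpm))  # increasing profile = gene order
  # genes designed below the floor never appear
  sim2 <- simulate_tpm_matrix(n_genes = 40, n_samples = 14,
                              mean_range = c(10, 200), seed = 3)
  rk2 <- rank_candidates(sim2$tpm, 50)
  expect_true(all(sim2$truth$mean[rk2$gene] > 50))
})
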