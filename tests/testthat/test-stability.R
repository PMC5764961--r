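abc_ct <- matrix(c(20, 21, 22, 25, 26, 27, 30, 30, 31), 3, 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
abc_q <- matrix(c(1, .5, .25, 1, .5, .25, 1, 1, .5), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))

test_that("delta-Ct stability reproduces the hand-worked A/B/C values", {
  r <- delta_ct_stability(abc_ct)
  v <- setNames(r$value, r$gene)
  expect_equal(unname(v[c("A", "B", "C")]),
               c(0.5 / sqrt(3), 0.5 / sqrt(3), 1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(v[["C"]], 0.5773503, tolerance = 1e-6)
  expect_equal(r$gene[r$rank == 3], "C")
})

test_that("delta-Ct is blind to per-sample and per-gene shifts", {
  set.seed(10)
  m <- random_ct_matrix(5, 8, 10)
  r0 <- delta_ct_stability(m)
  m_s <- sweep(m, 2, rnorm(8, 0, 2), `+`)   # per-sample shift
  m_g <- sweep(m_s, 1, rnorm(5, 0, 3), `+`) # per-gene shift
  r1 <- delta_ct_stability(m_g)
  expect_equal(r1$value, r0$value, tolerance = 1e-9)
  expect_equal(r1$rank, r0$rank)
})

test_that("geNorm reproduces the hand-worked A/B/C trace", {
  gn <- genorm(abc_q)
  first_pass <- gn$trace$iterations[[1]]
  expect_equal(unname(first_pass[c("A", "B", "C")]),
               c(0.2886751, 0.2886751, 0.5773503), tolerance = 1e-6)
  expect_equal(gn$trace$exclusion_order, "C")
  expect_equal(gn$trace$final_pair, c("A", "B"))
  expect_equal(gn$result$value[gn$result$gene %in% c("A", "B")], c(0, 0))
  expect_equal(gn$result$value[gn$result$gene == "C"], 0.5773503,
               tolerance = 1e-6)
})

test_that("exact scalar multiples of one profile all get M = 0", {
  prof <- c(1, 0.4, 0.2, 0.9)
  q <- rbind(a = prof, b = 2 * prof, c = 0.5 * prof)
  colnames(q) <- paste0("s", 1:4)
  gn <- genorm(q)
  expect_equal(gn$result$value, rep(0, 3))
})

test_that("geNorm is invariant to rescaling one gene's quantities", {
  set.seed(11)
  q <- matrix(2^-runif(40, 0, 5), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  gn1 <- genorm(q)
  q2 <- q; q2["g2", ] <- q2["g2", ] * 37.5
  gn2 <- genorm(q2)
  expect_equal(gn2$result$value, gn1$result$value, tolerance = 1e-9)
  expect_equal(gn2$result$gene, gn1$result$gene)
})

test_that("delta-Ct ordering equals first-pass geNorm M ordering (base 2)", {
  for (seed in 1:10) {
    m <- random_ct_matrix(5, 8, 100 + seed)
    q <- relative_quantities(m)
    dct <- delta_ct_stability(m)
    mvals <- genorm_m_first_pass <- oracle_genorm_m(q)
    # pairwise log2-ratio SD equals the delta-Ct SD exactly, so the mean
    # values coincide, not just the order
    expect_equal(setNames(dct$value, dct$gene)[names(mvals)], mvals,
                 tolerance = 1e-9)
  }
})

test_that("geNorm V series and recommended n behave as designed", {
  # top-3 exactly proportional -> V_2/3 = 0, two genes recommended
  prof <- 2^-c(0, 1, 2, 0.5, 1.5)
  q <- rbind(a = prof, b = prof * 0.5, c = prof * 0.25,
             d = 2^-c(0, 2, 1, 2.5, 0.2))
  colnames(q) <- paste0("s", 1:5)
  gn <- genorm(q)
  gv <- genorm_v(q, gn)
  expect_equal(gv$v$v[gv$v$n == 2], 0, tolerance = 1e-12)
  expect_equal(gv$recommended_n, 2)
  expect_true(gv$threshold_met)

  gv0 <- genorm_v(q, gn, threshold = 0)
  expect_false(gv0$threshold_met)
  expect_equal(gv0$recommended_n, nrow(q))

  # V values match the naive normalisation-factor oracle
  set.seed(12)
  q2 <- matrix(2^-runif(48, 0, 4), 6, 8,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  gn2 <- genorm(q2)
  gv2 <- genorm_v(q2, gn2)
  ranked <- gn2$result$gene[order(gn2$result$rank)]
  expect_equal(gv2$v$v, oracle_genorm_v(q2, ranked), tolerance = 1e-9)

  expect_error(genorm_v(abc_q, genorm(abc_q)), class = "refstab_insufficient_data")
})

test_that("BestKeeper reproduces hand-worked descriptives and flags", {
  m <- rbind(a = c(20, 21, 22), b = c(25, 26, 24), c = c(30, 33, 27))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(m)
  ga <- bk$gene_stats[bk$gene_stats$gene == "a", ]
  expect_equal(ga$arith_mean, 21)
  expect_equal(ga$sd, 2 / 3, tolerance = 1e-9)          # MAD (1+0+1)/3
  expect_equal(ga$cv_pct, 2 / 3 / 21 * 100, tolerance = 1e-9)
  expect_true(ga$min <= ga$geo_mean && ga$geo_mean <= ga$max)
  expect_false(ga$inconsistent)
  expect_true(bk$gene_stats$inconsistent[bk$gene_stats$gene == "c"])  # MAD 2 > 1
})

test_that("identical profiles correlate perfectly with the BestKeeper index", {
  m <- rbind(a = c(20, 22, 21, 23), b = c(20, 22, 21, 23))
  colnames(m) <- paste0("s", 1:4)
  bk <- bestkeeper(m)
  expect_equal(unname(bk$gene_stats$r_index), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(bk$index), unname(m["a", ]), tolerance = 1e-12)
})

test_that("BestKeeper MAD ignores per-gene shifts but CV% does not", {
  m <- random_ct_matrix(4, 6, 13)
  bk1 <- bestkeeper(m)
  m2 <- m; m2["g2", ] <- m2["g2", ] + 5
  bk2 <- bestkeeper(m2)
  expect_equal(bk2$gene_stats$sd, bk1$gene_stats$sd, tolerance = 1e-9)
  expect_lt(bk2$gene_stats$cv_pct[2], bk1$gene_stats$cv_pct[2])
})

test_that("NormFinder recovers designed single-group noise SDs", {
  # panel-sized matrix: with k genes the decontamination noise scales as
  # 1/(1 - 2/k), so sigma recovery is assessed at the 16-gene design size
  set.seed(14)
  design <- ct_sim_design()
  sigma <- design$sigma
  n <- 200
  y <- t(vapply(design$genes,
                function(g) rnorm(n, design$baseline_ct[g], sigma[g]),
                numeric(n)))
  colnames(y) <- paste0("s", 1:n)
  nf <- normfinder(y)
  est <- setNames(nf$result$value, nf$result$gene)[design$genes]
  # genes whose variance sits above the decontamination noise floor
  # (sum(sigma^2)/k^2, here ~0.1 cycles) are estimable to 20%; the two
  # quietest genes are only required to land below that floor
  estimable <- sigma >= 0.25
  expect_true(all(abs(est[estimable] - sigma[estimable]) /
                    sigma[estimable] < 0.2))
  expect_true(all(est[!estimable] < 0.15))
  # designed stable pair on top; overall order near-perfect (adjacent
  # sigmas differ by ~0.06 cycles and may swap at n = 200)
  ranked <- nf$result$gene[order(nf$result$rank)]
  expect_setequal(ranked[1:2], design$genes[order(sigma)][1:2])
  expect_gt(cor(nf$result$rank[match(design$genes, nf$result$gene)],
                rank(sigma), method = "spearman"), 0.95)
})

test_that("a gene with an intergroup offset gets the largest |d| and worst rho", {
  set.seed(15)
  n_per <- 20
  groups <- rep(c("ctrl", "treat"), each = n_per)
  y <- matrix(rnorm(4 * 2 * n_per, 0, 0.2), 4, 2 * n_per,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:(2 * n_per))))
  y <- sweep(y, 1, c(20, 22, 24, 26), `+`)
  y["g3", groups == "treat"] <- y["g3", groups == "treat"] + 1
  nf <- normfinder(y, groups)
  expect_equal(rownames(nf$intergroup_d)[which.max(abs(nf$intergroup_d[, "treat"]))],
               "g3")
  expect_equal(nf$result$gene[nf$result$rank == 4], "g3")
  # within each group the intergroup differences sum to ~0
  expect_equal(unname(colSums(nf$intergroup_d)), c(0, 0), tolerance = 1e-9)
})

test_that("NormFinder is invariant to per-sample constants and guards k >= 3", {
  y <- random_ct_matrix(5, 12, 16)
  nf1 <- normfinder(y)
  y2 <- sweep(y, 2, rnorm(12, 0, 3), `+`)
  nf2 <- normfinder(y2)
  expect_equal(nf2$result$value, nf1$result$value, tolerance = 1e-9)
  expect_error(normfinder(y[1:2, ]), "1 - 2/k",
               class = "refstab_insufficient_data")
  expect_error(normfinder(y, groups = c(rep("a", 11), "b")),
               class = "refstab_insufficient_data")
})

test_that("all four statistics match their naive oracles on random matrices", {
  for (seed in 1:12) {
    set.seed(seed)
    g <- sample(3:6, 1); n <- sample(4:10, 1)
    m <- random_ct_matrix(g, n, seed * 7)
    q <- relative_quantities(m)

    dct <- delta_ct_stability(m)
    expect_equal(setNames(dct$value, dct$gene)[rownames(m)],
                 oracle_delta_ct(m), tolerance = 1e-9)

    gn <- genorm(q)
    og <- oracle_genorm_full(q)
    expect_equal(gn$trace$exclusion_order, og$exclusion_order)
    expect_equal(gn$trace$m_at_exclusion, unname(og$m_at_exclusion),
                 tolerance = 1e-9)
    expect_equal(gn$trace$final_pair, og$final_pair)

    bk <- bestkeeper(m)
    ob <- oracle_bestkeeper(m)
    expect_equal(bk$gene_stats$sd, ob$mad, tolerance = 1e-9)
    expect_equal(bk$gene_stats$cv_pct, ob$cv, tolerance = 1e-9)
    expect_equal(unname(bk$gene_stats$r_index), ob$r, tolerance = 1e-9)

    nf <- normfinder(log2(q))
    expect_equal(setNames(nf$result$value, nf$result$gene)[rownames(m)],
                 oracle_normfinder(log2(q)), tolerance = 1e-9)

    grp <- rep(c("a", "b"), length.out = n)
    if (min(table(grp)) >= 2) {
      nfg <- normfinder(log2(q), grp)
      expect_equal(setNames(nfg$result$value, nfg$result$gene)[rownames(m)],
                   oracle_normfinder(log2(q), grp), tolerance = 1e-9)
    }
  }
})

test_that("gene and sample permutations never change values or ranks", {
  set.seed(17)
  for (i in 1:5) {
    m <- random_ct_matrix(6, 8, 300 + i)
    q <- relative_quantities(m)
    pg <- sample(nrow(m)); ps <- sample(ncol(m))
    mp <- m[pg, ps]; qp <- relative_quantities(mp)

    for (pair in list(
      list(delta_ct_stability(m), delta_ct_stability(mp)),
      list(genorm(q)$result, genorm(qp)$result),
      list(bestkeeper(m)$result, bestkeeper(mp)$result),
      list(normfinder(log2(q))$result, normfinder(log2(qp))$result))) {
      a <- pair[[1]]; b <- pair[[2]]
      expect_equal(setNames(b$value, b$gene)[a$gene], setNames(a$value, a$gene),
                   tolerance = 1e-9)
      expect_equal(setNames(b$rank, b$gene)[a$gene], setNames(a$rank, a$gene))
    }
  }
})

test_that("consensus ranking is the geometric mean of method ranks", {
  mk <- function(genes, ranks, method) structure(
    data.frame(gene = genes, value = ranks / 10, rank = ranks,
               stringsAsFactors = FALSE),
    method = method, class = c("stability_result", "data.frame"))
  res <- list(mk(c("x", "y"), c(1, 2), "m1"), mk(c("x", "y"), c(1, 2), "m2"),
              mk(c("x", "y"), c(1, 2), "m3"), mk(c("x", "y"), c(2, 1), "m4"))
  cons <- consensus_rank(res)
  expect_equal(cons$geomean_rank[cons$gene == "x"], 2^(1 / 4), tolerance = 1e-6)
  expect_equal(cons$geomean_rank[cons$gene == "y"], 8^(1 / 4), tolerance = 1e-6)
  expect_equal(cons$gene[cons$rank == 1], "x")  # 1.19 < 1.68

  one <- consensus_rank(res[1])
  expect_equal(one$rank, res[[1]]$rank[match(one$gene, res[[1]]$gene)])

  agree <- consensus_rank(res[1:3])
  expect_equal(setNames(agree$rank, agree$gene),
               setNames(res[[1]]$rank, res[[1]]$gene)[agree$gene])

  bad <- mk(c("x", "z"), c(1, 2), "m5")
  expect_error(consensus_rank(list(res[[1]], bad)),
               class = "refstab_integrity_error")
})

test_that("small-matrix guards are enforced", {
  m2 <- random_ct_matrix(2, 5, 1)
  expect_error(delta_ct_stability(m2), class = "refstab_insufficient_data")
  expect_error(genorm(relative_quantities(m2)), class = "refstab_insufficient_data")
  qneg <- matrix(c(1, -1, 1, 1, 1, 1, 1, 1, 1), 3, 3,
                 dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_error(genorm(qneg), class = "refstab_domain_error")
})
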