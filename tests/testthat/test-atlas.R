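test_that("replicate averaging is the per-tissue arithmetic mean", {
  m <- matrix(c(4, 6, 10, 20), 1)
  rownames(m) <- "g1"
  colnames(m) <- c("tA_r1", "tA_r2", "tB_r1", "tB_r2")
  atlas <- expression_atlas(m, data.frame(sample_id = colnames(m),
                                          tissue = c("tA", "tA", "tB", "tB")))
  prof <- average_replicates(atlas)
  expect_equal(unname(prof$means["g1", ]), c(5, 15))

  # single replicate passes through unchanged
  m1 <- matrix(c(3, 7), 1, dimnames = list("g1", c("s1", "s2")))
  a1 <- expression_atlas(m1, data.frame(sample_id = c("s1", "s2"),
                                        tissue = c("tA", "tB")))
  expect_equal(unname(average_replicates(a1)$means["g1", ]), c(3, 7))

  # random matrix equals an element-wise loop oracle
  set.seed(42)
  mm <- matrix(rexp(20 * 20), 20)
  rownames(mm) <- sprintf("g%02d", 1:20)
  colnames(mm) <- sprintf("s%02d", 1:20)
  des <- data.frame(sample_id = colnames(mm),
                    tissue = rep(sprintf("t%02d", 1:10), each = 2))
  prof <- average_replicates(expression_atlas(mm, des))
  for (g in 1:20) for (t in unique(des$tissue)) {
    cols <- des$sample_id[des$tissue == t]
    acc <- 0
    for (s in cols) acc <- acc + mm[g, s]
    expect_equal(prof$means[g, t], acc / length(cols))
  }
})

test_that("gene filter removes grand mean <= threshold inclusively and ncRNAs", {
  m <- rbind(rep(0.5, 10), rep(1.0, 10), rep(1.01, 10), rep(50, 10))
  rownames(m) <- c("low", "atone", "justover", "nc1")
  prof <- make_profile(m)
  out <- filter_genes(prof, ncRNA_ids = "nc1")
  expect_identical(rownames(out$means), "justover")
  expect_equal(unname(attr(out, "removed")),  c(2L, 1L))
  expect_error(filter_genes(make_profile(rbind(rep(0.2, 5)))),
               "no genes retained")
})

test_that("tau matches the index formula on canonical profiles", {
  expect_equal(compute_tau(make_profile(rbind(rep(8, 10))))$tau, 0)
  expect_equal(compute_tau(make_profile(rbind(c(rep(0, 9), 7))))$tau, 1)
  expect_equal(compute_tau(make_profile(rbind(c(10, 5, rep(0, 8)))))$tau,
               8.5 / 9)
  expect_error(compute_tau(make_profile(rbind(rep(0, 10), rep(1, 10)))),
               "all-zero")
})

test_that("tau is bounded, monotone in the max tissue, and oracle-equivalent", {
  set.seed(7)
  m <- matrix(rexp(200 * 10, rate = 0.1), 200)
  tau <- compute_tau(make_profile(m))$tau
  expect_true(all(tau >= 0 & tau <= 1))
  for (i in seq_len(nrow(m)))
    expect_equal(tau[i], tau_oracle(m[i, ]), tolerance = 1e-14)
  # raising the maximal tissue never decreases tau
  i <- which.max(m[1, ])
  for (boost in c(1.5, 3, 10)) {
    m2 <- m[1, , drop = FALSE]
    m2[1, i] <- m2[1, i] * boost
    expect_gte(compute_tau(make_profile(m2))$tau + 1e-12, tau[1])
  }
})

test_that("classification follows the category rules and precedence", {
  p1 <- make_profile(rbind(c(50, 2, 1, 1, 1, 1, 1, 1, 1, 1)))
  t1 <- classify_genes(p1, compute_tau(p1))
  expect_equal(as.character(t1$category), "TissueSpecific")
  expect_equal(t1$group, "t01")
  expect_equal(t1$tau, (1 - 2 / 50 + 8 * (1 - 1 / 50)) / 9)
  expect_gt(t1$tau, 0.85)

  p2 <- make_profile(rbind(c(40, 35, 2, 2, 1, 1, 1, 1, 1, 1)))
  t2 <- classify_genes(p2, compute_tau(p2))
  expect_equal(as.character(t2$category), "GroupEnriched")
  expect_equal(t2$group, "t01;t02")
  expect_equal(t2$tau, (0.125 + 2 * 0.95 + 6 * 0.975) / 9)

  # detected everywhere with low tau -> ExpressedInAll
  p3 <- make_profile(rbind(c(5, 5, 5, 5, 5, 5, 5, 5, 5, 6)))
  t3 <- classify_genes(p3, compute_tau(p3))
  expect_equal(as.character(t3$category), "ExpressedInAll")

  # enriched but under 5-fold and below detection somewhere -> Mixed
  p4 <- make_profile(rbind(c(3, 3, 3, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8)))
  t4 <- classify_genes(p4, compute_tau(p4))
  expect_equal(as.character(t4$category), "Mixed")
})

test_that("group-enriched search returns the smallest qualifying group", {
  # top-3 qualifies but so does top-2? min(top2)=30 >= 5*20 fails,
  # k=3: min(top3)=25 >= 5*1 holds -> group of 3
  p <- make_profile(rbind(c(40, 30, 25, 1, 1, 1, 1, 1, 1, 1)))
  tt <- classify_genes(p, compute_tau(p))
  expect_equal(as.character(tt$category), "GroupEnriched")
  expect_equal(tt$group, "t01;t02;t03")
})

test_that("tissue correlation is symmetric with unit diagonal on log2 scale", {
  set.seed(1)
  m <- matrix(rexp(50 * 4), 50)
  cc <- tissue_correlation(make_profile(m))
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_true(all(cc >= -1 & cc <= 1))
  # identical columns correlate at 1
  m2 <- cbind(m[, 1], m[, 1], m[, 2], m[, 3])
  cc2 <- tissue_correlation(make_profile(m2))
  expect_equal(cc2[1, 2], 1)
  # anti-proportional columns in log space -> -1
  lg <- seq(0.5, 3, length.out = 50)
  m3 <- cbind(2^lg - 1, 2^(3.5 - lg) - 1, m[, 1], m[, 2])
  expect_equal(tissue_correlation(make_profile(m3))[1, 2], -1)
  # brute-force pairwise oracle
  lgm <- log2(m + 1)
  for (a in 1:3) for (b in (a + 1):4) {
    num <- sum((lgm[, a] - mean(lgm[, a])) * (lgm[, b] - mean(lgm[, b])))
    den <- sqrt(sum((lgm[, a] - mean(lgm[, a]))^2) *
                sum((lgm[, b] - mean(lgm[, b]))^2))
    expect_equal(cc[a, b], num / den, tolerance = 1e-12)
  }
  # constant column is flagged
  m4 <- cbind(rep(3, 50), m[, 1:3])
  expect_warning(cc4 <- tissue_correlation(make_profile(m4)), "constant")
  expect_true(is.na(cc4[1, 2]))
})

test_that("fold-change/tau correlation is a tie-corrected rank correlation", {
  tau <- data.frame(gene_id = sprintf("g%02d", 1:12),
                    tau = seq(0.1, 0.95, length.out = 12),
                    fold_over_rest = 2^seq(0.2, 4, length.out = 12))
  expect_equal(foldchange_tau_correlation(tau)$rho, 1)
  tau$fold_over_rest <- rev(tau$fold_over_rest)
  expect_equal(foldchange_tau_correlation(tau)$rho, -1)
  tau$fold_over_rest <- rep(2, 12)
  expect_error(foldchange_tau_correlation(tau), "tied")
})

test_that("categories partition the retained gene set", {
  sim <- simulate_atlas(sim_config(n_genes = 800, seed = 3))
  prof <- filter_genes(average_replicates(sim$atlas))
  tau <- classify_genes(prof, compute_tau(prof))
  expect_false(anyNA(tau$category))
  expect_equal(sum(table(tau$category)), nrow(prof$means))
  # group field populated exactly for TissueSpecific and GroupEnriched
  expect_true(all(nzchar(tau$group[tau$category %in%
                                     c("TissueSpecific", "GroupEnriched")])))
  expect_true(all(tau$group[tau$category %in%
                              c("ExpressedInAll", "Mixed")] == ""))
  # TissueSpecific genes satisfy their defining thresholds
  ts <- tau[tau$category == "TissueSpecific", ]
  expect_true(all(ts$tau > 0.85))
  expect_true(all(ts$fold_over_rest >= 5))
})
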