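# Panel filtering, call-rate QC, PRS arithmetic and genotype PCs.

test_that("panel filter removes near-null and failed SNPs with strict bounds", {
  cfg <- simulation_config(n_snps = 123, seed = 21)
  panel <- generate_snp_panel(cfg, n_near_null = 28, n_failed = 3)
  kept <- filter_snp_panel(panel)
  expect_equal(nrow(kept), 92)
  expect_equal(nrow(attr(kept, "removed")), 31)

  # boundary ORs survive: the near-null zone is the open interval
  edge <- make_panel(c(0.95, 1.05, 1.0))
  kept_edge <- filter_snp_panel(edge)
  expect_equal(kept_edge$rsid, c("rs0001", "rs0002"))

  ok <- make_panel(c(1.2, 0.8))
  expect_equal(filter_snp_panel(ok)$rsid, ok$rsid)
  expect_error(filter_snp_panel(make_panel(1.0)), "no SNPs retained")
})

test_that("filter counts are total minus injected for disjoint compositions", {
  for (comp in list(c(10, 0, 0), c(10, 3, 0), c(10, 2, 4), c(50, 12, 5))) {
    n <- sum(comp)
    cfg <- simulation_config(n_snps = n, seed = n)
    panel <- generate_snp_panel(cfg, n_near_null = comp[2], n_failed = comp[3])
    expect_equal(nrow(filter_snp_panel(panel)), comp[1])
  }
})

test_that("sample call-rate QC applies the 0.95 rule exactly", {
  rsids <- sprintf("rs%04d", 1:92)
  gt <- make_genotypes(4, rsids, seed = 2)
  gt["S001", 1:5] <- NA   # 87/92 = 0.9457 -> dropped
  gt["S002", 1:4] <- NA   # 88/92 = 0.9565 -> kept
  out <- qc_samples(gt)
  expect_identical(rownames(out), c("S002", "S003", "S004"))
  expect_equal(attr(out, "dropped_samples")$sample_id, "S001")

  strip <- function(m) {
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    m
  }
  full <- make_genotypes(5, rsids[1:10], seed = 3)
  out_full <- qc_samples(full)
  expect_equal(strip(out_full), strip(full))
  expect_equal(nrow(attr(out_full, "dropped_samples")), 0)
  # idempotence
  expect_equal(strip(qc_samples(out)), strip(out))
  allna <- matrix(NA_real_, 2, 10,
                  dimnames = list(c("a", "b"), rsids[1:10]))
  expect_error(qc_samples(allna), "all samples")
})

test_that("SNP QC drops low call rates and duplicate-error flags", {
  rsids <- sprintf("rs%04d", 1:4)
  gt <- make_genotypes(50, rsids, seed = 4)
  gt[1:3, "rs0001"] <- NA  # 94% < 0.95 -> dropped
  gt[1:2, "rs0002"] <- NA  # 96% -> kept
  panel <- make_panel(rep(1.3, 4), status = c("ok", "ok", "duplicate_error", "ok"))
  out <- qc_snps(gt, panel = panel)
  expect_identical(colnames(out), c("rs0002", "rs0004"))
  dropped <- attr(out, "dropped_snps")
  expect_setequal(dropped$rsid, c("rs0001", "rs0003"))
  expect_equal(dropped$reason[dropped$rsid == "rs0003"], "duplicate_error")
  # idempotence on retained matrix
  strip <- function(m) {
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    m
  }
  expect_equal(strip(qc_snps(out, panel = panel)), strip(out))
})

test_that("PRS equals the naive double-loop accumulation and is additive", {
  panel <- make_panel(c(2, 0.5, 1.3, 1.1, 0.7, 1.6, 0.9, 1.2),
                      eaf = seq(0.1, 0.45, length.out = 8))
  gt <- make_genotypes(10, panel$rsid, seed = 5)
  raw <- compute_prs(gt, panel)
  oracle <- numeric(10)
  for (i in 1:10) {
    for (k in 1:8) oracle[i] <- oracle[i] + log(panel$or_value[k]) * gt[i, k]
  }
  expect_equal(unname(raw), oracle, tolerance = 1e-12)

  # disjoint sub-panels sum to the full score
  a <- snp_panel(as.data.frame(panel[1:3, setdiff(names(panel), "weight")]))
  b <- snp_panel(as.data.frame(panel[4:8, setdiff(names(panel), "weight")]))
  expect_equal(compute_prs(gt, a) + compute_prs(gt, b), raw, tolerance = 1e-12)
})

test_that("PRS handles zero genotypes, single-SNP arithmetic and missingness", {
  panel <- make_panel(2, eaf = 0.25)
  gt <- matrix(c(0, 2, NA), ncol = 1, dimnames = list(c("a", "b", "c"), "rs0001"))
  raw <- compute_prs(gt, panel)
  expect_equal(unname(raw["a"]), 0)
  expect_equal(unname(raw["b"]), 2 * log(2))
  expect_equal(unname(raw["c"]), 2 * 0.25 * log(2))  # expected-dosage imputation
  expect_equal(unname(compute_prs(gt, panel, missing_policy = "zero")["c"]), 0)
  expect_error(compute_prs(gt, panel, missing_policy = "fail"), "missing")
  expect_equal(unname(compute_prs(gt, panel, weights = "or")["b"]), 4)

  other <- make_panel(c(1.5, 2))
  expect_error(compute_prs(gt, other), "rs0002")
})

test_that("normalization divides by the control median and standardization is unit scale", {
  raw <- c(a = 1, b = 2, c = 3, d = 5)
  res <- normalize_prs(raw, control_ids = c("a", "b", "c"))
  expect_equal(res$normalized[1:3], c(0.5, 1.0, 1.5))
  ctrl_std <- res$standardized[1:3]
  expect_equal(mean(ctrl_std), 0, tolerance = 1e-9)
  expect_equal(stats::sd(ctrl_std), 1, tolerance = 1e-9)
  # positive scaling preserves rank order on both scales
  expect_identical(order(res$raw), order(res$normalized))
  expect_identical(order(res$raw), order(res$standardized))

  expect_error(normalize_prs(c(a = -1, b = 0, c = 1), c("a", "b", "c")),
               "standardized")
})

test_that("genotype PCs are orthogonal, sign-stable and separate subpopulations", {
  gt <- make_genotypes(60, sprintf("rs%04d", 1:30), seed = 6)
  pcs <- genotype_pcs(gt, k = 5)
  g <- crossprod(pcs)
  expect_true(all(abs(g[upper.tri(g)]) < 1e-8))

  # two subpopulations with divergent MAFs separate on PC1
  set.seed(7)
  n <- 100; m <- 80
  p1 <- runif(m, 0.05, 0.3); p2 <- pmin(p1 + 0.35, 0.95)
  ga <- matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m)
  gb <- matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m)
  gt2 <- rbind(ga, gb)
  dimnames(gt2) <- list(sprintf("P%03d", 1:n), sprintf("rs%04d", 1:m))
  pc2 <- genotype_pcs(gt2, k = 2)
  grp <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(stats::cor(pc2[, 1], grp)), 0.9)

  # duplicating every sample duplicates its coordinates
  dup <- gt[rep(1:60, each = 2), ]
  rownames(dup) <- sprintf("D%03d", 1:120)
  pcd <- genotype_pcs(dup, k = 3)
  expect_equal(pcd[seq(1, 120, 2), ], pcd[seq(2, 120, 2), ],
               ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(genotype_pcs(gt[1:4, 1:3], k = 5), "rank")
})
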