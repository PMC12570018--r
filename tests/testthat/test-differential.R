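test_that("ks_compare handles identical, disjoint and small samples", {
  r <- ks_compare(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r$d, 0)
  expect_equal(r$p, 1)

  r2 <- ks_compare(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
  expect_equal(r2$d, 1)

  expect_error(ks_compare(1, c(1, 2)), "at least 2")
})

test_that("ks_compare d equals the pooled-ECDF oracle and is symmetric", {
  set.seed(909)
  for (i in 1:50) {
    xs <- runif(sample(2:20, 1))
    ys <- runif(sample(2:20, 1))
    a <- ks_compare(xs, ys)
    expect_equal(a$d, ks_d_oracle(xs, ys), tolerance = 1e-12)
    b <- ks_compare(ys, xs)
    expect_equal(a$d, b$d)
    expect_equal(a$p, b$p)
  }
  # hand-checkable three-point case
  expect_equal(ks_compare(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$d,
               ks_d_oracle(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)),
               tolerance = 1e-12)
})

test_that("bh_adjust follows the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(1), 1)
  set.seed(123)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o])[order(o)], adj)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("promoter windows follow the strand-aware upstream interval rule", {
  genes <- data.frame(contig = "c1", start = 100L, end = 400L, strand = "+",
                      gene_id = "g1", annotation = "", stringsAsFactors = FALSE)
  inst <- data.frame(contig = "c1", site_pos = c(50L, 39L, 40L, 99L, 100L),
                     stringsAsFactors = FALSE)
  kept <- promoter_subset(inst, genes, window = 60)
  expect_equal(kept$site_pos, c(50L, 40L, 99L))

  genes$strand <- "-"
  inst2 <- data.frame(contig = "c1", site_pos = c(459L, 460L, 400L, 399L),
                      stringsAsFactors = FALSE)
  kept2 <- promoter_subset(inst2, genes, window = 60)
  expect_equal(sort(kept2$site_pos), c(400L, 459L))
})

make_profiles <- function(n = 20, fa = 0.5, fb = 0.5, cov = 50L, seed = 1) {
  set.seed(seed)
  inst <- data.frame(contig = "c1", strand = "+", start = seq_len(n) * 10L,
                     site_pos = seq_len(n) * 10L + 1L, motif = "GATC",
                     meth_offset = 1L, mod_type = "6mA")
  rec <- rbind(
    mk_records("t1", "c1", inst$site_pos, "+", "6mA", cov,
               rbinom(n, cov, fa)),
    mk_records("t2", "c1", inst$site_pos, "+", "6mA", cov,
               rbinom(n, cov, fa)),
    mk_records("b1", "c1", inst$site_pos, "+", "6mA", cov,
               rbinom(n, cov, fb)),
    mk_records("b2", "c1", inst$site_pos, "+", "6mA", cov,
               rbinom(n, cov, fb)))
  profile_instances(inst, rec, c(t1 = "top", t2 = "top", b1 = "bottom",
                                 b2 = "bottom"))
}

test_that("contig_differential: identical groups give d = 0, small sets are flagged", {
  prof <- make_profiles(n = 20)
  # compare the top group against itself by relabelling
  prof_same <- prof
  prof_same$group_mean[prof_same$group == "bottom"] <-
    prof_same$group_mean[prof_same$group == "top"]
  cd <- contig_differential(prof_same, "top", "bottom")
  expect_equal(cd$d, 0)
  expect_false(cd$significant)

  few <- make_profiles(n = 5)
  cd2 <- contig_differential(few, "top", "bottom", min_instances = 10)
  expect_equal(cd2$status, "insufficient_data")
  expect_true(is.na(cd2$d))
})

test_that("contig_differential detects a strong group shift and supports SE statistic", {
  prof <- make_profiles(n = 60, fa = 0.2, fb = 0.8, seed = 9)
  cd <- contig_differential(prof, "top", "bottom")
  expect_true(cd$significant)
  expect_gt(cd$d, 0.8)
  cd_se <- contig_differential(prof, "top", "bottom",
                               statistic_kind = "standard_error")
  expect_equal(cd_se$statistic_kind, "standard_error")
  expect_equal(cd_se$n_instances, 60L)
})

test_that("instance_differential effect sign and p-values match the exact oracle", {
  inst <- data.frame(contig = "c1", strand = "+", start = 10L, site_pos = 11L,
                     motif = "GATC", meth_offset = 1L, mod_type = "6mA")
  rec <- rbind(mk_records("t1", "c1", 11L, "+", "6mA", 100L, 90L),
               mk_records("b1", "c1", 11L, "+", "6mA", 100L, 10L))
  prof <- profile_instances(inst, rec, c(t1 = "top", b1 = "bottom"))
  r <- instance_differential(prof, "top", "bottom")
  expect_equal(r$delta, -0.8)
  expect_lt(r$p_raw, 1e-6)
  expect_lt(fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value, 1e-6)

  # equal pooled proportions: delta 0, p 1
  rec2 <- rbind(mk_records("t1", "c1", 11L, "+", "6mA", 100L, 10L),
                mk_records("b1", "c1", 11L, "+", "6mA", 100L, 10L))
  prof2 <- profile_instances(inst, rec2, c(t1 = "top", b1 = "bottom"))
  r2 <- instance_differential(prof2, "top", "bottom")
  expect_equal(r2$delta, 0)
  expect_equal(r2$p_raw, 1)
})

test_that("swapping group labels negates deltas and leaves p unchanged", {
  prof <- make_profiles(n = 15, fa = 0.3, fb = 0.6, seed = 4)
  ab <- instance_differential(prof, "top", "bottom")
  ba <- instance_differential(prof, "bottom", "top")
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_raw, ba$p_raw)

  cd_ab <- contig_differential(prof, "top", "bottom")
  cd_ba <- contig_differential(prof, "bottom", "top")
  expect_equal(cd_ab$d, cd_ba$d)
  expect_equal(cd_ab$p_raw, cd_ba$p_raw)
})

test_that("promoter-only scope restricts the tested instances", {
  prof <- make_profiles(n = 30, fa = 0.2, fb = 0.8, seed = 2)
  genes <- data.frame(contig = "c1", start = 160L, end = 240L, strand = "+",
                      gene_id = "g1", annotation = "", stringsAsFactors = FALSE)
  cd <- contig_differential(prof, "top", "bottom", scope = "promoter_only",
                            genes = genes, window = 60, min_instances = 2)
  # promoter [100, 160): site_pos 101, 111, ..., 151 -> 6 instances
  expect_equal(cd$n_instances, 6L)
  expect_error(contig_differential(prof, "top", "bottom",
                                   scope = "promoter_only"),
               "requires gene models")
})
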