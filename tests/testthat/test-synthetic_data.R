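test_that("the same configuration and seed produce byte-identical bundles", {
  cfg <- sim_config(seed = 5, contig_length_bp = 20000,
                    prophage = list(length_bp = 5000, motif_depletion_rho = 0.5),
                    genes = list(n_genes = 10, mean_length = 600),
                    background_site_rate = 0.1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(generate_bundle(cfg, d1))
  suppressMessages(generate_bundle(cfg, d2))
  f1 <- sort(list.files(d1))
  expect_true(length(f1) >= 10)
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("generated pileups satisfy n_mod <= valid_cov and parse back cleanly", {
  cfg <- sim_config(seed = 6, contig_length_bp = 20000,
                    prophage = list(length_bp = 5000, motif_depletion_rho = 0.5),
                    background_site_rate = 0.2)
  d <- withr::local_tempdir()
  sim <- suppressMessages(generate_bundle(cfg, d))
  expect_true(all(sim$records$n_mod <= sim$records$valid_cov))
  r <- read_bedmethyl(sim$paths$bedmethyl[1], "top1")
  orig <- sim$records[sim$records$sample_id == "top1", ]
  expect_equal(nrow(r), nrow(orig))
  expect_equal(sum(r$n_mod), sum(orig$n_mod))
  expect_equal(sum(r$valid_cov), sum(orig$valid_cov))
  # regions and RM table round-trip through their writers/parsers
  reg <- read_regions(sim$paths$regions)
  expect_equal(sort(unique(reg$label)), c("host", "prophage"))
  rm <- read_rm_table(sim$paths$rm)
  expect_equal(nrow(rm), nrow(sim$rm_genes))
  genes <- read_gff(sim$paths$gff, types = "gene")
  expect_equal(genes$start, sim$genes$start)
  expect_equal(genes$end, sim$genes$end)
})

test_that("degenerate fraction limits give saturated and empty sites", {
  cfg <- light_cfg(8, contig_length_bp = 20000, coverage_lambda = 200,
                   diff_fraction_of_instances = 0,
                   planted_motifs = list(list(motif = motif("GATC", 1, "6mA"),
                                              site_fraction_mean = 1,
                                              background_fraction_mean = 0)),
                   background_site_rate = 0.05)
  sim <- simulate_tables(cfg)
  ti <- sim$truth$instances
  key <- paste(sim$records$contig, sim$records$pos, sim$records$strand)
  planted <- key %in% paste(ti$contig, ti$site_pos, ti$strand)
  with_cov <- sim$records$valid_cov > 0
  expect_true(all(sim$records$fraction[planted & with_cov] == 1))
  expect_true(all(sim$records$fraction[!planted & with_cov] == 0))
})

test_that("natural instance counts match the composition expectation", {
  cfg <- light_cfg(9, contig_length_bp = 200000, background_site_rate = 0,
                   n_samples_per_group = 1, gc_fraction = 0.5)
  sim <- simulate_tables(cfg)
  n <- nrow(sim$truth$instances)
  L <- 200000
  expected <- 2 * (L - 3) / 256
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("the differential subset is the configured size and shifted group-wise", {
  sim <- simulate_tables(light_cfg(10, contig_length_bp = 60000,
                                   background_site_rate = 0,
                                   diff_fraction_of_instances = 0.2,
                                   diff_delta = 0.3))
  ti <- sim$truth$instances
  expect_equal(sum(ti$is_diff), round(0.2 * nrow(ti)))
  expect_true(all(ti$true_bottom >= 0 & ti$true_bottom <= 1))
  # shifted instances are more methylated in the bottom group on average
  expect_gt(mean(ti$true_bottom[ti$is_diff] - ti$true_top[ti$is_diff]), 0.05)
})

test_that("a prophage with depletion rho halves the planted-motif density", {
  hits <- 0
  tot <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 400 + s, contig_length_bp = 60000,
                      background_site_rate = 0, n_samples_per_group = 1,
                      genes = NULL, rm_table_spec = NULL,
                      gc_skew_planting = NULL,
                      prophage = list(length_bp = 20000,
                                      motif_depletion_rho = 0.5))
    sim <- simulate_tables(cfg)
    ti <- sim$truth$instances
    hits <- hits + sum(ti$in_prophage)
    tot <- tot + nrow(ti)
  }
  # prophage occupies 1/3 of the contig; rho = 0.5 leaves ~ 1/5 of instances
  frac <- hits / tot
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("infeasible configurations are rejected before any file is written", {
  expect_error(sim_config(contig_length_bp = 10000,
                          prophage = list(length_bp = 20000,
                                          motif_depletion_rho = 0.5)),
               "prophage longer")
  expect_error(sim_config(diff_delta = 2), "diff_delta")
  expect_error(sim_config(rm_table_spec = list(IV = c(n_mtase = 1, n_rease = 0))),
               "Type IV")
})
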