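test_that("network generation is deterministic and obeys size constraints", {
  expect_error(generate_network(5), ">= 10")
  expect_error(generate_network(100, model = "smallworld"))
  n1 <- generate_network(200, "scale_free", seed = 4)
  n2 <- generate_network(200, "scale_free", seed = 4)
  expect_identical(n1$edges, n2$edges)
  expect_equal(length(n1$nodes), 200L)
  # simple graph: no self loops, no duplicate unordered pairs
  expect_true(all(n1$edges[, 1] != n1$edges[, 2]))
  expect_false(any(duplicated(paste(n1$edges[, 1], n1$edges[, 2]))))
})

test_that("scale-free networks have heavy-tailed degrees", {
  net <- test_net_500()
  deg <- degree_table(net)$degree
  expect_gte(max(deg), 5 * median(deg))
})

test_that("cohorts without enrichment alter genes at the background rate", {
  net <- test_net_500()
  targets <- data.frame(gene = select_targets(net), enrichment = 1)
  coh <- generate_cohort(net, n_samples = 40, background_rate = 0.02,
                         targets = targets, seed = 12)
  M <- vapply(coh$profiles, `[[`, 1L, "M")
  mu <- 0.02 * 500
  sd_tot <- sqrt(0.02 * 0.98 * 500 / 40)
  expect_lt(abs(mean(M) - mu), 3 * sd_tot)
  # same seed regenerates identical profiles
  coh2 <- generate_cohort(net, n_samples = 40, background_rate = 0.02,
                          targets = targets, seed = 12)
  expect_identical(coh$profiles, coh2$profiles)
})

test_that("planted enrichment raises target-neighborhood alteration counts", {
  net <- test_net_500()
  coh <- generate_cohort(net, n_samples = 40, seed = 13)
  tg <- coh$truth$targets$gene[1]
  k <- length(neighbors(net, tg))
  x <- vapply(coh$profiles, function(p)
    count_altered_neighbors(net, tg, p)$x_obs, 1L)
  # expected ~ 0.16 * k under enrichment 8, background 0.02
  expect_gt(mean(x), 0.08 * k)
  expect_warning(
    generate_cohort(net, n_samples = 2, background_rate = 0.2,
                    targets = data.frame(gene = tg, enrichment = 8),
                    seed = 1),
    "clipped")
})

test_that("phenotypes respond to planted exposure as configured", {
  net <- test_net_500()
  coh <- generate_cohort(net, n_samples = 200, exposed_fraction = 0.5,
                         seed = 14)
  # null drug effect: GI50 independent of exposure
  c0 <- generate_phenotypes(coh, drug_effect = 0, seed = 15)
  r <- cor(c0$phenotypes$gi50[, 1], as.numeric(coh$truth$exposed))
  expect_lt(abs(r), 0.2)
  # strong drug effect lowers GI50 in exposed samples
  c1 <- generate_phenotypes(coh, drug_effect = 2, seed = 15)
  diff <- mean(c1$phenotypes$gi50[coh$truth$exposed, 1]) -
    mean(c1$phenotypes$gi50[!coh$truth$exposed, 1])
  expect_lt(diff, -1)
  # hazard ratio 4: exposed median event time ~ 1/4 of baseline
  c2 <- generate_phenotypes(coh, survival_hr = 4, censor_max = 1e6,
                            seed = 16)
  cl <- c2$phenotypes$clinical
  med <- tapply(cl$time, coh$truth$exposed[cl$sample], median)
  expect_equal(unname(med[["TRUE"]] / med[["FALSE"]]), 0.25,
               tolerance = 0.35)
  # deterministic regeneration
  c3 <- generate_phenotypes(coh, survival_hr = 4, censor_max = 1e6,
                            seed = 16)
  expect_identical(c2$phenotypes, c3$phenotypes)
})

test_that("fixtures round-trip exactly through the genomic parsers", {
  net <- generate_network(120, "scale_free", seed = 17)
  coh <- generate_cohort(net, n_samples = 10, n_targets = 3,
                         min_target_degree = 5, seed = 18)
  coh <- generate_phenotypes(coh, seed = 19)
  dir <- tempfile()
  write_fixture(coh, dir)
  fx <- read_fixture(dir)
  expect_identical(fx$net$adjacency, net$adjacency)
  expect_identical(fx$profiles, coh$profiles)
  expect_identical(fx$seeds, coh$truth$targets$gene)
  expect_equal(dim(fx$gi50), dim(coh$phenotypes$gi50))
  # MAF has the required header columns
  header <- readLines(file.path(dir, "muts.maf"), n = 1)
  expect_true(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                    "Variant_Classification") %in%
                    strsplit(header, "\t")[[1]]))
})

test_that("a cohort without phenotypes writes valid headered phenotype stubs", {
  net <- generate_network(60, "scale_free", seed = 20)
  coh <- generate_cohort(net, n_samples = 4, n_targets = 2,
                         min_target_degree = 3, seed = 21)
  dir <- tempfile()
  write_fixture(coh, dir)
  for (f in c("gi50.csv", "subtypes.csv", "clinical.csv")) {
    df <- read.csv(file.path(dir, f))
    expect_equal(nrow(df), 0L)
    expect_true("sample" %in% names(df))
  }
  fx <- read_fixture(dir)
  expect_identical(fx$profiles, coh$profiles)
  expect_null(fx$gi50)
})
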