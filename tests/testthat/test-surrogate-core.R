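test_that("seed set expansion applies the minimum-connection threshold", {
  # C adjacent to both seeds, D adjacent to one
  net <- ppi_network(rbind(c("A", "C"), c("B", "C"), c("A", "D"),
                           c("A", "B")), quiet = TRUE)
  gs2 <- expand_seed_set(net, c("A", "B"), min_connections = 2)
  expect_setequal(gs2$expanded, c("A", "B", "C"))
  gs1 <- expand_seed_set(net, c("A", "B"), min_connections = 1)
  expect_setequal(gs1$expanded, c("A", "B", "C", "D"))
  # no qualifying neighbors
  gs3 <- expand_seed_set(net, c("C", "D"), min_connections = 3)
  expect_setequal(gs3$expanded, c("C", "D"))
  # unknown seeds dropped with message; all-unknown errors
  expect_message(expand_seed_set(net, c("A", "B", "ZZZ")), "dropped")
  expect_error(suppressMessages(expand_seed_set(net, "ZZZ")), "no seed")
})

test_that("altered-neighbor counting excludes the focal gene itself", {
  net <- star_graph()
  prof <- make_profile("S1", mutated = c("L1", "X"), gained = "L3")
  cnt <- count_altered_neighbors(net, "X", prof)
  expect_equal(cnt$x_obs, 2L)
  expect_true(cnt$self_altered)
  expect_setequal(cnt$contributing$neighbor, c("L1", "L3"))
  expect_equal(cnt$contributing$types[cnt$contributing$neighbor == "L3"],
               "gain")
  # empty intersection and full neighborhood
  expect_equal(count_altered_neighbors(net, "X",
                                       make_profile("S2"))$x_obs, 0L)
  full <- make_profile("S3", mutated = paste0("L", 1:4))
  expect_equal(count_altered_neighbors(net, "X", full)$x_obs, 4L)
})

test_that("exact tail p-value matches brute-force subset enumeration", {
  expect_equal(exact_tail_pvalue(10, 4, 5, 0), 1)
  expect_equal(exact_tail_pvalue(10, 4, 5, 5), 0)
  expect_equal(exact_tail_pvalue(10, 4, 5, 3), 66 / 252)
  for (N in c(5, 8)) {
    for (k in 0:(N - 1)) {
      for (M in 1:N) {
        for (x in 0:(min(k, M) + 1)) {
          expect_equal(exact_tail_pvalue(N, k, M, x),
                       brute_force_tail(N, k, M, x),
                       tolerance = 1e-12,
                       info = sprintf("N=%d k=%d M=%d x=%d", N, k, M, x))
        }
      }
    }
  }
  expect_error(exact_tail_pvalue(10, 4, 11, 1), "infeasible")
})

test_that("permutation p-values agree with the exact null within Monte-Carlo error", {
  set.seed(42)
  cases <- list(c(10, 4, 5, 3), c(12, 6, 4, 2), c(8, 3, 6, 1),
                c(12, 2, 10, 2), c(9, 5, 5, 4))
  n_perm <- 20000
  for (cs in cases) {
    N <- cs[1]; k <- cs[2]; M <- cs[3]; x <- cs[4]
    p_exact <- exact_tail_pvalue(N, k, M, x)
    p_perm <- mean(perm_null_counts(N, k, M, n_perm) >= x)
    tol <- 4 * sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(p_perm - p_exact), tol + 1e-9)
  }
})

test_that("permutation p-value edge cases follow the null construction", {
  net <- star_graph()
  expect_equal(permutation_pvalue(net, "X", 0, 3, n_perm = 100, seed = 1), 1)
  # M = N: every permutation alters the full neighborhood
  expect_equal(permutation_pvalue(net, "X", 4, 5, n_perm = 200, seed = 1), 1)
  expect_error(permutation_pvalue(net, "X", 1, 6, n_perm = 100), "exceed")
  # add-one correction keeps p in (0, 1]
  p <- permutation_pvalue(net, "X", 1, 1, n_perm = 100, seed = 1,
                          add_one = TRUE)
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("exact p is monotone in x_obs and in M", {
  N <- 200
  for (k in c(3, 10, 40)) {
    for (M in c(5, 20, 80)) {
      p <- vapply(0:min(k, M), function(x) exact_tail_pvalue(N, k, M, x), 1.0)
      expect_true(all(diff(p) <= 1e-12))
    }
    for (x in c(1, 3)) {
      p <- vapply(seq(x, N, by = 7), function(M)
        exact_tail_pvalue(N, k, M, x), 1.0)
      expect_true(all(diff(p) >= -1e-12))
    }
  }
})

test_that("call_surrogates assigns states consistently with calls and alterations", {
  net <- test_net_500()
  cohort <- generate_cohort(net, n_samples = 8, seed = 5)
  fit <- call_surrogates(net, cohort$truth$targets$gene, cohort$profiles)
  genes <- fit$genes  # call_surrogates sorts the tested gene set
  sig <- matrix(fit$calls$significant, nrow = length(genes))
  for (i in seq_along(fit$samples)) {
    for (j in seq_along(genes)) {
      st <- fit$matrix[fit$samples[i], genes[j]]
      expect_equal(st %in% c(1L, 3L), sig[j, i])
      altered <- genes[j] %in% cohort$profiles[[fit$samples[i]]]$altered
      expect_equal(st %in% c(2L, 3L), altered)
    }
  }
  expect_true(all(fit$calls$p_value >= 0 & fit$calls$p_value <= 1))
  expect_true(all(fit$calls$x_obs <= pmin(fit$calls$k, fit$calls$M)))
})

test_that("samples with no alterations and alpha = 0 yield no significant calls", {
  net <- star_graph()
  profs <- list(make_profile("S1"))
  fit <- call_surrogates(net, c("X", "L1"), profs)
  expect_true(all(fit$calls$p_value == 1))
  expect_false(any(fit$calls$significant))
  prof2 <- list(make_profile("S1", mutated = c("L1", "L2", "L3", "L4")))
  fit2 <- call_surrogates(net, "X", prof2, alpha = 0)
  expect_false(any(fit2$calls$significant))
})

test_that("perm-mode runs are reproducible given a seed and match exact mode", {
  net <- test_net_500()
  cohort <- generate_cohort(net, n_samples = 6, seed = 9)
  genes <- cohort$truth$targets$gene
  f1 <- call_surrogates(net, genes, cohort$profiles, mode = "perm",
                        n_perm = 2000, seed = 11)
  f2 <- call_surrogates(net, genes, cohort$profiles, mode = "perm",
                        n_perm = 2000, seed = 11)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$matrix, f2$matrix)
  fe <- call_surrogates(net, genes, cohort$profiles, mode = "exact")
  # permutation estimate tracks the exact null
  expect_lt(max(abs(f1$calls$p_value - fe$calls$p_value)), 0.06)
})

test_that("neighbor frequencies aggregate contributing neighbors across samples", {
  net <- star_graph()
  profs <- c(lapply(1:3, function(i)
    make_profile(paste0("S", i), mutated = "L1")),
    lapply(4:5, function(i) make_profile(paste0("S", i), gained = "L2")))
  fit <- call_surrogates(net, "X", profs)
  nf <- neighbor_frequency(fit, "X")
  expect_equal(nf$n_samples_altered[nf$neighbor == "L1"], 3L)
  expect_equal(nf$n_samples_altered[nf$neighbor == "L2"], 2L)
  # leaves touch only the center within the star subnetwork
  expect_true(all(nf$degree_within_subnetwork == 1L))
  # x_obs = 0 everywhere -> empty table
  fit0 <- call_surrogates(net, "X", list(make_profile("S1")))
  expect_equal(nrow(neighbor_frequency(fit0, "X")), 0L)
  expect_error(neighbor_frequency(fit, "L9"), "not tested")
  # identical duplicated profiles double the frequencies
  profs2 <- c(profs, lapply(profs, function(p) {
    p$sample_id <- paste0(p$sample_id, "b"); p
  }))
  fit2 <- call_surrogates(net, "X", profs2)
  nf2 <- neighbor_frequency(fit2, "X")
  expect_equal(nf2$n_samples_altered[nf2$neighbor == "L1"], 6L)
})
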