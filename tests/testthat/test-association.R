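test_that("GI50 discretization yields equal-occupancy bins with stable ties", {
  lab <- discretize_gi50(c(1, 2, 3, 4))
  expect_equal(as.character(lab),
               c("sensitive", "sensitive", "insensitive", "insensitive"))
  lab2 <- discretize_gi50(c(1, 2, 2, 3))
  expect_equal(table(lab2)[["sensitive"]], 2L)
  expect_equal(table(lab2)[["insensitive"]], 2L)
  # first-occurring tie goes to the low bin (stable order)
  expect_equal(as.character(lab2[2]), "sensitive")
  expect_equal(as.character(lab2[3]), "insensitive")
  # rerun is deterministic
  expect_identical(lab2, discretize_gi50(c(1, 2, 2, 3)))
  # missing values propagate; orientation flag flips labels
  lab3 <- discretize_gi50(c(5, NA, 1, 3, 4, 2))
  expect_true(is.na(lab3[2]))
  lab4 <- discretize_gi50(c(1, 2, 3, 4), low_is_sensitive = FALSE)
  expect_equal(as.character(lab4[1]), "insensitive")
  expect_error(discretize_gi50(c(5, NA, NA, NA)), "at least 4")
})

test_that("bin sizes never differ by more than one", {
  set.seed(3)
  for (n in c(4, 5, 17, 30)) {
    v <- sample(round(rnorm(n), 1))  # induces ties
    tab <- table(discretize_gi50(v))
    expect_lte(abs(tab[["sensitive"]] - tab[["insensitive"]]), 1L)
  }
})

test_that("a perfectly informative feature drives refined OOB error below 10%", {
  set.seed(21)
  n <- 60
  labels <- factor(rep(c("sensitive", "insensitive"), each = n / 2))
  feats <- cbind(truth = as.integer(labels == "sensitive"),
                 matrix(rbinom(n * 19, 1, 0.5), nrow = n,
                        dimnames = list(NULL, paste0("noise", 1:19))))
  fit <- fit_drug_classifier(feats, labels, seed = 7)
  expect_lt(fit$oob_error_refined, 0.10)
  expect_true("truth" %in% fit$features_refined)
  expect_equal(length(fit$features_refined), max(1, round(0.10 * 20)))
})

test_that("refinement keeps max(1, round(fraction * p)) features", {
  set.seed(2)
  n <- 30
  labels <- factor(rep(c("a", "b"), each = n / 2))
  feats <- matrix(rbinom(n * 10, 1, 0.5), nrow = n)
  fit <- fit_drug_classifier(feats, labels, seed = 3)
  expect_length(fit$features_refined, 1L)
  expect_error(fit_drug_classifier(feats, factor(rep("a", n)), seed = 1),
               "single class")
})

test_that("permuted labels give chance-level OOB error", {
  set.seed(31)
  n <- 60
  labels <- factor(sample(rep(c("s", "i"), each = n / 2)))
  feats <- matrix(rbinom(n * 20, 1, 0.5), nrow = n)
  fit <- fit_drug_classifier(feats, labels, seed = 13)
  expect_gte(fit$oob_error_initial, 0.35)
  expect_lte(fit$oob_error_initial, 0.65)
})

test_that("chance-level contract tightens with more samples", {
  set.seed(41)
  n <- 200
  errs <- vapply(1:3, function(i) {
    labels <- factor(sample(rep(c("s", "i"), each = n / 2)))
    feats <- matrix(rbinom(n * 20, 1, 0.5), nrow = n)
    fit_drug_classifier(feats, labels, seed = 17 + i)$oob_error_initial
  }, 1.0)
  expect_lt(abs(mean(errs) - 0.5), 0.08)
})

test_that("drug panel report collects per-drug OOB errors", {
  set.seed(51)
  n <- 40
  feats <- matrix(rbinom(n * 12, 1, 0.5), nrow = n,
                  dimnames = list(sprintf("S%02d", 1:n),
                                  paste0("g", 1:12)))
  gi50 <- data.frame(sample = rownames(feats),
                     drugA = rnorm(n) - 2 * feats[, 1],
                     drugB = rnorm(n))
  rep <- drug_sensitivity_report(feats, gi50, seed = 5)
  expect_equal(rep$report$drug, c("drugA", "drugB"))
  expect_true(all(rep$report$oob_error_refined >= 0 &
                    rep$report$oob_error_refined <= 1))
})

test_that("subtype association reproduces the exact p on a balanced diagonal table", {
  # 3 surrogate samples all basal, 3 non-surrogate all luminal:
  # table [[3,0],[0,3]] has two-sided p = 2/20 = 0.1
  m <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1,
              dimnames = list(paste0("S", 1:6), "GENE1"))
  st <- setNames(rep(c("basal", "luminal"), each = 3), paste0("S", 1:6))
  out <- subtype_association(m, st)
  expect_equal(out$p_value[out$subtype == "basal"], 0.1, tolerance = 1e-9)
  expect_equal(out$p_value[out$subtype == "basal"],
               fisher_oracle(3, 0, 0, 3), tolerance = 1e-9)
  expect_equal(out$direction[out$subtype == "basal"], "enriched")
})

test_that("degenerate margins give p = 1 and never-significant genes are skipped", {
  m <- matrix(c(rep(1L, 6), rep(0L, 6)), ncol = 2,
              dimnames = list(paste0("S", 1:6), c("ALWAYS", "NEVER")))
  st <- setNames(rep(c("basal", "luminal"), each = 3), paste0("S", 1:6))
  out <- subtype_association(m, st)
  expect_false("NEVER" %in% out$gene)
  expect_true(all(out$p_value[out$gene == "ALWAYS"] == 1))
  expect_error(subtype_association(m, setNames(rep("basal", 6),
                                               paste0("S", 1:6))),
               "2 distinct subtype")
})

test_that("Fisher p-values match exhaustive enumeration for small margins", {
  for (a in 0:5) for (b in 0:3) for (cc in 0:3) for (d in 0:5) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    tab <- matrix(c(a, cc, b, d), 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 fisher_oracle(a, b, cc, d), tolerance = 1e-9,
                 info = sprintf("a=%d b=%d c=%d d=%d", a, b, cc, d))
  }
})

test_that("classifier blending sweeps the weight grid", {
  set.seed(61)
  y <- factor(rep(c("s", "i"), 20))
  # probabilities refer to the first factor level ("i")
  p_good <- ifelse(y == "i", 0.9, 0.1) + rnorm(40, 0, 0.05)
  p_bad <- runif(40)
  bl <- blend_classifiers(p_good, p_bad, y)
  expect_equal(nrow(bl), 11L)
  expect_lt(bl$error[bl$weight == 1], bl$error[bl$weight == 0])
})
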