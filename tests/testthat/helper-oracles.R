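# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive enumeration oracle for the neighborhood null: probability that
# a uniformly drawn M-subset of N items contains >= x of the first k items.
brute_force_tail <- function(N, k, M, x) {
  if (x <= 0) return(1)
  if (M == 0) return(0)
  subsets <- utils::combn(N, M)
  mean(apply(subsets, 2, function(s) sum(s <= k)) >= x)
}

# Closed-form k-group log-rank statistic computed directly from its
# definition (sum over distinct event times of observed minus expected
# events in group 1, variance-standardised).
logrank_oracle <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  ts <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1L])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1L])
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Two-sided Fisher exact p by enumeration of all 2x2 tables with the
# observed margins, using table probabilities from log-binomial
# coefficients only.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  logp <- function(x) lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  xs <- lo:hi
  probs <- exp(logp(xs))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Toy graphs.
path_graph <- function(symbols = c("A", "B", "C")) {
  ppi_network(cbind(symbols[-length(symbols)], symbols[-1]), quiet = TRUE)
}
star_graph <- function(center = "X", leaves = paste0("L", 1:4)) {
  ppi_network(cbind(center, leaves), quiet = TRUE)
}
triangle_graph <- function() {
  ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")), quiet = TRUE)
}

# Minimal alteration profile without going through file parsers.
make_profile <- function(sample_id, mutated = character(0),
                         gained = character(0), lost = character(0)) {
  altered <- sort(unique(c(mutated, gained, lost)))
  structure(list(sample_id = sample_id, mutated = sort(unique(mutated)),
                 gained = sort(unique(gained)), lost = sort(unique(lost)),
                 altered = altered, M = length(altered)),
            class = "alteration_profile")
}

# Write a tiny MAF file; rows is a data frame-like list of
# (gene, sample, class).
write_tiny_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  df <- data.frame(Hugo_Symbol = rows$gene,
                   Tumor_Sample_Barcode = rows$sample,
                   Variant_Classification = rows$class,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Shared medium network for cohort-level tests (built once per test run).
test_net_500 <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- generate_network(500, "scale_free", seed = 101)
    net
  }
})
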