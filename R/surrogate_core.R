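#' Expand a seed oncogene set over the network
#'
#' Grows a curated seed list by adding network neighbors with at least
#' `min_connections` interactions to seed genes. Seeds absent from the
#' network are dropped with a message.
#'
#' @param net a [ppi_network].
#' @param seeds character vector of seed gene symbols.
#' @param min_connections minimum number of seed neighbors a non-seed gene
#'   needs to join the set (default 2).
#' @return Object of class `surrogate_gene_set`: list with `seeds`,
#'   `expanded` (seeds plus qualifying neighbors, sorted) and
#'   `min_connections`.
#' @export
expand_seed_set <- function(net, seeds, min_connections = 2) {
  stopifnot(inherits(net, "ppi_network"))
  seeds <- unique(toupper(trimws(seeds)))
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown))
    message(sprintf("expand_seed_set: %d seed(s) not in network dropped (%s%s)",
                    length(unknown),
                    paste(utils::head(unknown, 3), collapse = ", "),
                    if (length(unknown) > 3) ", ..." else ""))
  seeds <- intersect(seeds, net$nodes)
  if (!length(seeds)) stop("no seed genes present in the network")
  candidates <- setdiff(unique(unlist(net$adjacency[seeds],
                                      use.names = FALSE)), seeds)
  n_links <- vapply(candidates, function(g)
    length(intersect(net$adjacency[[g]], seeds)), 1L)
  expanded <- sort(c(seeds, candidates[n_links >= min_connections]))
  structure(list(seeds = sort(seeds), expanded = expanded,
                 min_connections = min_connections),
            class = "surrogate_gene_set")
}

#' @export
print.surrogate_gene_set <- function(x, ...) {
  cat(sprintf("surrogate_gene_set: %d seeds expanded to %d genes (>= %d seed connections)\n",
              length(x$seeds), length(x$expanded), x$min_connections))
  invisible(x)
}

#' Count altered neighbors of a gene in one sample
#'
#' The observed statistic of the neighborhood-enrichment test: the number of
#' distinct altered genes among the immediate PPI neighbors of `gene`. The
#' gene's own alteration status is reported but never counted.
#'
#' @param net a [ppi_network].
#' @param gene gene symbol.
#' @param profile an `alteration_profile` (see [build_profiles()]).
#' @return List with `x_obs` (integer), `contributing` (data frame with
#'   columns `neighbor`, `types` — comma-joined alteration types) and
#'   `self_altered` (logical).
#' @export
count_altered_neighbors <- function(net, gene, profile) {
  gene <- toupper(trimws(gene))
  nbrs <- neighbors(net, gene)
  hit <- intersect(nbrs, profile$altered)
  types <- vapply(hit, function(g) {
    paste(c(if (g %in% profile$mutated) "mutation",
            if (g %in% profile$gained) "gain",
            if (g %in% profile$lost) "loss"), collapse = ",")
  }, "")
  list(x_obs = length(hit),
       contributing = data.frame(neighbor = hit, types = unname(types),
                                 stringsAsFactors = FALSE),
       self_altered = gene %in% profile$altered)
}

#' Exact tail probability of the neighborhood null
#'
#' Placing `M` distinct altered genes uniformly at random on a network of
#' `N` genes, the number landing among a fixed gene's `k` neighbors is
#' hypergeometric. This returns the upper tail `P(X >= x_obs)`, the exact
#' counterpart of the permutation p-value.
#'
#' @param N network size (number of genes).
#' @param k degree of the tested gene.
#' @param M number of distinct altered genes in the sample.
#' @param x_obs observed altered-neighbor count.
#' @return `P(X >= x_obs)` for `X ~ Hypergeometric(N, k, M)`.
#' @export
exact_tail_pvalue <- function(N, k, M, x_obs) {
  if (any(c(N, k, M, x_obs) < 0) || k > N || M > N)
    stop("infeasible null parameters: need 0 <= k, M <= N and x_obs >= 0")
  if (x_obs <= 0) return(1)
  if (x_obs > min(k, M)) return(0)
  stats::phyper(x_obs - 1, k, N - k, M, lower.tail = FALSE)
}

#' Sample null altered-neighbor counts by network permutation
#'
#' Simulates the null of randomly mutating the entire network: each
#' permutation places `M` distinct altered genes uniformly (drawn without
#' replacement from all `N` genes) and counts how many fall among a fixed
#' set of `k` neighbors. Sampling is sequential without replacement,
#' vectorised across permutations.
#'
#' @param N,k,M null parameters as in [exact_tail_pvalue()].
#' @param n_perm number of permutations.
#' @return Integer vector of `n_perm` null counts.
#' @export
perm_null_counts <- function(N, k, M, n_perm) {
  if (M > N) stop("M cannot exceed network size N")
  if (n_perm < 1) stop("n_perm must be >= 1")
  s <- rep.int(as.numeric(k), n_perm)   # neighbors not yet drawn
  hits <- integer(n_perm)
  for (t in seq_len(M)) {
    h <- stats::runif(n_perm) < s / (N - t + 1)
    hits <- hits + h
    s <- s - h
  }
  hits
}

# Tail p-value from cached/simulated null counts.
.perm_tail <- function(counts, x_obs, add_one = FALSE) {
  r <- sum(counts >= x_obs)
  if (add_one) (r + 1) / (length(counts) + 1) else r / length(counts)
}

#' Permutation p-value for one (gene, sample) test
#'
#' Proportion of network permutations in which the altered-neighbor count
#' reaches the observed count, per the permutation framework. `x_obs = 0`
#' always yields p = 1.
#'
#' @param net a [ppi_network].
#' @param gene gene symbol (determines `k`).
#' @param x_obs observed altered-neighbor count.
#' @param M number of distinct altered genes in the sample.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @param add_one if `TRUE`, apply the add-one correction
#'   `(r + 1) / (n_perm + 1)` so p is never exactly zero.
#' @return Permutation p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(net, gene, x_obs, M, n_perm = 10000,
                               seed = NULL, add_one = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  N <- length(net$nodes)
  k <- length(neighbors(net, gene))
  if (M > N) stop("M cannot exceed network size N")
  if (x_obs > min(k, M))
    stop("x_obs cannot exceed min(k, M)")
  if (!is.null(seed)) set.seed(seed)
  if (x_obs <= 0 && !add_one) return(1)
  .perm_tail(perm_null_counts(N, k, M, n_perm), x_obs, add_one)
}

# State codes of the sample x gene matrix.
.surrogate_states <- c("none", "surrogate_only", "altered_only", "both")

#' Call surrogate oncogenes across a cohort
#'
#' The main fit: for every sample and every gene in the surrogate set, tests
#' whether the gene's PPI neighborhood carries more altered genes than
#' expected when the sample's `M` alterations are placed on the network at
#' random. `mode = "exact"` (default) evaluates the null in closed form
#' (hypergeometric tail); `mode = "perm"` reproduces the permutation
#' procedure, caching the simulated null by `(k, M)` within the run so
#' p-values are monotone in the observed count by construction.
#'
#' @param net a [ppi_network].
#' @param gene_set a `surrogate_gene_set` from [expand_seed_set()], or a
#'   character vector of genes to test.
#' @param profiles list of alteration profiles from [build_profiles()].
#' @param alpha significance level; a call is significant when
#'   `p < alpha` (default 0.05).
#' @param mode `"exact"` or `"perm"`.
#' @param n_perm permutations per null (perm mode, default 10000).
#' @param seed RNG seed (perm mode); required there for reproducible runs.
#' @param add_one add-one correction of permutation p-values (perm mode).
#' @param p_adjust `"none"` (default; raw per-test alpha) or a method name
#'   for [stats::p.adjust()] (e.g. `"BH"`). Surrogate calls are nested,
#'   dependent tests, so adjusted p-values are approximate at best.
#' @return Object of class `surrogate_calls`: list with `calls` (data frame:
#'   sample, gene, k, M, x_obs, p_value, significant, self_altered),
#'   `matrix` (integer sample x gene state matrix coded 0 = none,
#'   1 = surrogate_only, 2 = altered_only, 3 = both), `contributing`
#'   (nested list `[[gene]][[sample]]` of contributing-neighbor tables),
#'   plus the call parameters and the network.
#' @export
call_surrogates <- function(net, gene_set, profiles, alpha = 0.05,
                            mode = c("exact", "perm"), n_perm = 10000,
                            seed = NULL, add_one = FALSE,
                            p_adjust = "none") {
  stopifnot(inherits(net, "ppi_network"))
  mode <- match.arg(mode)
  if (inherits(gene_set, "surrogate_gene_set")) {
    genes <- gene_set$expanded
  } else {
    genes <- sort(unique(toupper(trimws(gene_set))))
    gene_set <- structure(list(seeds = genes, expanded = genes,
                               min_connections = NA_integer_),
                          class = "surrogate_gene_set")
  }
  missing_genes <- setdiff(genes, net$nodes)
  if (length(missing_genes))
    stop("gene set members not in network: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (mode == "perm" && n_perm < 1) stop("n_perm must be >= 1")
  if (mode == "perm" && !is.null(seed)) set.seed(seed)
  N <- length(net$nodes)
  samples <- unname(vapply(profiles, `[[`, "", "sample_id"))
  k_of <- vapply(genes, function(g) length(net$adjacency[[g]]), 1L)

  null_cache <- new.env(parent = emptyenv())
  pval <- function(k, M, x) {
    if (mode == "exact") return(exact_tail_pvalue(N, k, M, x))
    key <- paste(k, M, sep = "_")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- perm_null_counts(N, k, M, n_perm)
    .perm_tail(null_cache[[key]], x, add_one)
  }

  n_tests <- length(samples) * length(genes)
  calls <- data.frame(
    sample = rep(samples, each = length(genes)),
    gene = rep(genes, times = length(samples)),
    k = rep(unname(k_of), times = length(samples)),
    M = rep(vapply(profiles, `[[`, 1L, "M"), each = length(genes)),
    x_obs = integer(n_tests), p_value = numeric(n_tests),
    significant = logical(n_tests), self_altered = logical(n_tests),
    stringsAsFactors = FALSE)
  contributing <- stats::setNames(
    lapply(genes, function(g) stats::setNames(vector("list", length(samples)),
                                              samples)), genes)
  row <- 0L
  for (p in profiles) {
    alt <- p$altered
    for (g in genes) {
      row <- row + 1L
      cnt <- count_altered_neighbors(net, g, p)
      calls$x_obs[row] <- cnt$x_obs
      calls$p_value[row] <- pval(k_of[[g]], p$M, cnt$x_obs)
      calls$self_altered[row] <- cnt$self_altered
      contributing[[g]][[p$sample_id]] <- cnt$contributing
    }
  }
  if (p_adjust != "none")
    calls$p_value <- stats::p.adjust(calls$p_value, method = p_adjust)
  calls$significant <- calls$p_value < alpha

  state <- matrix(0L, nrow = length(samples), ncol = length(genes),
                  dimnames = list(samples, genes))
  altered_flag <- matrix(FALSE, length(samples), length(genes),
                         dimnames = list(samples, genes))
  for (p in profiles)
    altered_flag[p$sample_id, ] <- genes %in% p$altered
  sig_flag <- matrix(calls$significant, nrow = length(genes))  # genes x samples
  sig_flag <- t(sig_flag)
  state[sig_flag & !altered_flag] <- 1L
  state[!sig_flag & altered_flag] <- 2L
  state[sig_flag & altered_flag] <- 3L

  structure(list(calls = calls, matrix = state,
                 contributing = contributing, alpha = alpha, mode = mode,
                 n_perm = if (mode == "perm") n_perm else NA_integer_,
                 seed = seed, add_one = add_one, p_adjust = p_adjust,
                 gene_set = gene_set, net = net,
                 samples = unname(samples), genes = genes),
            class = "surrogate_calls")
}

#' Extract the sample-by-gene surrogate state matrix
#'
#' @param fit a `surrogate_calls` object.
#' @param coded if `TRUE` (default) return integer codes 0-3; otherwise a
#'   character matrix of state names (`none`, `surrogate_only`,
#'   `altered_only`, `both`).
#' @return Sample x gene matrix.
#' @export
surrogate_matrix <- function(fit, coded = TRUE) {
  stopifnot(inherits(fit, "surrogate_calls"))
  if (coded) return(fit$matrix)
  m <- matrix(.surrogate_states[fit$matrix + 1L], nrow = nrow(fit$matrix),
              dimnames = dimnames(fit$matrix))
  m
}

#' Binary feature matrix for downstream classifiers
#'
#' Builds the feature table used for drug-sensitivity prediction: one 0/1
#' column per surrogate-set gene indicating a significant surrogate call,
#' optionally alongside one 0/1 column per gene indicating the gene itself
#' is altered in the sample.
#'
#' @param fit a `surrogate_calls` object.
#' @param include_altered also include per-gene alteration indicator columns
#'   (suffix `_alt`); default `TRUE`.
#' @param drop_constant drop features constant across samples (default
#'   `TRUE`; constant features carry no information).
#' @return Numeric sample x feature matrix with values in \{0, 1\}.
#' @export
surrogate_features <- function(fit, include_altered = TRUE,
                               drop_constant = TRUE) {
  stopifnot(inherits(fit, "surrogate_calls"))
  surr <- (fit$matrix == 1L | fit$matrix == 3L) + 0
  colnames(surr) <- paste0(fit$genes, "_surr")
  out <- surr
  if (include_altered) {
    alt <- (fit$matrix == 2L | fit$matrix == 3L) + 0
    colnames(alt) <- paste0(fit$genes, "_alt")
    out <- cbind(surr, alt)
  }
  if (drop_constant) {
    keep <- apply(out, 2, function(v) length(unique(v)) > 1L)
    out <- out[, keep, drop = FALSE]
  }
  out
}

#' Cross-sample frequency of contributing neighbors
#'
#' For one surrogate-set gene, aggregates the altered neighbors that
#' contributed to its test across all samples — the view that surfaces rare
#' or sample-unique mutations participating in the subnetwork.
#'
#' @param fit a `surrogate_calls` object.
#' @param gene gene symbol tested in the fit.
#' @return Data frame with columns `neighbor`, `n_samples_altered`, and
#'   `degree_within_subnetwork` (the neighbor's number of interactions with
#'   other members of the gene-centered subnetwork, i.e. the gene plus its
#'   neighbors), sorted by decreasing frequency.
#' @export
neighbor_frequency <- function(fit, gene) {
  stopifnot(inherits(fit, "surrogate_calls"))
  gene <- toupper(trimws(gene))
  if (!gene %in% fit$genes)
    stop("gene was not tested in this fit: ", gene)
  tabs <- fit$contributing[[gene]]
  nb <- unlist(lapply(tabs, function(d) d$neighbor), use.names = FALSE)
  if (!length(nb))
    return(data.frame(neighbor = character(0),
                      n_samples_altered = integer(0),
                      degree_within_subnetwork = integer(0)))
  freq <- sort(table(nb), decreasing = TRUE)
  subnet <- c(gene, fit$net$adjacency[[gene]])
  deg_sub <- vapply(names(freq), function(g)
    length(intersect(fit$net$adjacency[[g]], subnet)), 1L)
  data.frame(neighbor = names(freq),
             n_samples_altered = as.integer(freq),
             degree_within_subnetwork = unname(deg_sub),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export the gene-centered subnetwork for visualisation
#'
#' Writes node and edge CSV tables for a gene and its immediate neighbors,
#' annotated with cross-sample alteration frequency.
#'
#' @param fit a `surrogate_calls` object.
#' @param gene gene symbol tested in the fit.
#' @param node_path,edge_path output CSV paths.
#' @return Invisibly, a list with the node and edge tables.
#' @export
export_subnetwork <- function(fit, gene, node_path, edge_path) {
  freq <- neighbor_frequency(fit, gene)
  gene <- toupper(trimws(gene))
  subnet <- c(gene, fit$net$adjacency[[gene]])
  nodes <- data.frame(
    gene = subnet,
    role = c("focal", rep("neighbor", length(subnet) - 1L)),
    n_samples_altered = c(NA_integer_,
                          freq$n_samples_altered[
                            match(subnet[-1L], freq$neighbor)]),
    stringsAsFactors = FALSE)
  nodes$n_samples_altered[is.na(nodes$n_samples_altered) &
                            nodes$role == "neighbor"] <- 0L
  e <- fit$net$edges
  keep <- e[, 1L] %in% subnet & e[, 2L] %in% subnet
  edges <- as.data.frame(e[keep, , drop = FALSE], stringsAsFactors = FALSE)
  utils::write.csv(nodes, node_path, row.names = FALSE)
  utils::write.csv(edges, edge_path, row.names = FALSE)
  invisible(list(nodes = nodes, edges = edges))
}
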