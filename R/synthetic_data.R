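#' Generate a synthetic PPI-like network
#'
#' Scale-free mode uses preferential attachment, reproducing the heavy-
#' tailed degree distribution of curated interaction databases (where
#' oncogenes tend to be hubs); `erdos_renyi` gives a homogeneous-degree
#' control.
#'
#' @param n_nodes number of genes (>= 10).
#' @param model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`.
#' @param param edges added per new node (`m`, default 3) for scale-free;
#'   edge probability `p` for Erdos-Renyi.
#' @param seed RNG seed.
#' @return A [ppi_network] with nodes named `G0001`, `G0002`, ...
#' @export
generate_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                             param = 3, seed = NULL) {
  model <- match.arg(model)
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model,
    scale_free = igraph::sample_pa(n_nodes, m = param, directed = FALSE,
                                   algorithm = "psumtree"),
    erdos_renyi = igraph::sample_gnp(n_nodes, p = param))
  el <- igraph::as_edgelist(g, names = FALSE)
  width <- max(4L, nchar(as.character(n_nodes)))
  sym <- sprintf(paste0("G%0", width, "d"), seq_len(n_nodes))
  ppi_network(cbind(sym[el[, 1L]], sym[el[, 2L]]), nodes = sym,
              quiet = TRUE)
}

#' Default planted-target selection: highest-degree genes
#'
#' Oncogene stand-ins are drawn from the network hubs, mirroring the high
#' connectivity of real oncogenes.
#'
#' @param net a [ppi_network].
#' @param n number of targets.
#' @param min_degree minimum degree a target must have (default 20).
#' @return Character vector of target gene symbols.
#' @export
select_targets <- function(net, n = 5, min_degree = 20) {
  dt <- degree_table(net)
  dt <- dt[dt$degree >= min_degree, ]
  if (nrow(dt) < n)
    stop(sprintf("only %d node(s) with degree >= %d; cannot pick %d targets",
                 nrow(dt), min_degree, n))
  dt <- dt[order(-dt$degree, dt$gene), ]
  dt$gene[seq_len(n)]
}

#' Generate a synthetic cohort with planted neighborhood enrichment
#'
#' Each sample alters each gene independently at `background_rate`, except
#' the immediate neighbors of each planted target gene, which are altered
#' at `min(1, enrichment x background_rate)` in exposed samples. The
#' planted signal is neighborhood enrichment — exactly what the surrogate
#' statistic detects — while targets themselves stay at background rate.
#' A configurable share of alterations is labelled copy-number gain/loss
#' (default 30%, the approximate CNA share among cell-line neighbors);
#' the rest are mutations.
#'
#' @param net a [ppi_network].
#' @param n_samples cohort size (default 40).
#' @param background_rate per-gene alteration probability (default 0.02).
#' @param targets data frame with columns `gene` and `enrichment`, or
#'   `NULL` to pick `n_targets` hubs via [select_targets()] with a common
#'   `enrichment`.
#' @param n_targets,enrichment,min_target_degree defaults for automatic
#'   target selection (5 targets, enrichment 8, degree >= 20).
#' @param exposed_fraction fraction of samples carrying the planted signal
#'   (default 1; lower it to create contrast for phenotype association).
#' @param cna_fraction fraction of alterations labelled CNA (default 0.30).
#' @param seed RNG seed.
#' @return Object of class `synthetic_cohort`: list with `net`, `profiles`
#'   (as from [build_profiles()]), `truth` (targets data frame + named
#'   logical `exposed`) and the generator parameters.
#' @export
generate_cohort <- function(net, n_samples = 40, background_rate = 0.02,
                            targets = NULL, n_targets = 5, enrichment = 8,
                            min_target_degree = 20, exposed_fraction = 1,
                            cna_fraction = 0.30, seed = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (background_rate <= 0 || background_rate >= 1)
    stop("background_rate must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) {
    targets <- data.frame(gene = select_targets(net, n_targets,
                                                min_target_degree),
                          enrichment = enrichment,
                          stringsAsFactors = FALSE)
  }
  targets$gene <- toupper(trimws(targets$gene))
  if (!all(targets$gene %in% net$nodes))
    stop("planted targets must be network nodes")
  if (any(targets$enrichment < 1)) stop("enrichment factors must be >= 1")
  if (any(targets$enrichment * background_rate > 1))
    warning("enrichment x background_rate exceeds 1; clipped to 1")
  N <- length(net$nodes)
  # per-gene alteration probability in exposed samples: max over targets
  p_exposed <- stats::setNames(rep(background_rate, N), net$nodes)
  for (i in seq_len(nrow(targets))) {
    nb <- net$adjacency[[targets$gene[i]]]
    p_enr <- min(1, targets$enrichment[i] * background_rate)
    p_exposed[nb] <- pmax(p_exposed[nb], p_enr)
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  n_exposed <- round(exposed_fraction * n_samples)
  exposed <- stats::setNames(rep(FALSE, n_samples), sample_ids)
  if (n_exposed > 0)
    exposed[sample(sample_ids, n_exposed)] <- TRUE
  profiles <- lapply(stats::setNames(sample_ids, sample_ids), function(s) {
    p <- if (exposed[[s]]) p_exposed else rep(background_rate, N)
    altered <- net$nodes[stats::runif(N) < p]
    is_cna <- stats::runif(length(altered)) < cna_fraction
    gain <- stats::runif(length(altered)) < 0.5
    mut <- sort(altered[!is_cna])
    gai <- sort(altered[is_cna & gain])
    los <- sort(altered[is_cna & !gain])
    structure(list(sample_id = s, mutated = mut, gained = gai, lost = los,
                   altered = sort(altered), M = length(altered)),
              class = "alteration_profile")
  })
  structure(list(net = net, profiles = profiles,
                 truth = list(targets = targets, exposed = exposed),
                 phenotypes = NULL,
                 params = list(n_samples = n_samples,
                               background_rate = background_rate,
                               exposed_fraction = exposed_fraction,
                               cna_fraction = cna_fraction),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples on %d-node network; %d planted target(s), %d exposed sample(s)\n",
              length(x$profiles), length(x$net$nodes),
              nrow(x$truth$targets), sum(x$truth$exposed)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotypes: %d drug(s), subtypes, survival\n",
                ncol(x$phenotypes$gi50)))
  invisible(x)
}

#' Attach phenotypes driven by the planted signal
#'
#' Generates (i) a GI50 table in which exposed samples (those carrying the
#' planted surrogate signal) are shifted toward sensitivity by
#' `drug_effect` standard deviations of the Gaussian noise; (ii) subtype
#' labels assigned by exposure (`P(subtype_A | exposed) = subtype_prob`,
#' `1 - subtype_prob` otherwise); (iii) exponential survival with a group
#' hazard ratio for exposed samples and uniform censoring.
#'
#' @param cohort a `synthetic_cohort`.
#' @param drug_effect GI50 shift (noise-SD units) in exposed samples;
#'   negative shift = more sensitive. Default 2.
#' @param n_drugs drugs in the GI50 table (default 5).
#' @param subtype_prob probability an exposed sample gets the first
#'   subtype label (default 0.9).
#' @param survival_hr hazard ratio of exposed vs unexposed (default 4).
#' @param baseline_rate baseline exponential hazard (default 0.1).
#' @param censor_max upper bound of the uniform censoring time, as a
#'   multiple of the baseline mean survival (default 5, about 20%
#'   censoring in the baseline group).
#' @param seed RNG seed.
#' @return The cohort with a `phenotypes` element: `gi50` (sample x drug
#'   matrix), `subtypes` (named character), `clinical` (data frame:
#'   sample, time, event).
#' @export
generate_phenotypes <- function(cohort, drug_effect = 2, n_drugs = 5,
                                subtype_prob = 0.9, survival_hr = 4,
                                baseline_rate = 0.1, censor_max = 5,
                                seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.null(seed)) set.seed(seed)
  exposed <- cohort$truth$exposed
  n <- length(exposed)
  gi50 <- matrix(stats::rnorm(n * n_drugs), nrow = n,
                 dimnames = list(names(exposed),
                                 sprintf("drug%02d", seq_len(n_drugs))))
  gi50 <- gi50 - drug_effect * exposed  # lower GI50 = sensitive
  subtypes <- stats::setNames(ifelse(
    stats::runif(n) < ifelse(exposed, subtype_prob, 1 - subtype_prob),
    "basal", "luminal"), names(exposed))
  rate <- baseline_rate * ifelse(exposed, survival_hr, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_max / baseline_rate)
  clinical <- data.frame(sample = names(exposed),
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)
  cohort$phenotypes <- list(gi50 = gi50, subtypes = subtypes,
                            clinical = clinical)
  cohort
}

#' Write a synthetic cohort as the flat-file formats the parsers read
#'
#' Emits `edges.tsv`, `nodes.txt`, `muts.maf`, `cn.tsv`, `seeds.txt` and
#' (empty if no phenotypes) `gi50.csv`, `subtypes.csv`, `clinical.csv`,
#' such that [read_fixture()] round-trips the cohort exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(edges = file.path(out_dir, "edges.tsv"),
             nodes = file.path(out_dir, "nodes.txt"),
             maf = file.path(out_dir, "muts.maf"),
             gistic = file.path(out_dir, "cn.tsv"),
             seeds = file.path(out_dir, "seeds.txt"),
             gi50 = file.path(out_dir, "gi50.csv"),
             subtypes = file.path(out_dir, "subtypes.csv"),
             clinical = file.path(out_dir, "clinical.csv"))
  write_network(cohort$net, paths[["edges"]], paths[["nodes"]])
  maf <- do.call(rbind, lapply(cohort$profiles, function(p) {
    if (!length(p$mutated)) return(NULL)
    data.frame(Hugo_Symbol = p$mutated, Tumor_Sample_Barcode = p$sample_id,
               Variant_Classification = "Missense_Mutation",
               stringsAsFactors = FALSE)
  }))
  if (is.null(maf))
    maf <- data.frame(Hugo_Symbol = character(0),
                      Tumor_Sample_Barcode = character(0),
                      Variant_Classification = character(0))
  utils::write.table(maf, paths[["maf"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  samples <- names(cohort$profiles)
  cn <- matrix(0L, nrow = length(cohort$net$nodes), ncol = length(samples),
               dimnames = list(cohort$net$nodes, samples))
  for (p in cohort$profiles) {
    cn[p$gained, p$sample_id] <- 2L
    cn[p$lost, p$sample_id] <- -2L
  }
  cn_df <- data.frame(`Gene Symbol` = rownames(cn), cn,
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cn_df, paths[["gistic"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(cohort$truth$targets$gene, paths[["seeds"]])
  ph <- cohort$phenotypes
  gi <- if (is.null(ph)) {
    data.frame(sample = character(0))
  } else data.frame(sample = rownames(ph$gi50), ph$gi50,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(gi, paths[["gi50"]], row.names = FALSE)
  st <- if (is.null(ph)) {
    data.frame(sample = character(0), subtype = character(0))
  } else data.frame(sample = names(ph$subtypes),
                    subtype = unname(ph$subtypes), stringsAsFactors = FALSE)
  utils::write.csv(st, paths[["subtypes"]], row.names = FALSE)
  cl <- if (is.null(ph)) {
    data.frame(sample = character(0), time = numeric(0), event = integer(0))
  } else ph$clinical
  utils::write.csv(cl, paths[["clinical"]], row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into analysis inputs
#'
#' @param dir directory written by [write_fixture()] (or hand-assembled
#'   with the same file names).
#' @param quiet suppress parser messages.
#' @return List with `net`, `profiles`, `seeds`, and (when present and
#'   non-empty) `gi50`, `subtypes`, `clinical`.
#' @export
read_fixture <- function(dir, quiet = TRUE) {
  net <- load_network(file.path(dir, "edges.tsv"),
                      node_path = {
                        np <- file.path(dir, "nodes.txt")
                        if (file.exists(np)) np else NULL
                      }, quiet = quiet)
  maf <- read_maf(file.path(dir, "muts.maf"), quiet = quiet)
  cn <- read_gistic(file.path(dir, "cn.tsv"))
  profiles <- build_profiles(maf, cn, net, quiet = quiet)
  seeds <- readLines(file.path(dir, "seeds.txt"), warn = FALSE)
  out <- list(net = net, profiles = profiles,
              seeds = seeds[nzchar(seeds)])
  gp <- file.path(dir, "gi50.csv")
  if (file.exists(gp)) {
    gi <- utils::read.csv(gp, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(gi)) {
      m <- as.matrix(gi[, setdiff(names(gi), "sample"), drop = FALSE])
      rownames(m) <- gi$sample
      out$gi50 <- m
    }
  }
  sp <- file.path(dir, "subtypes.csv")
  if (file.exists(sp)) {
    st <- utils::read.csv(sp, stringsAsFactors = FALSE)
    if (nrow(st)) out$subtypes <- stats::setNames(st$subtype, st$sample)
  }
  cp <- file.path(dir, "clinical.csv")
  if (file.exists(cp)) {
    cl <- utils::read.csv(cp, stringsAsFactors = FALSE)
    if (nrow(cl)) out$clinical <- cl
  }
  out
}
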