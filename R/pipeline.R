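#' Build and validate a pipeline run configuration
#'
#' @param network path to the edge-list file.
#' @param maf path to the MAF mutation file.
#' @param gistic path to the GISTIC thresholded-by-genes file (optional).
#' @param seeds path to the seed oncogene list (one symbol per line).
#' @param nodes optional node-list path (isolated network nodes).
#' @param gi50,subtypes,clinical optional phenotype table paths (CSV).
#' @param alpha significance level in (0, 1].
#' @param mode `"exact"` or `"perm"`.
#' @param n_perm permutations (perm mode, >= 100).
#' @param min_connections seed-expansion threshold.
#' @param amp_threshold,del_threshold GISTIC call thresholds.
#' @param exclude_classes MAF variant classes to drop.
#' @param seed RNG seed recorded in the manifest.
#' @param out_dir output directory.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(network, maf, gistic = NULL, seeds,
                       nodes = NULL, gi50 = NULL, subtypes = NULL,
                       clinical = NULL, alpha = 0.05,
                       mode = c("exact", "perm"), n_perm = 10000,
                       min_connections = 2, amp_threshold = 2,
                       del_threshold = -2, exclude_classes = "Silent",
                       seed = 1, out_dir) {
  mode <- match.arg(mode)
  cfg <- list(network = network, maf = maf, gistic = gistic, seeds = seeds,
              nodes = nodes, gi50 = gi50, subtypes = subtypes,
              clinical = clinical, alpha = alpha, mode = mode,
              n_perm = n_perm, min_connections = min_connections,
              amp_threshold = amp_threshold, del_threshold = del_threshold,
              exclude_classes = exclude_classes, seed = seed,
              out_dir = out_dir)
  required <- c("network", "maf", "seeds")
  for (nm in c(required, "gistic", "nodes", "gi50", "subtypes", "clinical")) {
    p <- cfg[[nm]]
    if (is.null(p)) {
      if (nm %in% required) stop("config is missing required path: ", nm)
      next
    }
    if (!file.exists(p))
      stop(sprintf("config path '%s' does not exist: %s", nm, p))
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (mode == "perm" && n_perm < 100)
    stop("n_perm must be >= 100 in perm mode")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; values passed in `...`
#' override the file.
#'
#' @param path YAML file path.
#' @param ... overrides (e.g. `out_dir = "results"`).
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full surrogate-oncogene pipeline
#'
#' Orchestrates: load network -> parse MAF/GISTIC -> build profiles ->
#' expand seed set -> call surrogates -> optional association stages
#' (drug sensitivity, subtype, survival tree). Writes all output tables
#' plus a `manifest.json` recording the configuration, seed, package
#' version and input checksums; reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param config a `run_config` (or a YAML path accepted by
#'   [load_run_config()]).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the fitted `surrogate_calls` object, any
#'   association results, and the output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  say <- function(...) if (!quiet) message(...)

  say("stage: network")
  net <- .stage("network", load_network(config$network,
                                        node_path = config$nodes,
                                        quiet = quiet))
  say("stage: profiles")
  maf <- .stage("maf", read_maf(config$maf,
                                exclude_classes = config$exclude_classes,
                                quiet = quiet))
  cn <- if (!is.null(config$gistic))
    .stage("gistic", read_gistic(config$gistic,
                                 amp_threshold = config$amp_threshold,
                                 del_threshold = config$del_threshold))
  else NULL
  profiles <- .stage("profiles", build_profiles(maf, cn, net, quiet = quiet))
  say("stage: seed expansion")
  seed_genes <- readLines(config$seeds, warn = FALSE)
  seed_genes <- seed_genes[nzchar(trimws(seed_genes))]
  gene_set <- .stage("expand_seed_set",
                     expand_seed_set(net, seed_genes,
                                     min_connections = config$min_connections))
  say("stage: surrogate calls")
  fit <- .stage("call_surrogates",
                call_surrogates(net, gene_set, profiles,
                                alpha = config$alpha, mode = config$mode,
                                n_perm = config$n_perm, seed = config$seed))
  outputs <- c(calls = file.path(out_dir, "calls.csv"),
               matrix = file.path(out_dir, "matrix.csv"))
  write_surrogate_calls(fit, outputs[["calls"]], outputs[["matrix"]])
  results <- list(fit = fit)

  if (!is.null(config$gi50)) {
    say("stage: drug sensitivity")
    gi <- utils::read.csv(config$gi50, check.names = FALSE,
                          stringsAsFactors = FALSE)
    feats <- surrogate_features(fit)
    rep <- .stage("drug_sensitivity",
                  drug_sensitivity_report(feats, gi, seed = config$seed))
    outputs[["drug_report"]] <- file.path(out_dir, "drug_report.csv")
    utils::write.csv(rep$report, outputs[["drug_report"]],
                     row.names = FALSE)
    results$drug <- rep
  }
  if (!is.null(config$subtypes)) {
    say("stage: subtype association")
    st <- utils::read.csv(config$subtypes, stringsAsFactors = FALSE)
    assoc <- .stage("subtype_association", subtype_association(fit, st))
    outputs[["subtype_association"]] <- file.path(out_dir,
                                                  "subtype_association.csv")
    utils::write.csv(assoc, outputs[["subtype_association"]],
                     row.names = FALSE)
    results$subtype <- assoc
  }
  if (!is.null(config$clinical)) {
    say("stage: survival")
    cl <- utils::read.csv(config$clinical, stringsAsFactors = FALSE)
    feats <- (fit$matrix == 1L | fit$matrix == 3L) + 0
    common <- intersect(rownames(feats), cl$sample)
    cl <- cl[match(common, cl$sample), ]
    tree <- .stage("survival_tree", {
      keep <- colSums(feats[common, , drop = FALSE]) > 0
      fit_survival_tree(feats[common, keep, drop = FALSE],
                        cl$time, cl$event)
    })
    outputs[["survival_tree"]] <- file.path(out_dir, "survival_tree.txt")
    txt <- c(format_survival_tree(tree),
             if (!is.null(tree$logrank))
               sprintf("logrank chisq=%.6g df=%d p=%.6g",
                       tree$logrank$statistic, tree$logrank$df,
                       tree$logrank$p_value))
    writeLines(txt, outputs[["survival_tree"]])
    outputs[["survival_groups"]] <- file.path(out_dir,
                                              "survival_groups.csv")
    utils::write.csv(data.frame(sample = names(tree$groups),
                                group = as.character(tree$groups)),
                     outputs[["survival_groups"]], row.names = FALSE)
    results$survival <- tree
  }

  say("stage: manifest")
  input_paths <- Filter(Negate(is.null),
                        config[c("network", "nodes", "maf", "gistic",
                                 "seeds", "gi50", "subtypes", "clinical")])
  manifest <- list(
    package = "oncosurrogate",
    version = as.character(utils::packageVersion("oncosurrogate")),
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    input_checksums = as.list(tools::md5sum(unlist(input_paths))),
    outputs = basename(unname(outputs)))
  outputs[["manifest"]] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  results$outputs <- outputs
  invisible(results)
}
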