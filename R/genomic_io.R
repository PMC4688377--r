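#' Read somatic mutations from a MAF file
#'
#' Parses a tab-delimited Mutation Annotation Format table into per-sample
#' sets of mutated gene symbols. Only the `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` columns are consumed;
#' lines starting with `#` are skipped. Rows whose variant classification is
#' in `exclude_classes` (silent variants by default) are dropped, but their
#' samples are retained with empty mutation sets.
#'
#' @param path path to the MAF file.
#' @param exclude_classes variant classifications to drop (default `"Silent"`).
#' @param quiet suppress the kept/dropped row count message.
#' @return Named list mapping sample barcode to a sorted character vector of
#'   distinct mutated gene symbols (uppercased).
#' @export
read_maf <- function(path, exclude_classes = "Silent", quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read MAF file: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_col <- setdiff(req, names(df))
  if (length(missing_col))
    stop("MAF file is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  keep <- !(df$Variant_Classification %in% exclude_classes)
  if (!quiet)
    message(sprintf("read_maf: kept %d of %d rows (%d excluded by class)",
                    sum(keep), nrow(df), sum(!keep)))
  samples <- sort(unique(df$Tumor_Sample_Barcode))
  kept <- df[keep, , drop = FALSE]
  sets <- lapply(stats::setNames(samples, samples), function(s) {
    sort(unique(toupper(trimws(
      kept$Hugo_Symbol[kept$Tumor_Sample_Barcode == s]))))
  })
  sets
}

# Columns of a thresholded-by-genes matrix that annotate genes, not samples.
.gistic_annot_cols <- c("Locus ID", "Locus.ID", "Cytoband", "Gene ID",
                        "Gene.ID")
.gistic_gene_cols <- c("Gene Symbol", "Gene.Symbol", "Gene_Symbol",
                       "Hugo_Symbol")

#' Read copy-number calls from a GISTIC thresholded-by-genes matrix
#'
#' Consumes the `all_thresholded.by_genes` dialect: rows are genes, columns
#' are samples, entries are integer calls in \{-2, -1, 0, 1, 2\}. A gene
#' symbol column (`Gene Symbol` or similar) is required; standard annotation
#' columns (`Locus ID`, `Cytoband`) are ignored.
#'
#' @param path path to the tab-delimited matrix.
#' @param amp_threshold a gene is called gained in a sample when its call is
#'   `>= amp_threshold` (default 2, high-level amplification).
#' @param del_threshold a gene is called lost when its call is
#'   `<= del_threshold` (default -2, deep deletion).
#' @param gene_filter optional character vector restricting calls to a gene
#'   list (e.g. genes in high-confidence amplification/deletion peaks).
#' @return List with named lists `gained` and `lost`, each mapping sample to
#'   a sorted character vector of gene symbols.
#' @export
read_gistic <- function(path, amp_threshold = 2, del_threshold = -2,
                        gene_filter = NULL) {
  if (!file.exists(path)) stop("cannot read GISTIC file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gcol <- intersect(.gistic_gene_cols, names(df))
  if (!length(gcol))
    stop("GISTIC file is missing a gene symbol column (expected one of: ",
         paste(.gistic_gene_cols, collapse = ", "), ")")
  genes <- toupper(trimws(as.character(df[[gcol[1L]]])))
  sample_cols <- setdiff(names(df), c(gcol, .gistic_annot_cols))
  if (!length(sample_cols))
    stop("GISTIC file has no sample columns")
  calls <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_cols),
                  dimnames = list(NULL, sample_cols))
  for (s in sample_cols) {
    v <- df[[s]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) & !all(is.na(v))) {
        bad <- which(is.na(vn) & !is.na(v))[1L]
        stop(sprintf("non-numeric copy-number call at row %d, column '%s': '%s'",
                     bad, s, v[bad]))
      }
      v <- vn
    }
    calls[, s] <- v
  }
  if (!is.null(gene_filter)) {
    keep <- genes %in% toupper(trimws(gene_filter))
    genes <- genes[keep]
    calls <- calls[keep, , drop = FALSE]
  }
  out <- list(gained = list(), lost = list())
  for (s in sample_cols) {
    out$gained[[s]] <- sort(unique(genes[!is.na(calls[, s]) &
                                           calls[, s] >= amp_threshold]))
    out$lost[[s]] <- sort(unique(genes[!is.na(calls[, s]) &
                                         calls[, s] <= del_threshold]))
  }
  out
}

#' Build per-sample alteration profiles on a network
#'
#' Merges per-sample mutation sets and copy-number gain/loss sets, restricts
#' every set to the nodes of the active PPI network, and derives the pooled
#' altered set whose size `M` parameterises the permutation null. A sample
#' present in only one source gets empty sets for the other; a gene may be
#' both mutated and copy-altered but counts once in `altered`.
#'
#' @param maf_sets named list sample -> mutated genes, as from [read_maf()].
#' @param cn_sets list with `gained` and `lost` named lists, as from
#'   [read_gistic()]; may be `NULL`.
#' @param net a [ppi_network].
#' @param quiet suppress the off-network gene count message.
#' @return Named list (sorted by sample id) of `alteration_profile` objects:
#'   lists with `sample_id`, `mutated`, `gained`, `lost`, `altered`, `M`.
#' @export
build_profiles <- function(maf_sets, cn_sets = NULL, net, quiet = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(cn_sets)) cn_sets <- list(gained = list(), lost = list())
  samples <- sort(unique(c(names(maf_sets), names(cn_sets$gained),
                           names(cn_sets$lost))))
  n_dropped <- 0L
  profs <- lapply(stats::setNames(samples, samples), function(s) {
    mut <- toupper(if (is.null(maf_sets[[s]])) character(0) else maf_sets[[s]])
    gai <- toupper(if (is.null(cn_sets$gained[[s]])) character(0) else cn_sets$gained[[s]])
    los <- toupper(if (is.null(cn_sets$lost[[s]])) character(0) else cn_sets$lost[[s]])
    raw <- unique(c(mut, gai, los))
    on_net <- raw %in% net$nodes
    n_dropped <<- n_dropped + sum(!on_net)
    mut <- sort(unique(mut[mut %in% net$nodes]))
    gai <- sort(unique(gai[gai %in% net$nodes]))
    los <- sort(unique(los[los %in% net$nodes]))
    altered <- sort(unique(c(mut, gai, los)))
    structure(list(sample_id = s, mutated = mut, gained = gai, lost = los,
                   altered = altered, M = length(altered)),
              class = "alteration_profile")
  })
  if (!quiet && n_dropped > 0L)
    message(sprintf("build_profiles: dropped %d gene call(s) absent from the network",
                    n_dropped))
  profs
}

#' @export
print.alteration_profile <- function(x, ...) {
  cat(sprintf("alteration_profile %s: M = %d altered genes (%d mutated, %d gained, %d lost)\n",
              x$sample_id, x$M, length(x$mutated), length(x$gained),
              length(x$lost)))
  invisible(x)
}

#' Write per-sample alteration profiles to a long-format CSV
#'
#' One row per (sample, gene, alteration type).
#'
#' @param profiles list of profiles from [build_profiles()].
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_profile_summary <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      sample = p$sample_id,
      gene = c(p$mutated, p$gained, p$lost),
      type = rep(c("mutation", "gain", "loss"),
                 c(length(p$mutated), length(p$gained), length(p$lost))),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(sample = character(0), gene = character(0),
                       type = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
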