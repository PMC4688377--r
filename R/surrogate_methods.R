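#' @export
print.surrogate_calls <- function(x, ...) {
  n_sig <- sum(x$calls$significant)
  per_sample <- rowSums(x$matrix == 1L | x$matrix == 3L)
  cat("Surrogate oncogene calls\n")
  cat(sprintf("  %d samples x %d genes tested (%s mode%s), alpha = %g\n",
              length(x$samples), length(x$genes), x$mode,
              if (x$mode == "perm") sprintf(", %d permutations", x$n_perm)
              else "", x$alpha))
  cat(sprintf("  %d significant calls; mean %.2f surrogates per sample (range %d-%d)\n",
              n_sig, mean(per_sample), min(per_sample), max(per_sample)))
  if (x$mode == "perm" && !x$add_one && any(x$calls$p_value == 0))
    cat(sprintf("  %d call(s) with p = 0 should be read as p < %g\n",
                sum(x$calls$p_value == 0), 1 / x$n_perm))
  invisible(x)
}

#' Summarise surrogate calls per sample and per gene
#'
#' @param object a `surrogate_calls` object.
#' @param ... unused.
#' @return Object of class `summary.surrogate_calls` with per-sample
#'   significant-surrogate counts and per-gene prevalence across samples.
#' @export
summary.surrogate_calls <- function(object, ...) {
  sig <- object$matrix == 1L | object$matrix == 3L
  per_sample <- data.frame(sample = rownames(object$matrix),
                           n_surrogates = rowSums(sig),
                           M = object$calls$M[match(rownames(object$matrix),
                                                    object$calls$sample)],
                           row.names = NULL, stringsAsFactors = FALSE)
  deg <- vapply(object$genes, function(g)
    length(object$net$adjacency[[g]]), 1L)
  per_gene <- data.frame(gene = colnames(object$matrix),
                         degree = unname(deg),
                         n_samples_significant = colSums(sig),
                         prevalence = colMeans(sig),
                         row.names = NULL, stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$n_samples_significant,
                             per_gene$gene), ]
  structure(list(per_sample = per_sample, per_gene = per_gene,
                 alpha = object$alpha), class = "summary.surrogate_calls")
}

#' @export
print.summary.surrogate_calls <- function(x, n = 10, ...) {
  cat(sprintf("Per-sample significant surrogates (alpha = %g):\n", x$alpha))
  print(utils::head(x$per_sample, n), row.names = FALSE)
  cat("\nMost prevalent surrogate oncogenes:\n")
  print(utils::head(x$per_gene, n), row.names = FALSE)
  invisible(x)
}

#' Heatmap of surrogate states across the cohort
#'
#' Renders the sample x gene state matrix: light blue = significant
#' surrogate only, pink = gene altered only, purple = both, white = neither.
#'
#' @param x a `surrogate_calls` object.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.surrogate_calls <- function(x, ...) {
  m <- x$matrix
  keep <- colSums(m > 0L) > 0L
  if (any(keep)) m <- m[, keep, drop = FALSE]
  cols <- c("white", "lightblue", "pink", "purple")
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = cols, zlim = c(0, 3), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  graphics::title("Surrogate oncogene states")
  invisible(x)
}

#' @export
as.data.frame.surrogate_calls <- function(x, ...) x$calls

#' @export
as.matrix.surrogate_calls <- function(x, ...) x$matrix

#' Write surrogate call outputs to CSV
#'
#' @param fit a `surrogate_calls` object.
#' @param calls_path path for the long calls table.
#' @param matrix_path optional path for the coded state matrix.
#' @return Invisibly, `fit`.
#' @export
write_surrogate_calls <- function(fit, calls_path, matrix_path = NULL) {
  stopifnot(inherits(fit, "surrogate_calls"))
  utils::write.csv(fit$calls, calls_path, row.names = FALSE)
  if (!is.null(matrix_path)) {
    m <- data.frame(sample = rownames(fit$matrix), fit$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(m, matrix_path, row.names = FALSE)
  }
  invisible(fit)
}

#' Read a coded surrogate state matrix written by [write_surrogate_calls()]
#'
#' @param path CSV path with a `sample` column and one coded 0-3 column per
#'   gene.
#' @return Integer sample x gene matrix.
#' @export
read_surrogate_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("matrix CSV must have a 'sample' column")
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}
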