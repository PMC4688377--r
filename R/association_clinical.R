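#' Fisher tests of surrogate association with molecular subtype
#'
#' For each surrogate-set gene significant in at least one sample, tests the
#' association between significant-surrogate status and each subtype
#' (one-vs-rest) with a two-sided Fisher exact test on the 2x2 table
#' \{surrogate, no surrogate\} x \{in subtype, other subtypes\}.
#'
#' @param fit a `surrogate_calls` object, or a coded sample x gene state
#'   matrix (see [surrogate_matrix()]).
#' @param subtypes named character vector or single-column data frame
#'   mapping sample to subtype label; samples missing a label are dropped.
#' @return Data frame with columns `gene`, `subtype`, `p_value`,
#'   `odds_ratio` (conditional MLE from the exact test) and `direction`
#'   (`enriched`/`depleted`/`none`).
#' @export
subtype_association <- function(fit, subtypes) {
  m <- if (inherits(fit, "surrogate_calls")) fit$matrix else fit
  if (is.data.frame(subtypes)) {
    if (!all(c("sample", "subtype") %in% names(subtypes)))
      stop("subtype data frame needs 'sample' and 'subtype' columns")
    subtypes <- stats::setNames(as.character(subtypes$subtype),
                                subtypes$sample)
  }
  common <- intersect(rownames(m), names(subtypes)[!is.na(subtypes)])
  if (length(common) < 2L) stop("too few samples with subtype labels")
  m <- m[common, , drop = FALSE]
  lab <- subtypes[common]
  levs <- sort(unique(lab))
  if (length(levs) < 2L) stop("need at least 2 distinct subtype labels")
  sig <- m == 1L | m == 3L
  genes <- colnames(m)[colSums(sig) > 0L]
  rows <- list()
  for (g in genes) {
    for (st in levs) {
      tab <- table(factor(sig[, g], levels = c(TRUE, FALSE)),
                   factor(lab == st, levels = c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      orr <- unname(ft$estimate)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, subtype = st, p_value = ft$p.value, odds_ratio = orr,
        direction = if (is.na(orr) || orr == 1) "none"
        else if (orr > 1) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), subtype = character(0),
                      p_value = numeric(0), odds_ratio = numeric(0),
                      direction = character(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square comparing survival across groups, with
#' `k - 1` degrees of freedom.
#'
#' @param groups vector (or factor) of group labels, one per subject.
#' @param time nonnegative follow-up times.
#' @param event event indicator, 1 = event, 0 = censored.
#' @return Object of class `logrank_test`: list with `statistic`, `df`,
#'   `p_value` and the per-group observed/expected event counts.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd$n) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = sd$n, observed = sd$obs, expected = sd$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# Two-sample log-rank chi-square for a candidate split, NA when not
# computable (e.g. no events in the node).
.split_stat <- function(time, event, side) {
  if (length(unique(side)) < 2L || sum(event) < 1) return(NA_real_)
  out <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ side)$chisq,
    error = function(e) NA_real_)
  out
}

#' Fit a survival tree over binary genomic features
#'
#' Greedy recursive binary partitioning: at each step, among all current
#' leaves and all binary features, the split (feature present vs absent)
#' with the largest two-sample log-rank statistic is applied, provided both
#' children keep at least `min_leaf` subjects and the statistic reaches
#' `split_threshold` (default 3.84, the 0.05 critical value of chi-square
#' with 1 df — the complexity criterion). Growth stops at `max_leaves`
#' terminal groups.
#'
#' @param features sample x feature binary (0/1) matrix or data frame; row
#'   names are sample ids.
#' @param time,event survival outcome, one entry per row of `features`.
#' @param max_leaves maximum number of terminal groups (default 4).
#' @param min_leaf minimum subjects per leaf (default 10).
#' @param split_threshold minimum log-rank chi-square for a split.
#' @return Object of class `survival_tree`: tree node list, per-sample
#'   group factor, features used, overall [logrank_test()] across the
#'   groups (NULL for a single-leaf tree), and the outcome data. A tree
#'   with no admissible root split is returned as a single leaf with a
#'   warning.
#' @export
fit_survival_tree <- function(features, time, event, max_leaves = 4,
                              min_leaf = 10, split_threshold = 3.84) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("s", seq_len(nrow(features)))
  if (!all(features %in% c(0, 1)))
    stop("features must be binary 0/1")
  n <- nrow(features)
  if (length(time) != n || length(event) != n)
    stop("time/event length must match the feature rows")
  if (n < 2 * min_leaf) stop("too few samples for the requested min_leaf")
  # nodes: list of lists(id, idx, feature, left, right); leaf <=> feature NA
  nodes <- list(list(id = 1L, idx = seq_len(n), feature = NA_character_,
                     left = NA_integer_, right = NA_integer_))
  leaf_ids <- function() {
    ids <- vapply(nodes, `[[`, 1L, "id")
    ids[vapply(nodes, function(nd) is.na(nd$feature), TRUE)]
  }
  feats <- colnames(features)
  if (is.null(feats)) feats <- colnames(features) <- paste0("f", seq_len(ncol(features)))
  repeat {
    leaves <- leaf_ids()
    if (length(leaves) >= max_leaves) break
    best <- list(stat = -Inf)
    for (lid in leaves) {
      nd <- nodes[[lid]]
      for (f in feats) {
        side <- features[nd$idx, f]
        if (min(sum(side == 1), sum(side == 0)) < min_leaf) next
        st <- .split_stat(time[nd$idx], event[nd$idx], side)
        if (!is.na(st) && st > best$stat)
          best <- list(stat = st, leaf = lid, feature = f)
      }
    }
    if (!is.finite(best$stat) || best$stat < split_threshold) break
    nd <- nodes[[best$leaf]]
    side <- features[nd$idx, best$feature]
    left_id <- length(nodes) + 1L   # feature absent
    right_id <- length(nodes) + 2L  # feature present
    nodes[[left_id]] <- list(id = left_id, idx = nd$idx[side == 0],
                             feature = NA_character_, left = NA_integer_,
                             right = NA_integer_)
    nodes[[right_id]] <- list(id = right_id, idx = nd$idx[side == 1],
                              feature = NA_character_, left = NA_integer_,
                              right = NA_integer_)
    nodes[[best$leaf]]$feature <- best$feature
    nodes[[best$leaf]]$left <- left_id
    nodes[[best$leaf]]$right <- right_id
    nodes[[best$leaf]]$stat <- best$stat
  }
  leaves <- leaf_ids()
  if (length(leaves) == 1L)
    warning("no admissible split at the root; returning a single-leaf tree")
  group <- integer(n)
  for (i in seq_along(leaves)) group[nodes[[leaves[i]]]$idx] <- i
  group <- factor(group, labels = paste0("group", seq_along(leaves)))
  names(group) <- rownames(features)
  overall <- if (nlevels(group) >= 2L && sum(event) >= 1)
    logrank_test(group, time, event) else NULL
  structure(list(nodes = nodes, groups = group,
                 features_used = unique(stats::na.omit(
                   vapply(nodes, `[[`, "", "feature"))),
                 logrank = overall, max_leaves = max_leaves,
                 min_leaf = min_leaf, split_threshold = split_threshold,
                 time = time, event = event),
            class = "survival_tree")
}

# Bracket-text rendering of one node.
.render_node <- function(tree, id, group_of_leaf) {
  nd <- tree$nodes[[id]]
  if (is.na(nd$feature))
    return(sprintf("%s(n=%d)", group_of_leaf[[as.character(id)]],
                   length(nd$idx)))
  sprintf("[%s-: %s | %s+: %s]",
          nd$feature, .render_node(tree, nd$left, group_of_leaf),
          nd$feature, .render_node(tree, nd$right, group_of_leaf))
}

#' Bracket-text rendering of a survival tree
#'
#' @param tree a `survival_tree`.
#' @return Single character string, e.g.
#'   `"[A-: group1(n=50) | A+: [B-: group2(n=30) | B+: group3(n=20)]]"`.
#' @export
format_survival_tree <- function(tree) {
  stopifnot(inherits(tree, "survival_tree"))
  leaves <- vapply(tree$nodes, function(nd) is.na(nd$feature), TRUE)
  ids <- vapply(tree$nodes, `[[`, 1L, "id")[leaves]
  group_of_leaf <- stats::setNames(as.list(levels(tree$groups)),
                                   as.character(ids))
  .render_node(tree, 1L, group_of_leaf)
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("Survival tree (greedy log-rank partitioning)\n")
  cat("  ", format_survival_tree(x), "\n", sep = "")
  cat(sprintf("  %d group(s), min_leaf = %d, split threshold chi-square >= %g\n",
              nlevels(x$groups), x$min_leaf, x$split_threshold))
  if (!is.null(x$logrank))
    cat(sprintf("  overall log-rank: chi-square = %.4g on %d df, p = %.4g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}

#' @export
predict.survival_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  leaves <- which(vapply(object$nodes, function(nd) is.na(nd$feature), TRUE))
  leaf_group <- stats::setNames(levels(object$groups),
                                as.character(leaves))
  assign_one <- function(row) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (is.na(nd$feature)) return(leaf_group[[as.character(id)]])
      id <- if (row[[nd$feature]] == 0) nd$left else nd$right
    }
  }
  factor(apply(newdata, 1, assign_one), levels = levels(object$groups))
}

#' Kaplan-Meier curves of the survival-tree groups
#'
#' @param x a `survival_tree`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [survival::survfit] object.
#' @export
plot.survival_tree <- function(x, ...) {
  sf <- survival::survfit(survival::Surv(x$time, x$event) ~ x$groups)
  cols <- grDevices::hcl.colors(nlevels(x$groups), "Dark 3")
  graphics::plot(sf, col = cols, xlab = "time", ylab = "survival", ...)
  graphics::legend("topright", legend = levels(x$groups), col = cols,
                   lty = 1, bty = "n")
  invisible(sf)
}
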