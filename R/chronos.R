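# Standardized divergence-time comparison between two sets of posterior
# node-age estimates.

#' Standardize divergence times against a reference posterior
#'
#' For node `i` with reference posterior mean `x_i` and 95% interval
#' `(lower_i, upper_i)` of half-width `d_i = (upper_i - lower_i) / 2`, the
#' comparison mean `y_i` is standardized as `y*_i = (y_i - x_i) / d_i`.
#' `|y*_i| > 1` (strictly) flags the comparison estimate as falling outside
#' the reference 95% posterior interval.
#'
#' @param reference `data.frame` with columns `label`, `mean`, `lower`,
#'   `upper` (posterior mean and 95% interval per node).
#' @param comparison `data.frame` with columns `label`, `mean`; labels must
#'   all occur in `reference`.
#' @return `data.frame` of class `"time_standardization"` with columns
#'   `label`, `x`, `d`, `y`, `ystar`, `flagged`; summary fractions
#'   (`frac_flagged`, `frac_below`, `frac_above`) as attributes. Rows with
#'   a degenerate reference interval (`upper == lower`) are dropped with a
#'   warning.
#' @examples
#' ref <- data.frame(label = "n1", mean = 100, lower = 90, upper = 110)
#' cmp <- data.frame(label = "n1", mean = 85)
#' standardize_times(ref, cmp)$ystar  # -1.5, flagged below
#' @export
standardize_times <- function(reference, comparison) {
  need_ref <- c("label", "mean", "lower", "upper")
  if (!all(need_ref %in% names(reference)))
    stop("reference needs columns: ", paste(need_ref, collapse = ", "))
  if (!all(c("label", "mean") %in% names(comparison)))
    stop("comparison needs columns: label, mean")
  missing <- setdiff(comparison$label, reference$label)
  if (length(missing))
    stop("comparison label(s) missing from reference: ",
         paste(missing, collapse = ", "))
  if (any(reference$upper < reference$lower))
    stop("reference has upper < lower")
  idx <- match(comparison$label, reference$label)
  x <- reference$mean[idx]
  d <- (reference$upper[idx] - reference$lower[idx]) / 2
  y <- comparison$mean
  keep <- d > 0
  if (any(!keep))
    warning("dropping ", sum(!keep), " row(s) with degenerate reference ",
            "interval: ", paste(comparison$label[!keep], collapse = ", "))
  out <- data.frame(label = comparison$label[keep], x = x[keep], d = d[keep],
                    y = y[keep], stringsAsFactors = FALSE)
  out$ystar <- (out$y - out$x) / out$d
  out$flagged <- abs(out$ystar) > 1
  attr(out, "frac_flagged") <- mean(out$flagged)
  attr(out, "frac_below") <- mean(out$ystar < -1)
  attr(out, "frac_above") <- mean(out$ystar > 1)
  class(out) <- c("time_standardization", "data.frame")
  out
}

#' @export
print.time_standardization <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("flagged |y*| > 1: %.1f%% (%.1f%% below -1, %.1f%% above 1)\n",
              100 * attr(x, "frac_flagged"), 100 * attr(x, "frac_below"),
              100 * attr(x, "frac_above")))
  invisible(x)
}

#' Node ages of a chronogram keyed by clade signature
#'
#' Derives a label-matched age table from an ultrametric tree: each
#' internal node is keyed by the sorted, `";"`-joined labels of its
#' descendant leaves, so two chronograms with identical leaf sets can be
#' matched node-by-node regardless of topology-internal numbering.
#'
#' @param tree An ultrametric `"phylo"` tree with branch lengths in time
#'   units.
#' @return `data.frame` with columns `label` (clade signature) and `mean`
#'   (node age), suitable as a [standardize_times()] `comparison` table.
#' @export
clade_time_table <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  nt <- length(tree$tip.label)
  data.frame(
    label = vapply(seq_along(parts),
                   function(i) paste(sort(labs[parts[[i]]]), collapse = ";"),
                   character(1)),
    mean = ages[nt + seq_along(parts)],
    stringsAsFactors = FALSE)
}
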