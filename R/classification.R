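#' Cluster genotypes into tolerance classes by D value
#'
#' Agglomerative hierarchical clustering of the comprehensive D scores,
#' using between-groups average linkage on squared Euclidean distances
#' (the convention of the major commercial statistics packages). For
#' display and cutting, merge heights are mapped back to the Euclidean
#' (root) scale and rescaled linearly so the final merge sits at 25,
#' the conventional 0-25 dendrogram axis. The default cut at 8 on that
#' axis separates a ten-strain screen into non-, low- and high-tolerant
#' classes.
#'
#' Classes are named by ascending mean D (non-tolerant first). Genotype
#' input order does not affect the result: genotypes are ordered by
#' label before clustering, and merge-height ties resolve by the
#' smallest label.
#'
#' @param d numeric D scores, named by genotype (or a `d_scores` frame
#'   from the evaluation stage).
#' @param k desired number of classes; give either `k` or `cut_height`.
#' @param cut_height cut on the 0-25 rescaled dendrogram axis
#'   (default 8 when neither argument is given).
#' @param linkage `"average"` (default), `"ward"` or `"complete"`.
#' @return list of class `tolerance_classing`: `genotypes`, `d`,
#'   `label` (integer class per genotype, 1 = lowest mean D),
#'   `class_names`, `merge_tree` (the `hclust` object on the squared
#'   metric), `rescaled_heights`, `k`.
#' @examples
#' d <- c(JaCg205 = 0.935, ChCg77 = 0.871, ChCg57 = 0.487,
#'        JaCg32 = 0.351, JaCg151 = 0.228, JaCg49 = 0.004,
#'        JaCg41 = 0, JaCg45 = 0, JaCg57 = 0, JaCg144 = 0)
#' cls <- cluster_tolerance(d)
#' @export
cluster_tolerance <- function(d, k = NULL, cut_height = NULL,
                              linkage = c("average", "ward", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "d_scores") || (is.data.frame(d) && all(c("genotype", "d") %in% names(d)))) {
    dv <- d$d
    names(dv) <- d$genotype
    d <- dv
  }
  d <- as.numeric(d) |> stats::setNames(names(d))
  n <- length(d)
  if (n < 2) stop("need at least 2 genotypes to cluster", call. = FALSE)
  if (is.null(names(d))) names(d) <- paste0("G", seq_len(n))
  if (!is.null(k) && !is.null(cut_height)) {
    stop("give either k or cut_height, not both", call. = FALSE)
  }
  if (is.null(k) && is.null(cut_height)) cut_height <- 8
  if (!is.null(k)) {
    if (k > n) stop("k exceeds the number of genotypes", call. = FALSE)
    if (k > 1 && length(unique(d)) == 1) {
      stop("all D values equal; cannot form more than one class",
           call. = FALSE)
    }
  }

  # label order fixes tie-breaking and makes input order irrelevant
  ord <- order(names(d))
  ds <- d[ord]
  method <- c(average = "average", ward = "ward.D", complete = "complete")[linkage]
  hc <- stats::hclust(stats::dist(ds)^2, method = method)

  h_root <- sqrt(pmax(hc$height, 0))
  top <- max(h_root)
  rescaled <- if (top > 0) h_root * 25 / top else h_root

  if (!is.null(k)) {
    memb <- stats::cutree(hc, k = k)
  } else {
    if (top == 0) {
      memb <- stats::setNames(rep(1L, n), names(ds))
    } else {
      memb <- stats::cutree(hc, h = (cut_height * top / 25)^2)
    }
  }
  k_eff <- length(unique(memb))

  # relabel classes by ascending mean D
  mean_d <- tapply(ds, memb, mean)
  remap <- stats::setNames(rank(mean_d, ties.method = "first"),
                           names(mean_d))
  label_sorted <- as.integer(remap[as.character(memb)])
  names(label_sorted) <- names(memb)

  class_names <- if (k_eff == 1) "single-class"
  else if (k_eff == 2) c("non-tolerant", "high-tolerant")
  else if (k_eff == 3) c("non-tolerant", "low-tolerant", "high-tolerant")
  else paste0("class-", seq_len(k_eff))

  # report in original input order
  label <- label_sorted[names(d)]
  out <- list(genotypes = names(d), d = unname(d), label = unname(label),
              class_names = class_names, merge_tree = hc,
              rescaled_heights = rescaled, k = k_eff)
  class(out) <- "tolerance_classing"
  out
}

#' Export a tolerance dendrogram as a Newick string
#'
#' Branch lengths come from the rescaled 0-25 dendrogram heights, so the
#' tree can be inspected in any phylogenetics viewer.
#'
#' @param classing a `tolerance_classing` from [cluster_tolerance()].
#' @param path optional file to write; omit to get the string only.
#' @return the Newick string, invisibly if written to a file.
#' @export
dendrogram_newick <- function(classing, path = NULL) {
  stopifnot(inherits(classing, "tolerance_classing"))
  hc <- classing$merge_tree
  hc$height <- classing$rescaled_heights
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' @export
print.tolerance_classing <- function(x, ...) {
  cat(sprintf("Tolerance classing: %d genotypes in %d class(es)\n",
              length(x$genotypes), x$k))
  for (cl in seq_len(x$k)) {
    members <- x$genotypes[x$label == cl]
    cat(sprintf("  %s (mean D = %.3f): %s\n", x$class_names[cl],
                mean(x$d[x$label == cl]), paste(members, collapse = ", ")))
  }
  invisible(x)
}
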