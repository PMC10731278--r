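#' Column-wise membership functions (min-max normalization)
#'
#' For each column (indicator or comprehensive index), the membership
#' value of genotype i is
#' \deqn{U_i = (X_i - X_{min}) / (X_{max} - X_{min})}
#' so the weakest genotype of a column scores 0, the strongest scores 1,
#' and every entry lies in \[0, 1\]. Membership is invariant under
#' positive affine transforms of a column.
#'
#' @param x numeric matrix, genotypes in rows.
#' @param degenerate policy for a constant column (max = min), where the
#'   membership is undefined: `"error"` (default) or `"drop"` the column
#'   with a warning. Silently mapping a constant column to 0.5 would
#'   distort the D score, so it is never done.
#' @return membership matrix of the same shape (minus dropped columns),
#'   entries in \[0, 1\].
#' @examples
#' membership_values(cbind(F1 = c(2.759, 2.318, -2.722, -2.355)))
#' @export
membership_values <- function(x, degenerate = c("error", "drop")) {
  degenerate <- match.arg(degenerate)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("membership needs at least 2 genotypes", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in membership input",
                               call. = FALSE)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat)) {
    nm <- colnames(x)[flat] %||% paste0("column ", which(flat))
    if (degenerate == "error") {
      stop("constant column(s), membership undefined: ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    warning("dropping constant column(s): ", paste(nm, collapse = ", "),
            call. = FALSE)
    x <- x[, !flat, drop = FALSE]
    rng <- rng[, !flat, drop = FALSE]
    span <- span[!flat]
    if (ncol(x) == 0) stop("all columns constant; nothing to evaluate",
                           call. = FALSE)
  }
  u <- sweep(sweep(x, 2, rng[1, ], "-"), 2, span, "/")
  u
}

#' Standardize indicator columns
#'
#' Centers each column to mean 0 and scales to unit (n-1) standard
#' deviation, the preprocessing applied to the resistance-coefficient
#' matrix before principal component analysis.
#'
#' @param x numeric matrix, genotypes in rows.
#' @return standardized matrix with the same dimnames.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    nm <- colnames(x)[s == 0] %||% paste0("column ", which(s == 0))
    stop("zero-variance column(s) cannot be standardized: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  z <- scale(x, center = TRUE, scale = s)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Comprehensive indices by principal component analysis
#'
#' Decomposes the standardized resistance-coefficient matrix into
#' principal components. The component scores are the comprehensive
#' indices F1..Fm (one summary value per genotype and component); the
#' contribution rate of a component is its share of total variance in
#' percent. With g genotypes at most g - 1 components carry variance, so
#' with 4 genotypes the first three components always reach a cumulative
#' contribution of 100%.
#'
#' Component signs are not identified by the decomposition but change
#' the membership step, so each component is oriented deterministically:
#' the sum of its loadings is made positive; if that sum is zero the
#' sign of the largest-magnitude loading decides.
#'
#' @param x column-standardized numeric matrix (mean 0, sd 1 per
#'   column); use [standardize_columns()] first.
#' @param retain component retention rule: `NULL` (default) keeps every
#'   component with positive variance, capped at genotypes - 1; an
#'   integer keeps that many leading components; `c(cumulative = p)`
#'   keeps the smallest set reaching a cumulative contribution of `p`
#'   percent; `"all"` keeps all (including zero-variance components, for
#'   exact reconstruction).
#' @return list of class `comprehensive_indices` with elements
#'   `scores` (genotypes x components), `loadings`, `contribution`
#'   (percent per component), `cumulative`, `eigenvalues`.
#' @export
comprehensive_indices <- function(x, retain = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 genotypes for PCA", call. = FALSE)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(s - 1) > 1e-4)) {
    stop("input must be column-standardized (mean 0, sd 1); ",
         "call standardize_columns() first", call. = FALSE)
  }
  cv <- crossprod(x) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  val <- pmax(eg$values, 0)
  vec <- eg$vectors
  # deterministic sign orientation
  for (j in seq_len(ncol(vec))) {
    cs <- sum(vec[, j])
    if (abs(cs) < 1e-12) cs <- vec[which.max(abs(vec[, j])), j]
    if (cs < 0) vec[, j] <- -vec[, j]
  }
  total <- sum(val)
  contribution <- 100 * val / total
  tol <- 1e-10 * max(val, 1)

  if (is.null(retain)) {
    m <- min(sum(val > tol), n - 1)
  } else if (identical(retain, "all")) {
    m <- length(val)
  } else if (!is.null(names(retain)) && names(retain)[1] == "cumulative") {
    m <- which(cumsum(contribution) >= retain[[1]] - 1e-9)[1]
    if (is.na(m)) m <- length(val)
  } else if (is.numeric(retain) && length(retain) == 1 && retain >= 1) {
    m <- min(as.integer(retain), length(val))
  } else {
    stop("invalid 'retain' rule", call. = FALSE)
  }
  idx <- seq_len(m)
  scores <- x %*% vec[, idx, drop = FALSE]
  colnames(scores) <- paste0("F", idx)
  rownames(scores) <- rownames(x)
  loadings <- vec[, idx, drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("F", idx))
  out <- list(scores = scores,
              loadings = loadings,
              contribution = contribution[idx],
              cumulative = cumsum(contribution)[idx],
              eigenvalues = val[idx])
  class(out) <- "comprehensive_indices"
  out
}

#' Weights from component contribution rates
#'
#' The weight of comprehensive index i is its contribution rate divided
#' by the sum of the contribution rates of all retained indices,
#' \deqn{W_i = P_i / \sum_j P_j,} so the weights are positive and sum
#' to one.
#'
#' @param contribution positive contribution rates in percent.
#' @return numeric weight vector summing to 1.
#' @examples
#' contribution_weights(c(45.5, 31.7, 22.8))  # 0.455 0.317 0.228
#' @export
contribution_weights <- function(contribution) {
  contribution <- as.numeric(contribution)
  if (length(contribution) == 0 || any(!is.finite(contribution)) ||
      any(contribution <= 0)) {
    stop("contribution rates must all be positive and finite", call. = FALSE)
  }
  contribution / sum(contribution)
}

new_d_scores <- function(genotypes, d, mode) {
  out <- data.frame(genotype = genotypes, d = as.numeric(d),
                    rank = rank(-d, ties.method = "min"),
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("d_scores", "data.frame")
  out
}

#' Unweighted comprehensive D score
#'
#' The plain mean of a genotype's membership values across indicators,
#' \deqn{D = (1/n) \sum_i U_i.} Higher D means greater stress
#' tolerance. Used when all indicators count equally (e.g. one trait at
#' several stress levels).
#'
#' @param u membership matrix from [membership_values()].
#' @return data frame of class `d_scores` with columns `genotype`, `d`,
#'   `rank` (1 = most tolerant; ties share the smaller rank).
#' @export
d_score_unweighted <- function(u) {
  u <- as.matrix(u)
  if (nrow(u) == 0 || ncol(u) == 0) stop("empty membership matrix",
                                         call. = FALSE)
  new_d_scores(rownames(u) %||% as.character(seq_len(nrow(u))),
               rowMeans(u), "unweighted")
}

#' Weighted comprehensive D score
#'
#' The contribution-weighted sum of a genotype's membership values,
#' \deqn{D = \sum_i W_i U_i,} with weights from
#' [contribution_weights()]. With uniform weights this reduces exactly
#' to the unweighted score.
#'
#' @param u membership matrix (columns = comprehensive indices).
#' @param w weight vector, one weight per column of `u`.
#' @return data frame of class `d_scores` (see [d_score_unweighted()]).
#' @export
d_score_weighted <- function(u, w) {
  u <- as.matrix(u)
  w <- as.numeric(w)
  if (length(w) != ncol(u)) {
    stop(sprintf("got %d weights for %d membership columns",
                 length(w), ncol(u)), call. = FALSE)
  }
  new_d_scores(rownames(u) %||% as.character(seq_len(nrow(u))),
               drop(u %*% w), "weighted")
}

#' Full comprehensive evaluation of a trait table
#'
#' Runs the whole scoring chain. In `unweighted` mode the resistance
#' coefficients themselves are the indices: membership is taken over the
#' raw coefficient columns and D is their mean (the single-trait strain
#' screen). In `weighted` mode the coefficient matrix is standardized,
#' summarized by principal components into comprehensive indices,
#' membership is taken over the component scores, and D is the
#' contribution-weighted sum (the multi-trait seedling evaluation).
#'
#' @param table a [trait_table()].
#' @param indicators an [indicator_spec()]; defaults to every trait x
#'   stress level present.
#' @param mode `"unweighted"` or `"weighted"`.
#' @param retain component retention rule, see [comprehensive_indices()]
#'   (weighted mode only).
#' @param degenerate constant-column policy, see [membership_values()].
#' @param missing missing-cell policy, see [build_resistance_matrix()].
#' @return list of class `cd_evaluation`: `scores` (the `d_scores`
#'   frame), plus intermediates `crc`, and in weighted mode
#'   `standardized`, `indices`, `weights`, and `membership`.
#' @export
evaluate <- function(table, indicators = NULL,
                     mode = c("unweighted", "weighted"),
                     retain = NULL, degenerate = c("error", "drop"),
                     missing = c("error", "drop_indicator")) {
  mode <- match.arg(mode)
  crc <- build_resistance_matrix(table, indicators, missing = match.arg(missing))
  if (nrow(crc) < 2) stop("evaluation needs at least 2 genotypes",
                          call. = FALSE)
  if (mode == "unweighted") {
    u <- membership_values(crc, degenerate = degenerate)
    scores <- d_score_unweighted(u)
    out <- list(scores = scores, crc = crc, membership = u,
                standardized = NULL, indices = NULL, weights = NULL,
                mode = mode)
  } else {
    z <- standardize_columns(crc)
    ci <- comprehensive_indices(z, retain = retain)
    w <- contribution_weights(ci$contribution)
    u <- membership_values(ci$scores, degenerate = degenerate)
    if (ncol(u) < length(w)) {  # degenerate component dropped
      w <- contribution_weights(ci$contribution[colnames(ci$scores) %in% colnames(u)])
    }
    scores <- d_score_weighted(u, w)
    out <- list(scores = scores, crc = crc, membership = u,
                standardized = z, indices = ci, weights = w, mode = mode)
  }
  class(out) <- "cd_evaluation"
  out
}

#' @export
print.cd_evaluation <- function(x, ...) {
  cat(sprintf("Comprehensive tolerance evaluation (%s mode)\n", x$mode))
  cat(sprintf("  %d genotypes, %d indicator(s)\n",
              nrow(x$crc), ncol(x$crc)))
  if (!is.null(x$weights)) {
    cat("  component weights:",
        paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  }
  s <- x$scores[order(x$scores$rank), ]
  cat("  D scores (descending):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-12s D = %.3f  rank %d\n",
                s$genotype[i], s$d[i], s$rank[i]))
  }
  invisible(x)
}
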