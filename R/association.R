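#' Pearson association between two tolerance score vectors
#'
#' Correlates the comprehensive D scores obtained at two biological
#' levels (e.g. free-living strains versus the seedlings they
#' mycorrhize) and tests the correlation with the exact small-sample
#' Student-t test: \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 degrees
#' of freedom, two-tailed. No normal approximation is used; at n = 4
#' the approximation would be badly off.
#'
#' @param x,y numeric vectors of equal length (n >= 3), matched by
#'   genotype.
#' @return object of class `cd_association` with elements `r`, `t_stat`,
#'   `df`, `p_two_tailed`, `n`.
#' @examples
#' pearson_association(c(0, 0.228, 0.351, 0.935),
#'                     c(0.894, 0.539, 0.411, 0.189))
#' @export
pearson_association <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired scores", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite scores", call. = FALSE)
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("zero variance in one of the score vectors",
                                 call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (1 - r^2 <= .Machine$double.eps) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  }
  out <- list(r = r, t_stat = t_stat, df = df, p_two_tailed = p, n = n)
  class(out) <- "cd_association"
  out
}

#' @export
print.cd_association <- function(x, ...) {
  cat("Pearson association of comprehensive D scores\n")
  cat(sprintf("  r = %.3f, t = %.3f, df = %d, two-tailed p = %.3f (n = %d)\n",
              x$r, x$t_stat, x$df, x$p_two_tailed, x$n))
  invisible(x)
}

#' Root-to-shoot transfer factor
#'
#' TF = shoot metal concentration / root metal concentration; values
#' below 1 mean the metal is retained in the root rather than
#' translocated to the shoot.
#'
#' @param shoot_cd shoot concentration (mg/kg, >= 0).
#' @param root_cd root concentration (mg/kg, > 0).
#' @return dimensionless ratio.
#' @export
transfer_factor <- function(shoot_cd, root_cd) {
  if (any(!is.finite(root_cd)) || any(root_cd <= 0)) {
    stop("root concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(shoot_cd)) || any(shoot_cd < 0)) {
    stop("shoot concentration must be >= 0", call. = FALSE)
  }
  shoot_cd / root_cd
}

#' Soil-to-shoot bioconcentration factor
#'
#' BF = shoot metal concentration / soil metal concentration; measures
#' how strongly the plant concentrates the metal from the substrate.
#'
#' @param shoot_cd shoot concentration (mg/kg, >= 0).
#' @param soil_cd soil concentration (mg/kg, > 0).
#' @return dimensionless ratio.
#' @export
bioconcentration_factor <- function(shoot_cd, soil_cd) {
  if (any(!is.finite(soil_cd)) || any(soil_cd <= 0)) {
    stop("soil concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(shoot_cd)) || any(shoot_cd < 0)) {
    stop("shoot concentration must be >= 0", call. = FALSE)
  }
  shoot_cd / soil_cd
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard qPCR fold change of a target gene against a reference gene,
#' treated versus control:
#' 2^-((Ct_target,treated - Ct_ref,treated) -
#'     (Ct_target,control - Ct_ref,control)).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values.
#' @return fold change (1 = no change).
#' @export
ddct_relative_expression <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
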