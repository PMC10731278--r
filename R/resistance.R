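#' Specify the evaluation indicators
#'
#' An indicator is one trait measured at one stress level. The cadmium
#' resistance coefficient of a genotype for that indicator is the ratio
#' of its mean trait value under stress to its mean control value,
#' expressed in percent. For traits where a *smaller* value under stress
#' means better tolerance (e.g. malondialdehyde content), set
#' `direction = "lower"` and the ratio is inverted so that larger
#' coefficients always mean more tolerant.
#'
#' @param trait trait label(s).
#' @param stress_level positive treatment level(s), recycled against
#'   `trait`.
#' @param direction `"higher"` (default; trait is better when retained
#'   under stress) or `"lower"`.
#' @return data frame of class `indicator_spec` with columns `trait`,
#'   `stress_level`, `direction`.
#' @export
indicator_spec <- function(trait, stress_level, direction = "higher") {
  spec <- data.frame(trait = as.character(trait),
                     stress_level = as.numeric(stress_level),
                     direction = direction,
                     stringsAsFactors = FALSE)
  if (any(spec$stress_level <= 0)) {
    stop("indicator stress_level must be > 0 (0 is the control)",
         call. = FALSE)
  }
  if (!all(spec$direction %in% c("higher", "lower"))) {
    stop("direction must be 'higher' or 'lower'", call. = FALSE)
  }
  class(spec) <- c("indicator_spec", "data.frame")
  spec
}

# every trait x nonzero treatment combination present in the table,
# all higher-is-better
default_indicators <- function(table) {
  stress <- table[table$treatment > 0, c("trait", "treatment")]
  u <- unique(stress)
  u <- u[order(u$trait, u$treatment), , drop = FALSE]
  indicator_spec(u$trait, u$treatment)
}

#' Cadmium resistance coefficient of a single measurement pair
#'
#' The resistance coefficient is the trait value under stress divided by
#' the control value, times 100. A genotype that grows as well under
#' stress as without scores 100; one that does not grow at all scores 0.
#'
#' @param stress_value mean trait value under stress (>= 0).
#' @param control_value mean trait value in the control (> 0).
#' @return the coefficient in percent.
#' @examples
#' resistance_coefficient(2, 4)  # 50
#' @export
resistance_coefficient <- function(stress_value, control_value) {
  if (any(!is.finite(control_value)) || any(control_value <= 0)) {
    stop("control value must be finite and > 0 (undefined baseline)",
         call. = FALSE)
  }
  if (any(!is.finite(stress_value)) || any(stress_value < 0)) {
    stop("stress value must be finite and >= 0", call. = FALSE)
  }
  100 * stress_value / control_value
}

#' Build the genotype-by-indicator resistance matrix
#'
#' Replicate measurements are averaged per (genotype, trait, treatment)
#' cell first; the coefficient is then formed from the two cell means.
#' Lower-is-better indicators are inverted (100 x control / stress) so a
#' larger entry always means more tolerant.
#'
#' @param table a [trait_table()].
#' @param indicators an [indicator_spec()]; defaults to every trait x
#'   stress-level combination in the table, higher-is-better.
#' @param missing what to do when a genotype lacks the stress cell of an
#'   indicator: `"error"` (default) or `"drop_indicator"` (drop the
#'   whole indicator column with a warning; silent dropping would change
#'   the PCA weights, so it is never the default).
#' @return numeric matrix (genotypes x indicators, percent) of class
#'   `resistance_matrix`. Row order follows first appearance in the
#'   table; column names are `trait@level`.
#' @export
build_resistance_matrix <- function(table, indicators = NULL,
                                    missing = c("error", "drop_indicator")) {
  stopifnot(inherits(table, "trait_table") || is.data.frame(table))
  missing <- match.arg(missing)
  if (is.null(indicators)) indicators <- default_indicators(table)

  genotypes <- unique(table$genotype)
  # replicate means per (genotype, trait, treatment)
  cell <- stats::aggregate(value ~ genotype + trait + treatment,
                           data = as.data.frame(table), FUN = mean)
  cell_key <- paste(cell$genotype, cell$trait, cell$treatment, sep = "\r")
  cell_mean <- function(g, tr, lev) {
    i <- match(paste(g, tr, lev, sep = "\r"), cell_key)
    if (is.na(i)) NA_real_ else cell$value[i]
  }

  n_ind <- nrow(indicators)
  crc <- matrix(NA_real_, length(genotypes), n_ind,
                dimnames = list(genotypes,
                                paste0(indicators$trait, "@",
                                       indicators$stress_level)))
  drop_cols <- logical(n_ind)
  for (j in seq_len(n_ind)) {
    tr <- indicators$trait[j]
    lev <- indicators$stress_level[j]
    inv <- identical(indicators$direction[j], "lower")
    for (i in seq_along(genotypes)) {
      g <- genotypes[i]
      ctrl <- cell_mean(g, tr, 0)
      strs <- cell_mean(g, tr, lev)
      if (is.na(ctrl) || is.na(strs)) {
        if (missing == "drop_indicator") { drop_cols[j] <- TRUE; next }
        stop(sprintf("missing %s cell for genotype=%s trait=%s level=%g",
                     if (is.na(ctrl)) "control" else "stress", g, tr, lev),
             call. = FALSE)
      }
      if (ctrl <= 0) {
        stop(sprintf(
          "undefined baseline: control mean <= 0 for genotype=%s trait=%s",
          g, tr), call. = FALSE)
      }
      if (inv) {
        if (strs <= 0) {
          stop(sprintf(
            "cannot invert lower-is-better indicator with stress mean <= 0 (genotype=%s trait=%s level=%g)",
            g, tr, lev), call. = FALSE)
        }
        crc[i, j] <- 100 * ctrl / strs
      } else {
        crc[i, j] <- resistance_coefficient(strs, ctrl)
      }
    }
  }
  if (any(drop_cols)) {
    warning("dropping indicator(s) with missing cells: ",
            paste(colnames(crc)[drop_cols], collapse = ", "), call. = FALSE)
    crc <- crc[, !drop_cols, drop = FALSE]
  }
  if (ncol(crc) == 0) stop("no indicators left after missing-cell policy",
                           call. = FALSE)
  class(crc) <- c("resistance_matrix", class(crc))
  crc
}
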