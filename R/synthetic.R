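#' Configuration for the synthetic phenotype generator
#'
#' The generator emulates a tolerance screen: each genotype carries a
#' latent tolerance on \[0, 1\]; each trait declines with dose at a
#' per-trait sensitivity, attenuated by tolerance; replicates add
#' multiplicative lognormal noise. The default configuration mirrors a
#' ten-strain colony-area screen at four cadmium doses with three
#' replicates.
#'
#' The retention of trait t for genotype g at dose d is
#' `exp(-sensitivity_t * d * (1 - tolerance_g))` (exponential family) or
#' `max(0, 1 - sensitivity_t * d * (1 - tolerance_g))` (linear family,
#' which can reach exact zero growth). A tolerance of 1 gives no decline
#' at any dose.
#'
#' @param n_genotypes number of genotypes.
#' @param latent_tolerance per-genotype tolerance in \[0, 1\]; drawn
#'   uniformly when `NULL`.
#' @param traits data frame with columns `label`, `control_mean` (> 0,
#'   trait units), `control_cv` (between-genotype CV of the control
#'   mean), `sensitivity` (decline rate per dose unit), `direction`.
#' @param stress_levels positive doses (e.g. mg/L Cd).
#' @param dose_response `"exponential"` (default) or `"linear"`.
#' @param noise_cv replicate coefficient of variation (>= 0).
#' @param n_replicates replicates per cell (>= 1).
#' @param seed RNG seed; a fixed seed reproduces the table exactly.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_genotypes = 10,
                             latent_tolerance = NULL,
                             traits = data.frame(
                               label = "colony_area",
                               control_mean = 4,
                               control_cv = 0.25,
                               sensitivity = 0.5,
                               direction = "higher",
                               stringsAsFactors = FALSE),
                             stress_levels = c(2, 4, 6, 8),
                             dose_response = c("exponential", "linear"),
                             noise_cv = 0.05,
                             n_replicates = 3,
                             seed = 1) {
  dose_response <- match.arg(dose_response)
  if (n_genotypes < 1) stop("n_genotypes must be >= 1", call. = FALSE)
  if (!is.null(latent_tolerance)) {
    if (length(latent_tolerance) != n_genotypes ||
        any(latent_tolerance < 0) || any(latent_tolerance > 1)) {
      stop("latent_tolerance must be n_genotypes values in [0, 1]",
           call. = FALSE)
    }
  }
  need <- c("label", "control_mean", "control_cv", "sensitivity")
  if (!all(need %in% names(traits))) {
    stop("traits needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(traits$control_mean <= 0)) stop("control means must be > 0",
                                          call. = FALSE)
  if (any(stress_levels <= 0)) stop("stress levels must be > 0",
                                    call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  cfg <- list(n_genotypes = n_genotypes,
              latent_tolerance = latent_tolerance,
              traits = traits,
              stress_levels = as.numeric(stress_levels),
              dose_response = dose_response,
              noise_cv = noise_cv,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# lognormal multiplier with mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic trait table with known tolerance structure
#'
#' Produces a [trait_table()] (control level 0 plus every configured
#' stress level, replicated) whose latent per-genotype tolerance is
#' attached as `attr(x, "latent_tolerance")`, so recovery of the planted
#' ranking by the evaluation chain can be checked.
#'
#' @param config a [generator_config()].
#' @return a `trait_table` with the latent tolerance attribute.
#' @examples
#' tab <- generate_trait_table(generator_config(seed = 42))
#' head(tab)
#' @export
generate_trait_table <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    stop("config must come from generator_config()", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  ng <- config$n_genotypes
  genotypes <- sprintf("G%02d", seq_len(ng))
  tol <- config$latent_tolerance %||% stats::runif(ng)
  names(tol) <- genotypes

  levels <- c(0, config$stress_levels)
  reps <- seq_len(config$n_replicates)
  rows <- vector("list", nrow(config$traits))
  for (ti in seq_len(nrow(config$traits))) {
    tr <- config$traits[ti, ]
    # per-genotype control mean, varying between genotypes
    ctrl_mean <- tr$control_mean * rlnorm_cv(ng, tr$control_cv)
    grid <- expand.grid(replicate = reps, treatment = levels,
                        genotype = genotypes, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    g_idx <- match(grid$genotype, genotypes)
    stressor <- grid$treatment * (1 - tol[g_idx]) * tr$sensitivity
    retention <- if (config$dose_response == "exponential") {
      exp(-stressor)
    } else {
      pmax(0, 1 - stressor)
    }
    retention <- pmin(pmax(retention, 0), 1)
    mu <- ctrl_mean[g_idx] * retention
    grid$trait <- tr$label
    grid$value <- mu * rlnorm_cv(nrow(grid), config$noise_cv)
    rows[[ti]] <- grid[c("genotype", "trait", "treatment", "replicate",
                         "value")]
  }
  tab <- trait_table(do.call(rbind, rows))
  attr(tab, "latent_tolerance") <- tol
  tab
}

#' Load a packaged worked-example fixture
#'
#' Three small published worked examples ship with the package so every
#' stage can be exercised against known printed values:
#' \describe{
#'   \item{table1_strain_D}{ten-strain screen: strain labels with their
#'     unweighted comprehensive D values and rank.}
#'   \item{table2_seedling_eval}{four-seedling evaluation: the 4 x 3
#'     comprehensive-index matrix F, membership matrix U, component
#'     weights, D scores and ranks.}
#'   \item{table3_association}{the paired strain/seedling D vectors for
#'     the four shared genotypes plus the published correlation
#'     (r = -0.923) and two-tailed significance (0.077).}
#' }
#'
#' @param name fixture name, one of the three above.
#' @return `table1_strain_D`: data frame (strain, D, rank).
#'   `table2_seedling_eval`: list with `F` (matrix), `U` (matrix),
#'   `weights`, `D` (named vector), `rank`.
#'   `table3_association`: list with `pairs` (data frame genotype,
#'   d_strain, d_seedling), `r`, `p`.
#' @export
load_fixture <- function(name = c("table1_strain_D", "table2_seedling_eval",
                                  "table3_association")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "ecotol",
                                  mustWork = TRUE)
  if (name == "table1_strain_D") {
    df <- utils::read.csv(path("table1_strain_D.csv"),
                          stringsAsFactors = FALSE)
    return(df)
  }
  if (name == "table2_seedling_eval") {
    df <- utils::read.csv(path("table2_seedling_eval.csv"),
                          stringsAsFactors = FALSE)
    w <- utils::read.csv(path("table2_weights.csv"),
                         stringsAsFactors = FALSE)
    Fm <- as.matrix(df[paste0("F", 1:3)])
    Um <- as.matrix(df[paste0("U", 1:3)])
    rownames(Fm) <- rownames(Um) <- df$genotype
    return(list(F = Fm, U = Um,
                weights = stats::setNames(w$weight, w$component),
                D = stats::setNames(df$D, df$genotype),
                rank = stats::setNames(df$rank, df$genotype)))
  }
  pairs <- utils::read.csv(path("table3_association.csv"),
                           stringsAsFactors = FALSE)
  stat <- utils::read.csv(path("table3_printed.csv"),
                          stringsAsFactors = FALSE)
  list(pairs = pairs,
       r = stat$value[stat$statistic == "r"],
       p = stat$value[stat$statistic == "p"])
}
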