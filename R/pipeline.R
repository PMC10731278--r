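#' Run the full tolerance-evaluation pipeline from a configuration
#'
#' Orchestrates simulate/read -> resistance coefficients -> evaluation
#' -> classification -> association as one reproducible run. Every
#' intermediate is written as CSV, the dendrogram as Newick, and a JSON
#' manifest records the configuration snapshot, input digests, package
#' version, seed and per-stage outputs. Re-running an identical
#' configuration reproduces all numeric outputs bit-identically, and the
#' manifest's `digest` field (an MD5 over the output-file digests) is
#' then identical too.
#'
#' @param config a list, or path to a YAML/JSON file, with entries:
#' \describe{
#'   \item{seed}{integer seed used for any simulation (default 1).}
#'   \item{out_dir}{output directory (created if absent).}
#'   \item{input}{either `simulate:` (arguments for
#'     [generator_config()]) or `trait_csv:` plus optional `dialect:`
#'     (see [read_trait_table()]).}
#'   \item{evaluation}{`mode:` "unweighted"/"weighted", optional
#'     `indicators:` (list of trait/stress_level/direction), `retain:`;
#'     or `from_indices:` (CSV of a genotype column plus
#'     comprehensive-index columns) with `weights:` to score printed
#'     index tables directly.}
#'   \item{classification}{optional; `k:` or `cut_height:`, `linkage:`.}
#'   \item{association}{optional; `other_dscores:` path to a second
#'     dscores.csv to correlate with this run's D vector.}
#' }
#' @param out_dir overrides `config$out_dir`.
#' @return the manifest, invisibly (class `run_manifest`). On a stage
#'   failure the run aborts with the stage named and files already
#'   written are renamed with a `.partial` suffix.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- read_config(config)
  } else {
    config_path <- NULL
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured",
                                                   call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)

  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_results(x, p)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (p in written) file.rename(p, paste0(p, ".partial"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- list()

  # --- input stage -----------------------------------------------------
  ev_cfg <- config$evaluation %||% list()
  from_indices <- ev_cfg$from_indices
  table <- NULL
  if (is.null(from_indices)) {
    table <- stage("input", {
      inp <- config$input %||% stop("config$input required", call. = FALSE)
      if (!is.null(inp$simulate)) {
        sim <- inp$simulate
        sim$seed <- sim$seed %||% seed
        if (!is.null(sim$traits)) sim$traits <- as.data.frame(sim$traits)
        do.call(generator_config, sim) |> generate_trait_table()
      } else if (!is.null(inp$trait_csv)) {
        inputs[[inp$trait_csv]] <- unname(tools::md5sum(inp$trait_csv))
        read_trait_table(inp$trait_csv, inp$dialect %||% list())
      } else {
        stop("config$input needs 'simulate' or 'trait_csv'", call. = FALSE)
      }
    })
  }

  # --- evaluation stage ------------------------------------------------
  scores <- stage("evaluation", {
    if (!is.null(from_indices)) {
      inputs[[from_indices]] <- unname(tools::md5sum(from_indices))
      fm <- utils::read.csv(from_indices, stringsAsFactors = FALSE)
      gcol <- names(fm)[1]
      Fm <- as.matrix(fm[-1])
      rownames(Fm) <- fm[[gcol]]
      w <- as.numeric(unlist(ev_cfg$weights))
      if (length(w) != ncol(Fm)) {
        stop("weights length does not match index columns", call. = FALSE)
      }
      u <- membership_values(Fm)
      emit(u, "membership.csv")
      emit(data.frame(component = colnames(Fm), weight = w), "weights.csv")
      sc <- d_score_weighted(u, w)
      emit(sc, "dscores.csv")
      sc
    } else {
      ind <- NULL
      if (!is.null(ev_cfg$indicators)) {
        idf <- do.call(rbind, lapply(ev_cfg$indicators, as.data.frame))
        ind <- indicator_spec(idf$trait, idf$stress_level,
                              idf$direction %||% "higher")
      }
      res <- evaluate(table, indicators = ind,
                      mode = ev_cfg$mode %||% "unweighted",
                      retain = ev_cfg$retain)
      emit(res$crc, "crc.csv")
      emit(res$membership, "membership.csv")
      if (!is.null(res$indices)) {
        emit(res$indices$scores, "indices.csv")
        emit(data.frame(component = colnames(res$indices$scores),
                        contribution = res$indices$contribution,
                        weight = res$weights), "weights.csv")
      }
      emit(res$scores, "dscores.csv")
      res$scores
    }
  })

  # --- classification stage --------------------------------------------
  cls_cfg <- config$classification
  classing <- NULL
  if (!is.null(cls_cfg)) {
    classing <- stage("classification", {
      cl <- cluster_tolerance(scores,
                              k = cls_cfg$k,
                              cut_height = cls_cfg$cut_height,
                              linkage = cls_cfg$linkage %||% "average")
      emit(cl, "classes.csv")
      nwk <- file.path(out_dir, "dendrogram.nwk")
      dendrogram_newick(cl, nwk)
      written <- c(written, nwk)
      cl
    })
  }

  # --- association stage -----------------------------------------------
  assoc <- NULL
  if (!is.null(config$association)) {
    assoc <- stage("association", {
      other <- config$association$other_dscores
      inputs[[other]] <- unname(tools::md5sum(other))
      odf <- utils::read.csv(other, stringsAsFactors = FALSE)
      m <- match(scores$genotype, odf$genotype)
      if (any(is.na(m))) {
        stop("genotypes missing from other_dscores: ",
             paste(scores$genotype[is.na(m)], collapse = ", "),
             call. = FALSE)
      }
      a <- pearson_association(scores$d, odf$d[m])
      emit(a, "association.csv")
      a
    })
  }

  out_digests <- vapply(sort(written), function(p) unname(tools::md5sum(p)),
                        character(1))
  names(out_digests) <- basename(sort(written))
  manifest <- list(
    package = "ecotol",
    version = as.character(utils::packageVersion("ecotol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_file = config_path,
    config = config,
    input_digests = inputs,
    outputs = as.list(out_digests),
    digest = unname(tools::md5sum(
      {
        tf <- tempfile()
        writeLines(paste(names(out_digests), out_digests), tf)
        tf
      }))
  )
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
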