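#' Validate a pipeline configuration
#'
#' The pipeline is driven by one JSON configuration (list or file path):
#' grid extent and cell size, per-species simulation/fit settings, traffic
#' settings, MCMC and CV budgets, overlap pairs, output directory and one
#' master seed from which every stage derives its own seed via
#' [derive_seed()]. Validation is fail-fast: unknown covariate names or
#' missing fields error before any computation.
#'
#' @param config list or path to a JSON file.
#' @return the validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$grid$bbox) || is.null(config$grid$cell_size)) {
    stop("config$grid needs bbox and cell_size", call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "occucar_out"
  config$mcmc <- config$mcmc %||% list()
  m <- config$mcmc
  config$mcmc <- list(n_chains = m$n_chains %||% 1, n_iter = m$n_iter %||% 3000,
                      burnin = m$burnin %||% 1500, thin = m$thin %||% 3)
  config$cv <- config$cv %||% list(repeats = 0)
  if (is.null(config$species) || !length(config$species)) {
    stop("config needs at least one species entry", call. = FALSE)
  }
  if (is.data.frame(config$species)) {
    stop("config$species must be a list of objects (use JSON array of objects)",
         call. = FALSE)
  }
  for (sp in config$species) {
    if (is.null(sp$name) || is.null(sp$beta) || is.null(sp$gamma)) {
      stop("each species needs name, beta, gamma", call. = FALSE)
    }
    ncov <- length(sp$beta) - 1L
    terms <- sp$ecological %||% paste0("x", seq_len(ncov))
    bad <- setdiff(terms, paste0("x", seq_len(ncov)))
    if (length(bad)) {
      stop(sprintf("species '%s': unknown covariate name(s): %s",
                   sp$name, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$traffic$beta)) {
    stop("config$traffic needs beta (intercept + dist_coast at least)",
         call. = FALSE)
  }
  config
}

#' Run the end-to-end exposure-assessment pipeline
#'
#' Grid construction, per-species synthetic survey + site-occupancy iCAR fit
#' (+ optional cross-validation), traffic simulation + binomial iCAR fit,
#' posterior-median prediction surfaces, and pairwise species-vs-traffic
#' overlap statistics. Every artifact is written under `config$out_dir` and
#' recorded (with an MD5 checksum) in `manifest.json`; rerunning the same
#' config reproduces byte-identical CSV outputs.
#'
#' @param config list or JSON path, see [validate_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  grid <- build_grid(unlist(config$grid$bbox), config$grid$cell_size)
  mc <- function(stage) mcmc_config(
    n_chains = config$mcmc$n_chains, n_iter = config$mcmc$n_iter,
    burnin = config$mcmc$burnin, thin = config$mcmc$thin,
    seed = derive_seed(config$seed, stage))
  artifacts <- character(0)
  surfaces <- list()
  cv_report <- list()

  for (sp in config$species) {
    nm <- sp$name
    sim <- simulate_occupancy_dataset(
      grid, beta = unlist(sp$beta), gamma = unlist(sp$gamma),
      V_rho = sp$V_rho %||% 1,
      visits_per_cell = sp$visits_per_cell %||% NULL,
      seed = derive_seed(config$seed, paste0("simulate-", nm)))
    artifacts <- c(artifacts,
                   write_dataset(sim, file.path(out, nm),
                                 seed = derive_seed(config$seed,
                                                    paste0("simulate-", nm))))
    eco <- unlist(sp$ecological) %||% paste0("x", seq_len(length(sp$beta) - 1L))
    spec <- model_spec(ecological = eco,
                       detection = unlist(sp$detection) %||%
                         colnames(sim$data$W)[-1])
    fit <- fit_site_occupancy_icar(sim$data, spec,
                                   mcmc = mc(paste0("fit-occupancy-", nm)))
    surf <- predict_surface(fit)
    f <- file.path(out, paste0("surface_", nm, ".csv"))
    utils::write.csv(as.data.frame(surf), f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    surfaces[[nm]] <- surf
    if ((config$cv$repeats %||% 0) > 0) {
      cv <- cross_validate(sim$data, spec, repeats = config$cv$repeats,
                           seed = derive_seed(config$seed, paste0("cv-", nm)),
                           mcmc = mc(paste0("cv-mcmc-", nm)))
      cv_report[[nm]] <- list(mean_AUC = cv$mean_AUC, mean_TSS = cv$mean_TSS,
                              per_repeat = cv$per_repeat)
    }
  }

  tr <- simulate_traffic_dataset(grid, beta = unlist(config$traffic$beta),
                                 V_rho = config$traffic$V_rho %||% 0.5,
                                 seed = derive_seed(config$seed, "simulate-traffic"))
  tspec <- model_spec(ecological = colnames(tr$X)[-1], detection = character(0))
  tfit <- fit_binomial_icar(tr$X[, -1, drop = FALSE], tr$data$trials,
                            tr$data$presence, grid, tspec,
                            mcmc = mc("fit-traffic"))
  tsurf <- predict_surface(tfit)
  f <- file.path(out, "surface_traffic.csv")
  utils::write.csv(as.data.frame(tsurf), f, row.names = FALSE)
  artifacts <- c(artifacts, f)

  overlaps <- lapply(names(surfaces), function(nm) {
    ov <- niche_overlap(surfaces[[nm]], tsurf)
    list(species = nm, D = ov$D, I = ov$I, H = ov$H,
         n_cells = ov$n_cells_compared)
  })
  f <- file.path(out, "overlap_report.json")
  jsonlite::write_json(overlaps, f, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, f)
  if (length(cv_report)) {
    f <- file.path(out, "cv_report.json")
    jsonlite::write_json(cv_report, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    artifacts <- c(artifacts, f)
  }

  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    grid = list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                n_cells = grid$n_cells, cell_size = grid$cell_size),
    artifacts = lapply(artifacts, function(a) {
      list(path = a, md5 = unname(tools::md5sum(a)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize observation records
#'
#' Per-class record counts and percentages — the shape of a survey's summary
#' tables (sightings per species; vessels per class).
#'
#' @param labels character/factor vector of record labels.
#' @return data.frame with `label`, `count`, `percent` sorted by count.
#' @export
summarize_observations <- function(labels) {
  tb <- sort(table(labels), decreasing = TRUE)
  data.frame(label = names(tb), count = as.integer(tb),
             percent = round(100 * as.integer(tb) / sum(tb), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate <out_dir> [seed]` writes one synthetic survey;
#' `run <config.json>` executes the full pipeline; `overlap <a.csv> <b.csv>`
#' compares two per-cell surface CSVs (columns `cell_id`, `prob_median`).
#' Model fitting, selection and CV are reachable through `run` or the R API.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly (0 on success).
#' @export
occucar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: occucar (simulate <out_dir> [seed] | run <config.json> | overlap <a.csv> <b.csv>)"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  if (cmd == "simulate") {
    if (length(args) < 2) { message(usage); return(invisible(1L)) }
    seed <- if (length(args) >= 3) as.integer(args[3]) else 1L
    grid <- build_grid(c(0, 0, 80, 68), 4)
    sim <- simulate_occupancy_dataset(grid, beta = c(-1, 1, 0.8),
                                      gamma = c(0, 0.5, -0.4, -0.3),
                                      V_rho = 1, seed = seed)
    write_dataset(sim, args[2], seed = seed)
    message(sprintf("wrote sites.csv / visits.csv / truth.json to %s", args[2]))
  } else if (cmd == "run") {
    if (length(args) < 2) { message(usage); return(invisible(1L)) }
    run_pipeline(args[2])
    message("pipeline complete")
  } else if (cmd == "overlap") {
    if (length(args) < 3) { message(usage); return(invisible(1L)) }
    a <- utils::read.csv(args[2]); b <- utils::read.csv(args[3])
    ov <- niche_overlap(a$prob_median, b$prob_median)
    cat(jsonlite::toJSON(list(D = ov$D, I = ov$I, H = ov$H,
                              n_cells = ov$n_cells_compared),
                         auto_unbox = TRUE, digits = NA), "\n")
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
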