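# Config-driven orchestration: one config describes an input (edge list,
# association table, or a simulation spec) and a list of experiments;
# run_pipeline() executes them in order, writes per-stage outputs and a
# machine-readable manifest. All randomness derives from one master seed
# (stage name hashed into a sub-seed), so runs are reproducible and
# insensitive to stage reordering.

PIPELINE_EXPERIMENTS <- c("summary", "percolation", "tau_sweep",
                          "theta_sweep", "robustness", "edge_stats",
                          "degree_fit")

#' Read a pipeline configuration
#'
#' YAML or JSON (by extension). Recognized fields: `input` (one of
#' `edge_list: <path>`, `association_table: <path>`, or `simulate:` with
#' growth-model parameters `m`, `c`, `l`, `p0`, `n_target` and optional
#' weight spec `weights: {slope, intercept, noise_sd, log_base}`),
#' `experiments` (subset of `summary`, `percolation`, `tau_sweep`,
#' `theta_sweep`, `robustness`, `edge_stats`, `degree_fit`), `k_max`,
#' `tau_values`, `theta_values`, `alpha_values`, `n_seeds`, `x_min`,
#' `bins`, `master_seed`, `output_dir`.
#'
#' @param path Config file path.
#' @return Validated config list (see [validate_pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown experiment names, missing inputs and
#' unsorted parameter grids before any computation starts.
#'
#' @param config Config list.
#' @return The validated config with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(experiments = character(0), k_max = 6,
                   tau_values = c(0, 0.01, 0.02, 0.05),
                   theta_values = c(0.02, 0.05, 0.1, 0.2),
                   alpha_values = c(0, 0.1, 0.2, 0.3),
                   n_seeds = 10, x_min = 8, bins = 100,
                   master_seed = 1, output_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$experiments <- as.character(unlist(config$experiments))
  bad <- setdiff(config$experiments, PIPELINE_EXPERIMENTS)
  if (length(bad)) {
    stop("unknown experiment(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (config$k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  for (gr in c("tau_values", "theta_values", "alpha_values")) {
    v <- config[[gr]]
    if (length(v) && is.unsorted(v)) {
      stop(gr, " must be sorted ascending", call. = FALSE)
    }
  }
  src <- config$input
  if (is.null(src) || !is.list(src) ||
      sum(c("edge_list", "association_table", "simulate") %in% names(src)) != 1L) {
    stop("config$input must name exactly one of edge_list, association_table, simulate",
         call. = FALSE)
  }
  if (!is.null(src$edge_list) && !file.exists(src$edge_list)) {
    stop("input edge list not found: ", src$edge_list, call. = FALSE)
  }
  if (!is.null(src$association_table) && !file.exists(src$association_table)) {
    stop("input association table not found: ", src$association_table,
         call. = FALSE)
  }
  config
}

pipeline_load_input <- function(config) {
  src <- config$input
  if (!is.null(src$edge_list)) {
    list(net = read_edge_list(src$edge_list),
         desc = list(type = "edge_list", path = src$edge_list))
  } else if (!is.null(src$association_table)) {
    list(net = symmetrize(read_association_table(src$association_table)),
         desc = list(type = "association_table",
                     path = src$association_table))
  } else {
    sim <- src$simulate
    gp <- growth_params(
      m = sim$m %||% 4, c = sim$c %||% 4, l = sim$l %||% 20,
      p0 = sim$p0 %||% 0.2, n_target = sim$n_target %||% 2000,
      seed = derive_seed(config$master_seed, "simulate"))
    net <- grow_network(gp)
    if (!is.null(sim$weights)) {
      ws <- sim$weights
      net <- assign_synthetic_weights(
        net, slope = ws$slope %||% 5.0, intercept = ws$intercept %||% -4.4,
        noise_sd = ws$noise_sd %||% 0.2, log_base = ws$log_base %||% 10,
        seed = derive_seed(config$master_seed, "simulate_weights"))
    }
    list(net = net,
         desc = list(type = "simulate",
                     params = gp[c("m", "c", "l", "p0", "n_target")],
                     seed = gp$seed, weighted = !is.null(sim$weights)))
  }
}

#' Run the experiment pipeline
#'
#' Loads (or simulates) the input network, executes the configured
#' experiments in order, writes one output file per stage under
#' `output_dir` and a `manifest.json` recording the input, the derived
#' seeds, the package version and every stage's output path. A failing
#' stage aborts with an error naming the stage.
#'
#' @param config Config list or path to a YAML/JSON config file.
#' @param output_dir Overrides `config$output_dir` when non-NULL.
#' @return The manifest (list), invisibly; written as
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  message("[pipeline] loading input")
  input <- pipeline_load_input(config)
  net <- input$net
  if (input$desc$type == "simulate") {
    write_edge_list(net, file.path(out, "network.tsv"))
    jsonlite::write_json(input$desc, file.path(out, "simulate_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  stages <- list()
  seeds <- list()
  for (exp in config$experiments) {
    t0 <- Sys.time()
    message("[pipeline] stage ", exp)
    res <- tryCatch(
      run_stage(exp, net, config, out, seeds),
      error = function(e) stop("stage '", exp, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    seeds <- res$seeds
    stages[[exp]] <- list(output = res$output,
                          seconds = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs")))
    message(sprintf("[pipeline] stage %s done (%.1fs)", exp,
                    stages[[exp]]$seconds))
  }

  manifest <- list(
    package = "kcliquenet",
    version = as.character(utils::packageVersion("kcliquenet")),
    input = input$desc,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    master_seed = config$master_seed,
    stage_seeds = seeds,
    k_max = config$k_max,
    stages = stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

run_stage <- function(exp, net, config, out, seeds) {
  path <- switch(exp,
    summary = {
      p <- file.path(out, "summary.json")
      write_summary_json(network_summary(net), p)
      p
    },
    percolation = {
      p <- file.path(out, "percolation.tsv")
      write_profile(percolation_profile(net, config$k_max), p)
      p
    },
    tau_sweep = {
      p <- file.path(out, "tau_sweep.tsv")
      write_sweep(perturbation_sweep(net, "tau", config$tau_values,
                                     config$k_max), p)
      p
    },
    theta_sweep = {
      p <- file.path(out, "theta_sweep.tsv")
      write_sweep(perturbation_sweep(net, "theta", config$theta_values,
                                     config$k_max), p)
      p
    },
    robustness = {
      s <- derive_seed(config$master_seed, "robustness")
      seeds$robustness <- s
      p <- file.path(out, "robustness.tsv")
      rnd <- perturbation_sweep(net, "alpha_random", config$alpha_values,
                                config$k_max, config$n_seeds, s)
      dg <- perturbation_sweep(net, "alpha_degree", config$alpha_values,
                               config$k_max, config$n_seeds, s)
      write.table(rbind(rnd$results, dg$results), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      p
    },
    edge_stats = {
      p <- file.path(out, "edge_stats.tsv")
      write.table(edge_stats(net), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (is_weighted_net(net) && igraph::ecount(net) >= config$bins) {
        write_bin_fit_json(bin_and_fit(net, b = config$bins),
                           file.path(out, "bin_fit.json"))
      }
      p
    },
    degree_fit = {
      p <- file.path(out, "degree_ccdf.tsv")
      fit <- fit_degree_exponent(net, "mle", x_min = config$x_min)
      write_ccdf(fit, p)
      jsonlite::write_json(fit[c("gamma", "method", "x_min", "n_tail")],
                           file.path(out, "degree_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      p
    })
  list(output = path, seeds = seeds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
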