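#' Run a processing stage from a configuration list
#'
#' Programmatic entry point behind the `padftex` command line.  A
#' configuration is a named list with a `command` field (one of `simulate`,
#' `correlate`, `filter`, `harmonics`, `padf`, `texture-scan`, `calibrate`)
#' plus the stage's parameters.  Every stage is deterministic given `seed`,
#' never mutates its inputs, and writes a provenance record (full
#' configuration, seed, package version) next to its output.
#'
#' Stage parameters (defaults in parentheses):
#' \describe{
#'   \item{simulate}{`out`; `mode` ("rings"), `model` ("uniform"),
#'     `epsilon` (0.1), `gamma` (0.35), `nc` (10), `nd` (100), `a` (5.6),
#'     `nphi` (360), `nq` (60), `qmax` (4), `sigma_q` (0.05), `sigma_phi_deg`
#'     (2), `photon_scale` (none), `excitation` (0), `seed` (1).}
#'   \item{correlate}{`input` (polar stack), `out` (RDS with the
#'     correlation volume).}
#'   \item{filter}{`input`, `out` (CSV of profile records); `lattice_tol`
#'     (0.05), `rk_max` (Inf), `ratio_tol` (0.02).}
#'   \item{harmonics}{`input` (correlation RDS), `out` (CSV power table);
#'     `lmax` (12), `cutoff` (1e-6).}
#'   \item{padf}{`input` (correlation RDS), `out` (RDS with the PADF);
#'     `lmax` (8), `rmin` (1), `rmax` (10), `nr` (64).}
#'   \item{texture-scan}{`out` (CSV exponent table); `nc`
#'     ("8,32,128,512"), `eps` (0.05), `reps` (200), `seed` (1).}
#'   \item{calibrate}{`ring_radius` (mm), `d_spacing` (58.380 angstrom),
#'     `wavelength`; prints and returns the distance.}
#' }
#'
#' @param config named list, see above.
#' @return the stage result, invisibly.
#' @export
run_pipeline <- function(config) {
  cmd <- config$command
  if (is.null(cmd)) stop("config error: missing key 'command'")
  get <- function(key, default = NULL, required = FALSE) {
    v <- config[[key]]
    if (is.null(v)) {
      if (required) stop("config error: missing key '", key, "'")
      return(default)
    }
    v
  }
  num <- function(key, default = NULL, required = FALSE) {
    v <- get(key, default, required)
    if (is.null(v)) return(NULL)
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) stop("config error: key '", key, "' is not numeric")
    v
  }

  result <- switch(cmd,
    simulate = {
      out <- get("out", required = TRUE)
      lattice <- hex_lattice(num("a", 5.6))
      qmax <- num("qmax", 4)
      grid <- polar_grid(seq(qmax / num("nq", 60), qmax,
                             length.out = num("nq", 60)),
                         n_phi = num("nphi", 360))
      model <- orientation_model(get("model", "uniform"),
                                 epsilon = num("epsilon", 0.1),
                                 gamma = num("gamma", 0.35))
      cfg <- sim_config(n_domains = num("nc", 10), n_patterns = num("nd", 100),
                        sigma_q = num("sigma_q", 0.05),
                        sigma_phi = num("sigma_phi_deg", 2) * pi / 180,
                        mode = get("mode", "rings"),
                        photon_scale = num("photon_scale"),
                        seed = num("seed", 1),
                        excitation = num("excitation", 0))
      ens <- simulate_ensemble(cfg, lattice, model, grid)
      write_polar_stack(ens$patterns, out, truth = ens$truth,
                        orientations = ens$orientations,
                        meta = list(config = config))
      ens
    },
    correlate = {
      stack <- read_polar_stack(get("input", required = TRUE))
      vol <- correlate_stack(stack$patterns)
      out <- get("out", required = TRUE)
      saveRDS(vol, out)
      vol
    },
    filter = {
      stack <- read_polar_stack(get("input", required = TRUE))
      rec <- ensemble_filter(stack$patterns,
                             tolerance = num("ratio_tol", 0.02),
                             rk_max = num("rk_max", Inf),
                             lattice_tolerance = num("lattice_tol", 0.05))
      utils::write.csv(rec, get("out", required = TRUE), row.names = FALSE)
      rec
    },
    harmonics = {
      vol <- readRDS(get("input", required = TRUE))
      bl <- correlation_to_bl(vol, l_max = num("lmax", 12),
                              svd_cutoff = num("cutoff", 1e-6))
      pw <- bl_power(bl)
      utils::write.csv(pw, get("out", required = TRUE), row.names = FALSE)
      pw
    },
    padf = {
      vol <- readRDS(get("input", required = TRUE))
      padf <- padf_from_correlation(
        vol, l_max = num("lmax", 8),
        r_values = seq(num("rmin", 1), num("rmax", 10),
                       length.out = num("nr", 64)))
      saveRDS(padf, get("out", required = TRUE))
      padf
    },
    `texture-scan` = {
      nc <- as.numeric(strsplit(as.character(get("nc", "8,32,128,512")),
                                ",")[[1]])
      model <- orientation_model("sinusoidal", epsilon = num("eps", 0.05))
      res <- scaling_experiment(nc, model, n_patterns = num("reps", 200),
                                seed = num("seed", 1))
      tab <- res$table
      tab$texture_slope <- res$texture_slope
      tab$nano_slope <- res$nano_slope
      utils::write.csv(tab, get("out", required = TRUE), row.names = FALSE)
      res
    },
    calibrate = {
      L <- calibrate_distance(num("ring_radius", required = TRUE),
                              num("d_spacing", 58.380),
                              num("wavelength", required = TRUE))
      message(sprintf("calibrated distance: %.6f m", L))
      L
    },
    stop("config error: unknown command '", cmd, "'"))

  out <- config[["out"]]
  if (!is.null(out)) {
    prov <- c(sprintf("# padftex %s provenance",
                      as.character(utils::packageVersion("padftex"))),
              sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
              vapply(names(config), function(k)
                sprintf("%s = %s", k, paste(config[[k]], collapse = ",")), ""))
    writeLines(prov, paste0(out, ".prov"))
  }
  invisible(result)
}

#' Command-line interface
#'
#' Parses `padftex <command> --key value ...` argument vectors and calls
#' [run_pipeline()].  Used by the `inst/cli/padftex.R` launcher:
#' `Rscript -e 'padftex::padftex_cli()' <command> --key value ...`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
padftex_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: padftex <simulate|correlate|filter|harmonics|padf|texture-scan|calibrate>",
    "[--key value ...]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  config <- list(command = args[1])
  i <- 2
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args)) {
      message("bad argument: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    config[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) {
                       message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                               " error: ", conditionMessage(e))
                       1L
                     })
  invisible(status)
}
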