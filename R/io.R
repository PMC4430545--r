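# Configuration loading/validation, TSV round-trips, provenance manifest.

.cfg_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("ap_config_error", "error")))
}

.check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    .cfg_error("unknown key(s) in '", where, "': ",
               paste(extra, collapse = ", "))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing the system, steering
#' protocol, Langevin parameters, stage plan, run mode, output directory
#' and master seed.  Unknown keys are rejected; missing settings are filled
#' with the package defaults (ten 2 A stages spanning 13 to 33 A,
#' k = 7.2 kcal/mol/A^2, gamma = 5/ps, dt = 2 fs, t_relax = 100 ps).
#' Every field is validated by constructing the corresponding module
#' objects before any compute.
#'
#' @param path config file (.yaml/.yml or .json)
#' @return object of class \code{"run_config"} with the constructed
#'   \code{system}, \code{steering}, \code{params}, \code{plan},
#'   \code{mode}, \code{out_dir}, \code{seed} and the \code{raw} config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .cfg_error("config file not found: ", path)
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    .cfg_error("config parse error in ", path, ": ", conditionMessage(e))
  })
  .check_keys(raw, c("system", "steering", "langevin", "plan", "mode",
                     "out_dir", "seed"), "config")
  if (is.null(raw$system) || is.null(raw$system$kind)) {
    .cfg_error("config must provide system$kind")
  }
  .check_keys(raw$system, c("kind", "params", "x0", "v0"), "system")
  .check_keys(raw$steering, c("k", "velocity", "reaction_coord"), "steering")
  .check_keys(raw$langevin,
              c("temperature", "friction", "timestep", "masses"), "langevin")
  .check_keys(raw$plan,
              c("lambda_start", "lambda_end", "n_stages", "tps", "velocity",
                "t_relax", "record_spacing", "relax_method",
                "resample_velocities", "t_equil"), "plan")

  mode <- if (is.null(raw$mode)) "asmd" else raw$mode
  if (!mode %in% c("smd", "asmd", "frasmd")) {
    .cfg_error("mode must be one of smd, asmd, frasmd (got '", mode, "')")
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  wrap <- function(expr, where) {
    tryCatch(expr, error = function(e) {
      .cfg_error("invalid '", where, "': ", conditionMessage(e))
    })
  }
  spec <- wrap(do.call(potential_spec,
                       c(list(kind = raw$system$kind),
                         as.list(raw$system$params))), "system")
  potential <- make_potential(spec)

  plan_args <- as.list(raw$plan)
  plan_args$master_seed <- seed
  if (mode == "smd" && is.null(plan_args$n_stages)) plan_args$n_stages <- 1L
  plan <- wrap(do.call(stage_plan, plan_args), "plan")

  st_args <- as.list(raw$steering)
  if (is.null(st_args$k)) st_args$k <- 7.2
  velocity <- if (!is.null(plan$velocity)) plan$velocity
              else if (!is.null(st_args$velocity)) st_args$velocity else 10
  steering <- wrap(steering_protocol(
    k = st_args$k, lambda_start = plan$segments[1L, 1L],
    lambda_end = plan$segments[nrow(plan$segments), 2L],
    velocity = velocity, mode = "pull",
    reaction_coord = st_args$reaction_coord), "steering")

  lv <- as.list(raw$langevin)
  params <- wrap(do.call(langevin_params, lv), "langevin")

  x0 <- raw$system$x0
  if (is.null(x0)) {
    if (potential$dimension != 1L) {
      .cfg_error("system$x0 is required for multidimensional systems")
    }
    x0 <- plan$segments[1L, 1L]  # start on the reaction coordinate
  }
  v0 <- raw$system$v0
  state <- wrap(system_state(as.numeric(x0),
                             if (is.null(v0)) NULL else as.numeric(v0)),
                "system")
  if (length(state$positions) != potential$dimension) {
    .cfg_error("system$x0 length does not match potential dimension")
  }

  structure(list(system = list(potential = potential, state = state),
                 steering = steering, params = params, plan = plan,
                 mode = mode,
                 out_dir = if (is.null(raw$out_dir)) "run" else raw$out_dir,
                 seed = seed, raw = raw),
            class = "run_config")
}

.canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

.config_hash <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(.canonical_json(raw)), tmp)
  unname(tools::md5sum(tmp))
}

.fmt <- function(x) sprintf("%.17g", x)  # repr-precision, diff-able

#' Write a PMF curve as TSV
#'
#' Columns lambda [A], F [kcal/mol], n_traj; floats at full repr precision
#' so that a read-back reproduces the curve exactly.
#'
#' @param pmf a [pmf_curve()]
#' @param path output path
#' @export
write_pmf_tsv <- function(pmf, path) {
  df <- data.frame(lambda = .fmt(pmf$lambda), F = .fmt(pmf$F),
                   n_traj = pmf$n_traj)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PMF curve written by [write_pmf_tsv()]
#'
#' @param path TSV path
#' @return a [pmf_curve()]
#' @export
read_pmf_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "numeric", "integer"))
  pmf_curve(df$lambda, df$F, n_traj = df$n_traj[1L])
}

#' Write a work ensemble as TSV
#'
#' One comment header line naming the temperature and grid size, then a
#' \code{lambda} column followed by one column per trajectory.
#'
#' @param ensemble a [work_ensemble()]
#' @param path output path
#' @export
write_work_tsv <- function(ensemble, path) {
  hdr <- sprintf("# temperature_K=%s n_traj=%d n_grid=%d",
                 .fmt(ensemble$temperature), nrow(ensemble$W),
                 ncol(ensemble$W))
  df <- data.frame(lambda = .fmt(ensemble$lambda))
  for (i in seq_len(nrow(ensemble$W))) {
    df[[sprintf("traj%d", i)]] <- .fmt(ensemble$W[i, ])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a work ensemble written by [write_work_tsv()]
#'
#' @param path TSV path
#' @return a [work_ensemble()]
#' @export
read_work_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  temp <- as.numeric(sub(".*temperature_K=([^ ]+).*", "\\1", hdr))
  df <- read.table(text = lines[-1L], header = TRUE, sep = "\t")
  W <- t(as.matrix(df[, -1L, drop = FALSE]))
  work_ensemble(df$lambda, W, temp)
}

#' Write run outputs plus a JSON provenance manifest
#'
#' Emits the assembled PMF, per-stage work ensembles, and the per-stage log
#' as TSV, plus \code{manifest.json} recording the files (with md5), the
#' config hash, seed, mode, package version and a timestamp.  Re-running
#' with the same inputs overwrites the TSVs byte-identically.
#'
#' @param results output of [run_smd()]/[run_naive_asmd()]/[run_fr_asmd()];
#'   a bare \code{stage_result} is also accepted
#' @param dir output directory (created if needed)
#' @param config optional \code{run_config} (for the config hash)
#' @param seed master seed to record
#' @param mode run mode to record
#' @return invisibly, the manifest as a list
#' @export
write_outputs <- function(results, dir, config = NULL, seed = NA_integer_,
                          mode = NA_character_) {
  if (inherits(results, "stage_result")) {
    results <- list(stages = list(results), pmf = results$pmf,
                    log = results$log)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- file.path(dir, "pmf.tsv")
  write_pmf_tsv(results$pmf, p)
  files <- c(files, p)
  for (s in seq_along(results$stages)) {
    p <- file.path(dir, sprintf("work_stage%d.tsv", s))
    write_work_tsv(results$stages[[s]]$ensemble, p)
    files <- c(files, p)
  }
  p <- file.path(dir, "stages.tsv")
  log <- results$log
  log$mean_W_end <- .fmt(log$mean_W_end)
  log$F_end <- .fmt(log$F_end)
  write.table(log, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    config_hash = if (is.null(config)) NA else .config_hash(config$raw),
    seed = seed, mode = mode,
    n_stages = length(results$stages),
    package_version = as.character(utils::packageVersion("adaptivepull")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
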