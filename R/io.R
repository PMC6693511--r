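#' Read / write stance records as delimited text
#'
#' Tab-separated table with a one-line header naming the columns
#' (`t, cop_x, cop_z, force_x, force_z, ankle_x, ankle_z, ankle_angle`) and
#' a preceding comment line declaring the units (`# units: m` or
#' `# units: cm`; centimetre files are converted to metres on input; angles
#' are always radians, forces newtons, time seconds). Validation rejects
#' non-monotone time stamps, negative normal forces and non-finite values
#' with the offending line number.
#'
#' @param path file path.
#' @param rec a [stance_record()].
#' @param units output length unit.
#' @return `read_stance_record` returns a [stance_record()].
#' @export
read_stance_record <- function(path) {
  lines <- readLines(path)
  uline <- grep("^#\\s*units:", lines, value = TRUE)
  k <- 1
  if (length(uline)) {
    u <- trimws(sub("^#\\s*units:", "", uline[1]))
    k <- switch(u, m = 1, cm = 0.01,
                stop("unknown units '", u, "' in ", path))
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  need <- c("t", "cop_x", "force_x", "force_z", "ankle_x", "ankle_z",
            "ankle_angle")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  if (anyNA(tab) || !all(vapply(tab, function(cc) all(is.finite(cc)), TRUE))) {
    bad <- which(!stats::complete.cases(tab))[1]
    stop("non-finite value at data line ", bad)
  }
  if (any(diff(tab$t) <= 0)) {
    bad <- which(diff(tab$t) <= 0)[1] + 1L
    stop("non-monotone time at data line ", bad)
  }
  if (any(tab$force_z < 0)) {
    bad <- which(tab$force_z < 0)[1]
    stop("negative normal force at data line ", bad)
  }
  stance_record(t = tab$t, cop_x = k * tab$cop_x,
                cop_z = if ("cop_z" %in% names(tab)) k * tab$cop_z else
                  rep(0, nrow(tab)),
                force_x = tab$force_x, force_z = tab$force_z,
                ankle_x = k * tab$ankle_x, ankle_z = k * tab$ankle_z,
                ankle_angle = tab$ankle_angle)
}

#' @rdname read_stance_record
#' @export
write_stance_record <- function(rec, path, units = c("m", "cm")) {
  units <- match.arg(units)
  k <- if (units == "cm") 100 else 1
  out <- rec
  for (cc in c("cop_x", "cop_z", "ankle_x", "ankle_z"))
    out[[cc]] <- k * rec[[cc]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  for (i in seq_len(nrow(out)))
    writeLines(paste(sprintf("%.17g", as.numeric(out[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Fit-result serialization
#'
#' Writes a [fit_foot()] result as structured text (YAML): the fitted
#' parameters under their ankle-frame names (in cm, following the
#' conventional reporting of foot-geometry fits), the error summary
#' statistics, and the final cost.
#' @param fit a `foot_fit`.
#' @param path file path.
#' @export
write_fit_result <- function(fit, path) {
  st <- error_statistics(fit)
  pars <- as.list(round(100 * coef(fit), 4))   # cm
  if (fit$type == "ellipse") pars$theta_E <- unname(coef(fit)[["theta_E"]])
  yaml::write_yaml(list(
    model = fit$type,
    parameters_cm = pars,
    cost = fit$cost,
    converged = fit$converged,
    errors = list(
      position_mm = list(mean = 1000 * st["position", "mean"],
                         sd = 1000 * st["position", "sd"],
                         max = 1000 * st["position", "max"]),
      orientation_deg = list(mean = 180 / pi * st["orientation", "mean"],
                             sd = 180 / pi * st["orientation", "sd"],
                             max = 180 / pi * st["orientation", "max"]))),
    path)
  invisible(path)
}

#' Command-line dispatcher
#'
#' Entry point used by the `gaitstep` script under `inst/cli`: runs one of
#' the pipeline stages and writes its outputs as text files.
#'
#' Subcommands:
#' * `synth --out FILE [--model ellipse|double_circle] [--noise SD_m]
#'   [--seed N]`: generate a synthetic stance record.
#' * `fit-foot --model ellipse|double_circle --record FILE --out FILE
#'   [--foot-config FILE]`: fit foot geometry to a stance record.
#' * `simulate --out FILE [--speed V] [--seed N]`: design and roll out a
#'   synthetic reference step; writes the trajectory.
#' * `track --record FILE(trajectory) --out FILE [--iters N]`: tracking OCP
#'   against a reference trajectory rollout.
#' * `predict --out FILE [--iters N] [--rounds N]`: reduced-scale
#'   prediction OCP.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_dispatch <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gaitstep <synth|fit-foot|simulate|track|predict> [options]",
    "run `gaitstep <subcommand>` with --help for options", sep = "\n")
  status <- tryCatch({
    if (!length(args)) { message(usage); return(invisible(2L)) }
    cmd <- args[1]
    opt <- parse_cli_options(args[-1])
    if (!is.null(opt$seed)) set.seed(as.integer(opt$seed))
    switch(cmd,
      "synth" = cli_synth(opt),
      "fit-foot" = cli_fit_foot(opt),
      "simulate" = cli_simulate(opt),
      "track" = cli_track(opt),
      "predict" = cli_predict(opt),
      { message("unknown subcommand: ", cmd); message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status %||% 0L))
}

parse_cli_options <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unknown argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opt[[key]] <- args[i + 1]; i <- i + 2
    } else {
      opt[[key]] <- TRUE; i <- i + 1
    }
  }
  opt
}

cli_synth <- function(opt) {
  if (is.null(opt$out)) stop("synth needs --out FILE")
  foot <- default_foot(opt$model %||% "ellipse")
  cfg <- stance_generator_config(foot,
                                 sigma_pos = as.numeric(opt$noise %||% 0),
                                 seed = as.integer(opt$seed %||% 1))
  g <- generate_stance_record(cfg)
  write_stance_record(g$record, opt$out)
  truth <- paste0(opt$out, ".truth.yaml")
  write_foot_config(foot, truth)
  message("wrote ", opt$out, " (+ ground truth sidecar ", truth, ")")
  0L
}

cli_fit_foot <- function(opt) {
  if (is.null(opt$record) || is.null(opt$out))
    stop("fit-foot needs --record FILE and --out FILE")
  model <- opt$model %||% "ellipse"
  rec <- read_stance_record(opt$record)
  init <- if (!is.null(opt$foot_config))
    read_foot_config(opt$foot_config, model) else default_foot(model)
  fit <- fit_foot(init, rec, fit_config())
  write_fit_result(fit, opt$out)
  message("wrote ", opt$out, " (cost ", signif(fit$cost, 4), ")")
  0L
}

cli_simulate <- function(opt) {
  if (is.null(opt$out)) stop("simulate needs --out FILE")
  m <- default_gait_model("ellipse")
  gen <- design_reference_step(m, speed = as.numeric(opt$speed %||% 0.8))
  res <- generate_reference_gait(gen)
  write_trajectory(res$trajectory, opt$out)
  message("wrote ", opt$out)
  0L
}

cli_track <- function(opt) {
  if (is.null(opt$record) || is.null(opt$out))
    stop("track needs --record FILE (a trajectory) and --out FILE")
  m <- default_gait_model("ellipse")
  traj <- read_trajectory(opt$record)
  ref <- reference_from_trajectory(m, traj)
  cfg <- ocp_config(nodes = vapply(traj$phases, function(p) ncol(p$X), 0L),
                    periodicity = FALSE,
                    max_iter = as.integer(opt$iters %||% 60))
  sol <- solve_ocp(m, build_phase_schedule("ellipse"), "tracking", cfg,
                   guess = traj, ref = ref)
  write_trajectory(sol$trajectory, opt$out,
                   summary = list(objective = sol$objective,
                                  status = sol$status,
                                  max_equality = sol$residuals$max_equality))
  message("wrote ", opt$out, " (", sol$status, ")")
  if (sol$status %in% c("converged", "stalled", "max_iter")) 0L else 1L
}

cli_predict <- function(opt) {
  if (is.null(opt$out)) stop("predict needs --out FILE")
  m <- default_gait_model("ellipse")
  sol <- predict_walking(m, rounds = as.integer(opt$rounds %||% 3),
                         max_iter = as.integer(opt$iters %||% 100))
  write_trajectory(sol$trajectory, opt$out,
                   summary = list(objective = sol$objective,
                                  status = sol$status,
                                  average_speed = average_speed(sol),
                                  step_length = step_length(sol, m),
                                  max_equality = sol$residuals$max_equality,
                                  min_inequality = sol$residuals$min_inequality))
  message("wrote ", opt$out, " (", sol$status,
          "; speed ", signif(average_speed(sol), 4),
          " m/s, step ", signif(step_length(sol, m), 4), " m)")
  0L
}
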