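#' Multi-phase gait trajectory
#'
#' Discretized states, controls and impact impulses over one walking step:
#' for each continuous phase, node times, 30-dimensional states
#' `(q, qdot, a)` and 12-dimensional excitation controls at the shooting
#' nodes plus the phase duration; for each instantaneous phase the
#' pre-impact state and the constraint-space impulse vector.
#'
#' Constructed by [generate_reference_gait()], [initialize_guess()] and
#' [solve_ocp()].
#'
#' @name gait_trajectory
NULL

#' @export
print.gait_trajectory <- function(x, ...) {
  nd <- vapply(x$phases, function(p) ncol(p$X), 0L)
  du <- vapply(x$phases, `[[`, 0, "duration")
  cat(sprintf("gait_trajectory: %d continuous phases (+%d impacts), %.3f s\n",
              length(x$phases), length(x$impacts), sum(du)))
  cat(sprintf("  nodes: %s; durations: %s s\n", paste(nd, collapse = "/"),
              paste(signif(du, 4), collapse = "/")))
  invisible(x)
}

#' Write / read a trajectory as delimited text
#'
#' A structured-summary header (YAML, commented) followed by a tab-separated
#' per-node table with time, states, controls; impacts are stored in the
#' header with their impulse vectors. Values are written with 17 significant
#' digits so a round trip preserves them to formatting precision.
#'
#' @param traj a `gait_trajectory`.
#' @param path file path.
#' @param summary optional named list merged into the header (objective,
#'   residual norms, ...).
#' @return `read_trajectory` returns a `gait_trajectory`.
#' @export
write_trajectory <- function(traj, path, summary = NULL) {
  hdr <- list(
    foot_model = traj$schedule$foot_model %||% "unknown",
    phases = lapply(traj$phases, function(p)
      list(modes = as.list(p$modes), nodes = ncol(p$X), duration = p$duration)),
    impacts = lapply(traj$impacts, function(im)
      list(at_phase = im$at_phase, impulses = as.list(im$impulses),
           modes = as.list(im$modes),
           pre = as.list(im$pre))),
    pre_impact_state = as.list(traj$pre_impact_state %||% numeric()))
  if (!is.null(summary)) hdr$summary <- summary
  ytxt <- strsplit(yaml::as.yaml(hdr, precision = 15), "\n")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", ytxt), con)
  writeLines("# ---", con)
  cols <- c("phase", "node", "t",
            paste0("q", 1:9), paste0("qd", 1:9), paste0("a", 1:12),
            paste0("u", 1:12))
  writeLines(paste(cols, collapse = "\t"), con)
  for (j in seq_along(traj$phases)) {
    p <- traj$phases[[j]]
    for (k in seq_len(ncol(p$X))) {
      vals <- c(p$t[k], p$X[, k], p$U[, k])
      writeLines(paste(c(j, k, sprintf("%.17g", vals)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hd <- grep("^# ", lines, value = TRUE)
  hd <- sub("^# ?", "", hd)
  hd <- hd[hd != "---"]
  hdr <- yaml::yaml.load(paste(hd, collapse = "\n"))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  phases <- list()
  for (j in sort(unique(tab$phase))) {
    tj <- tab[tab$phase == j, ]
    tj <- tj[order(tj$node), ]
    phases[[j]] <- list(t = tj$t,
                        X = t(as.matrix(tj[, 4:33])),
                        U = t(as.matrix(tj[, 34:45])),
                        duration = hdr$phases[[j]]$duration,
                        modes = unlist(hdr$phases[[j]]$modes))
    dimnames(phases[[j]]$X) <- NULL; dimnames(phases[[j]]$U) <- NULL
  }
  impacts <- lapply(hdr$impacts, function(im)
    list(at_phase = im$at_phase, impulses = unlist(im$impulses),
         modes = unlist(im$modes), pre = unlist(im$pre)))
  sched <- if (!is.null(hdr$foot_model) && hdr$foot_model != "unknown")
    build_phase_schedule(hdr$foot_model) else NULL
  structure(list(phases = phases, impacts = impacts, schedule = sched,
                 pre_impact_state = unlist(hdr$pre_impact_state),
                 summary = hdr$summary),
            class = "gait_trajectory")
}
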