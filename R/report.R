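# Pipeline orchestration: config parsing, stage chaining
# (ops -> states -> segments -> permeation/permeability -> profile), and
# the per-state permeability report with the CTRW check.

#' Read and validate a run configuration (YAML)
#'
#' Figure-obscured constants have no silent default at the pipeline level:
#' the channel z bounds are always mandatory, the D1 cutoff is mandatory
#' whenever a D1 order parameter is configured, and the SF/CE profile
#' windows are mandatory whenever the profile stage is enabled.  This
#' guards against silently irreproducible reports.
#'
#' @param path YAML file path.
#' @return a validated `run_config` (named list) with attribute `sha256`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  attr(cfg, "sha256") <- digest::digest(file = path, algo = "sha256")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(ok, msg) if (!ok) stop("config error: ", msg,
                                          call. = FALSE)
  need(!is.null(cfg$trajectory) || !is.null(cfg$structure),
       "a 'structure' (PDB) and/or 'trajectory' (DCD) path is required")
  need(!is.null(cfg$channel), "a 'channel' block is required")
  need(!is.null(cfg$channel$z_lo) && !is.null(cfg$channel$z_hi),
       paste("channel z_lo/z_hi are mandatory: the counting boundaries are",
             "not derivable from structure and must be stated explicitly"))
  if (!is.null(cfg$ops$d1))
    need(!is.null(cfg$states$d1_cutoff),
         paste("states$d1_cutoff is mandatory when a D1 order parameter is",
               "configured: the wide/narrow boundary is figure-defined and",
               "must be stated explicitly"))
  if (isTRUE(cfg$profile$enabled)) {
    need(!is.null(cfg$profile$sf_z_range) &&
           !is.null(cfg$profile$ce_z_range),
         paste("profile sf_z_range/ce_z_range are mandatory when the",
               "profile stage is enabled: the SF/CE windows are",
               "figure-defined and must be stated explicitly"))
  }
  structure(cfg, class = "run_config")
}

op_from_cfg <- function(traj, spec, kind, name) {
  sels <- lapply(spec$atoms, function(s)
    select_atoms(traj$topology, residue_name = s$residue_name,
                 residue_number = s$residue_number,
                 atom_name = s$atom_name, chain = s$chain))
  op_series(traj, sels, kind = kind, name = name,
            chain = spec$chain %||% NA_character_)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages: load -> order parameters -> state classification -> segments ->
#' per-state permeation/permeability -> (optional) radius profile ->
#' Table-1-analog report.  All outputs are deterministic given identical
#' inputs and configuration; every artifact records the config SHA-256.
#'
#' @param config a `run_config` (from [read_run_config()]) or a named list
#'   with the same shape.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly; the report is also returned in
#'   `attr(, "report")`.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  con <- file(logf, "w")
  on.exit(close(con))
  sha <- attr(cfg, "sha256") %||%
    digest::digest(cfg, algo = "sha256")
  log_line(con, "aquaflux ", as.character(utils::packageVersion("aquaflux")),
           " | config sha256 ", sha)
  meta <- c(sprintf("# aquaflux %s", utils::packageVersion("aquaflux")),
            sprintf("# config_sha256: %s", sha))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_line(con, sprintf("stage %-12s %.2fs", name,
                          proc.time()[["elapsed"]] - t0))
    r
  }

  loaded <- stage("load", {
    if (!is.null(cfg$structure)) {
      pdb <- read_pdb(cfg$structure,
                      dt_ns = cfg$dt_ns %||% 0.1)
      top <- pdb$topology
      traj <- if (!is.null(cfg$trajectory))
        read_dcd(cfg$trajectory, top, dt_ns = cfg$dt_ns,
                 box = unlist(cfg$box)) else pdb$trajectory
    } else {
      stop("config must give 'structure' (PDB); DCD carries no topology")
    }
    list(top = top, traj = traj)
  })
  traj <- loaded$traj

  ch <- cfg$channel
  channel <- channel_spec(z_lo = ch$z_lo, z_hi = ch$z_hi,
                          buffer = ch$buffer %||% 2,
                          radial_cutoff = ch$radial_cutoff %||% 6,
                          center = unlist(ch$center %||% c(0, 0)))

  ops <- NULL; sf <- NULL; ce <- NULL; joint <- NULL
  if (!is.null(cfg$ops)) {
    ops <- stage("ops", {
      out <- list()
      if (!is.null(cfg$ops$d1))
        out$D1 <- op_from_cfg(loaded$traj, cfg$ops$d1, "distance", "D1")
      if (!is.null(cfg$ops$d2))
        out$D2 <- op_from_cfg(loaded$traj, cfg$ops$d2, "distance", "D2")
      write_op_csv(out, file.path(outdir, "order_parameters.csv"))
      out
    })
    joint <- stage("states", {
      hyst <- cfg$states$hysteresis %||% 0.2
      smooth <- cfg$states$smoothing_window %||% 5L
      if (!is.null(ops$D1))
        sf <- classify_states(ops$D1, cutoffs = cfg$states$d1_cutoff,
                               labels = c("narrow", "wide"),
                               hysteresis = hyst,
                               smoothing_window = smooth)
      if (!is.null(ops$D2))
        ce <- classify_states(ops$D2,
                               cutoffs = unlist(cfg$states$d2_cutoffs %||%
                                                  c(6.5, 7.5)),
                               labels = c("closed", "intermediate", "open"),
                               hysteresis = hyst,
                               smoothing_window = smooth)
      j <- if (!is.null(sf) && !is.null(ce)) joint_states(sf, ce)
           else sf %||% ce
      if (!is.null(j))
        write_states_csv(sf %||% j, file.path(outdir, "states.csv"),
                         ce = ce, joint = if (!is.null(sf) &&
                                              !is.null(ce)) j)
      j
    })
  }

  segs <- stage("segments", {
    if (is.null(joint)) {
      data.frame(state = "ALL", start = 1L, end = n_frames(traj) + 1L,
                 duration_ns = n_frames(traj) * (frame_dt(traj) %||% 1),
                 stringsAsFactors = FALSE)
    } else {
      state_segments(joint, min_dwell_ns = cfg$states$min_dwell_ns %||% 1)
    }
  })

  est <- stage("permeability", {
    e <- per_state_estimates(traj, channel, segs,
                             window_ns = cfg$window_ns %||% 2,
                             molar_volume = cfg$molar_volume %||% 18.0)
    regions <- track_regions(traj, channel)
    ev <- count_events(regions)
    utils::write.csv(as.data.frame(ev),
                     file.path(outdir, "permeation_events.csv"),
                     row.names = FALSE)
    utils::write.csv(cumulative_curve(ev, traj$times),
                     file.path(outdir, "cumulative_permeation.csv"),
                     row.names = FALSE)
    e
  })

  if (isTRUE(cfg$profile$enabled)) {
    stage("profile", {
      prof <- pore_radius_profile(traj, z_lo = channel$z_lo,
                                  z_hi = channel$z_hi,
                                  spacing = cfg$profile$spacing %||% 0.25)
      utils::write.csv(as.data.frame(prof),
                       file.path(outdir, "radius_profile.csv"),
                       row.names = FALSE)
      calls <- call_states_from_profile(prof,
                                        unlist(cfg$profile$sf_z_range),
                                        unlist(cfg$profile$ce_z_range))
      jsonlite::write_json(calls, file.path(outdir, "profile_states.json"),
                           auto_unbox = TRUE, digits = NA)
      prof
    })
  }

  rep <- stage("report", {
    r <- table1_report(est)
    writeLines(c(meta, r$text), file.path(outdir, "report.txt"))
    utils::write.csv(r$table, file.path(outdir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(config_sha256 = sha, estimates = est,
                              table = r$table),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    r
  })
  log_line(con, "done")
  out <- invisible(outdir)
  attr(out, "report") <- rep
  attr(out, "estimates") <- est
  out
}

# canonical column order for the per-state report
STATE_ORDER <- c("WO", "NO", "NI", "WC")

#' Format per-state estimates as a Table-1-analog report
#'
#' Rows p_f, p_d, p_f/p_d and N-bar; one column per joint state, ordered
#' WO, NO, NI, WC then alphabetically.  Permeabilities are rounded to two
#' decimals, occupancies to one; undefined ratios print as an en dash.
#'
#' @param est `permeability_estimates` from [per_state_estimates()].
#' @return list: `table` (formatted data.frame), `numbers` (numeric
#'   data.frame), `text` (printable lines).
#' @export
table1_report <- function(est) {
  if (nrow(est) == 0L) stop("no estimates to report", call. = FALSE)
  # merge segments of the same state: duration-weighted means
  states <- unique(est$state)
  ord <- order(match(states, STATE_ORDER, nomatch = 999L), states)
  states <- states[ord]
  fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  cols <- lapply(states, function(s) {
    rows <- est[est$state == s, , drop = FALSE]
    wdur <- (rows$t1 - rows$t0); wdur <- wdur / sum(wdur)
    pf <- sum(rows$p_f * wdur)
    pd <- sum(rows$p_d * wdur)
    nb <- sum(rows$N_bar * wdur)
    ns <- sqrt(sum((rows$N_se * wdur)^2))
    chk <- ctrw_check(pf, pd, nb)
    c(p_f = fmt2(round(pf, 2)), p_d = fmt2(round(pd, 2)),
      ratio = if (chk$defined) fmt2(chk$ratio) else "–",
      N_bar = if (is.na(nb)) "-" else
        sprintf("%.1f±%.1f", nb, if (is.na(ns)) 0 else ns))
  })
  tab <- data.frame(quantity = c("p_f", "p_d", "p_f/p_d", "N_bar"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(states)) tab[[states[i]]] <- cols[[i]]
  txt <- c(paste(c(sprintf("%-8s", "SF CE"),
                   sprintf("%12s", states)), collapse = ""),
           vapply(seq_len(nrow(tab)), function(r)
             paste(c(sprintf("%-8s", tab$quantity[r]),
                     sprintf("%12s", unlist(tab[r, -1L]))), collapse = ""),
             character(1)))
  list(table = tab, numbers = est, text = txt)
}
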