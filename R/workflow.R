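#' Read a flat key=value configuration file
#'
#' INI-style: one `key = value` per line, `#` comments, no sections. Values
#' are parsed as numeric where possible, comma-separated values become
#' vectors, "true"/"false" become logical.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else if (length(parts) > 1) parts else val
  }
  out
}

#' Run the full hybrid-phasing workflow
#'
#' Orchestrates the whole pipeline on a synthetic case or on files named in
#' the configuration: cell analysis (Matthews for every candidate order) ->
#' self-rotation function (NCS order, axis, equatorial twofold count) ->
#' Cn expansion of the partial monomer -> constrained MR placement ->
#' per-protomer rigid-body refinement with the magnification diagnostic
#' (if the inferred scale error exceeds `mag_tolerance` the model is
#' rescaled and re-placed, and the event is recorded) -> density
#' modification with phase extension -> machine-readable report.
#'
#' @param case A `synthetic_case` from [make_ring_case()], or NULL to load
#'   inputs from the config (keys `hkl`, `partial_pdb`, `em_map`).
#' @param config Named list (or path to a key=value file): optional keys
#'   `candidates` (default 11:14), `protomer_mass` (Da; default: atomic mass
#'   of the partial monomer divided by its completeness), `psi_step`,
#'   `srf_step` (section grid step, degrees),
#'   `mag_tolerance` (default 0.01), `d_start`, `total_cycles`,
#'   `solvent_update`, `ncs_update`, `n_steps`, `out_dir`, `force`,
#'   `use_truth_histogram` (synthetic cases only).
#' @param verbose Print stage progress.
#' @return List of class `workflow_report` (also serialized to
#'   `out_dir/report.json` when `out_dir` is set): matthews table, SRF
#'   results, placement, rigid-body summary, magnification events, DM
#'   summary and trace tail, plus a file manifest.
#' @export
run_workflow <- function(case = NULL, config = list(), verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- function(key, default) if (is.null(config[[key]])) default
                                else config[[key]]
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- cfg("out_dir", NULL)
  force <- isTRUE(cfg("force", FALSE))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    # resumable stages: reuse the stored result unless force = TRUE
    if (!is.null(out_dir)) {
      fn <- file.path(out_dir, paste0(name, ".rds"))
      if (!force && file.exists(fn)) {
        say("stage %s: reusing %s", name, fn)
        return(readRDS(fn))
      }
      val <- expr
      saveRDS(val, fn)
      return(val)
    }
    expr
  }

  if (is.null(case)) {
    refl <- read_hkl(config$hkl)
    partial <- read_pdb(config$partial_pdb)
    em <- if (!is.null(config$em_map)) read_mrc(config$em_map, periodic = FALSE)
          else NULL
    truth_refl <- NULL
  } else {
    refl <- case$refl_obs
    partial <- case$partial_monomer
    em <- case$em_map
    truth_refl <- if (isTRUE(cfg("use_truth_histogram", TRUE)))
      case$refl_truth else NULL
  }
  cell <- refl_cell(refl); sg <- refl_sg(refl)
  candidates <- cfg("candidates", 11:14)

  # --- stage 1: cell analysis -------------------------------------------
  frac <- cfg("partial_fraction",
              if (!is.null(case)) case$params$delivered_fraction else 1)
  # default protomer mass: atomic mass of the partial model scaled up by
  # its completeness (heavy atoms only; good enough for Vm bookkeeping)
  aw <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
  mass_partial <- sum(aw[partial$element], na.rm = TRUE)
  protomer_mass <- cfg("protomer_mass", mass_partial / frac)
  matthews <- do.call(rbind, lapply(candidates, function(n) {
    mt <- matthews_coefficient(cell, sg, n * protomer_mass)
    data.frame(n = n, vm = mt$vm, solvent = mt$solvent_fraction)
  }))
  say("analyze: Vm %.2f-%.2f A^3/Da over n = %s",
      min(matthews$vm), max(matthews$vm),
      paste(range(candidates), collapse = "-"))

  # --- stage 2: self-rotation function ----------------------------------
  srf <- stage("srf", {
    eng <- srf_engine(refl)
    det <- detect_ncs_order(eng, candidates = candidates,
                            step = cfg("srf_step", 5))
    if (det$ambiguous || is.na(det$n))
      stop_workflow("srf", "ambiguous NCS order; score table attached",
                    det$table)
    prof <- equatorial_twofold_profile(
      eng, axis = polar_to_vec(det$peak$theta, det$peak$phi))
    cnt <- count_equatorial_twofolds(prof, expected_order = det$n)
    list(det = det, equatorial = cnt)
  })
  n <- srf$det$n
  say("srf: n = %d, axis (theta %.0f, phi %.0f), %d equatorial twofolds",
      n, srf$det$peak$theta, srf$det$peak$phi, srf$equatorial$count)

  # --- stage 3: expansion + placement (+ magnification loop) ------------
  mag_tol <- cfg("mag_tolerance", 0.01)
  place_once <- function(monomer) {
    ring <- expand_cn(monomer, cn_operators(n, c(0, 0, 1), c(0, 0, 0)))
    pl <- search_placement(ring, refl, theta = srf$det$peak$theta,
                           phi = srf$det$peak$phi, order = n,
                           psi_step = cfg("psi_step", 2))
    placed <- apply_placement(ring, pl)
    rb <- rigid_body_refine(placed, refl,
                            axis = attr(pl, "axis"),
                            center = placement_ring_center(pl))
    list(ring = ring, pl = pl, placed = placed, rb = rb)
  }
  pr <- stage("placement", {
    monomer <- partial
    events <- list()
    res <- place_once(monomer)
    if (abs(res$rb$s - 1) > mag_tol) {
      events[[1]] <- sprintf(
        "magnification error inferred: s = %.4f; model rescaled by %.4f and re-placed",
        res$rb$s, 1 / res$rb$s)
      monomer <- rescale_magnification(monomer, 1 / res$rb$s,
                                       center = c(0, 0, 0))
      res <- place_once(monomer)
    }
    c(res, list(events = events, monomer = monomer))
  })
  say("place: psi %.1f, hand %+d, cor %.3f; rigid-body s = %.4f (%s)",
      pr$pl$psi[1], pr$pl$hand[1], pr$pl$cor[1], pr$rb$s,
      if (length(pr$events)) "rescaled" else "no magnification issue")

  # --- stage 4: density modification ------------------------------------
  solvent <- 1 - 1.23 / matthews$vm[matthews$n == n]
  dmcfg <- dm_config(d_start = cfg("d_start", 7.9),
                     total_cycles = cfg("total_cycles", 104),
                     solvent_update = cfg("solvent_update", 50),
                     ncs_update = cfg("ncs_update", 20),
                     n_steps = cfg("n_steps", 13),
                     solvent_fraction = solvent)
  dm <- stage("denmod", {
    fc_start <- calc_structure_factors(pr$rb$model, cell, sg,
                                       d_min = min(refl$d))
    start <- phase_recombine(refl, fc_start)
    start$phi[start$d < dmcfg$d_start] <- NA_real_
    start$fom[start$d < dmcfg$d_start] <- NA_real_
    ops <- cn_operators(n, attr(pr$pl, "axis"),
                        placement_ring_center(pr$pl))
    if (is.null(em))
      stop_workflow("denmod", "no EM map available for mask generation")
    run_dm(start, dmcfg, ops = ops, em_map = em, placement = pr$pl,
           hist_ref = truth_refl, verbose = verbose)
  })
  say("denmod: %d cycles, final NCS correlation %.3f", nrow(dm$trace),
      dm$ncs_cc)

  manifest <- if (is.null(out_dir)) character(0) else list.files(out_dir)
  report <- list(
    space_group = sg$symbol,
    cell = unlist(cell[c("a", "b", "c", "alpha", "beta", "gamma")]),
    matthews = matthews,
    srf = list(n = n, theta = srf$det$peak$theta, phi = srf$det$peak$phi,
               score_table = srf$det$table,
               equatorial_twofolds = srf$equatorial$count),
    placement = list(psi = pr$pl$psi[1], hand = pr$pl$hand[1],
                     translation = c(pr$pl$tx[1], pr$pl$ty[1], pr$pl$tz[1]),
                     score = pr$pl$cor[1],
                     rank_gap = if (nrow(pr$pl) > 1)
                       pr$pl$cor[1] - pr$pl$cor[2] else NA_real_),
    rigid_body = list(s = pr$rb$s, delta_r = pr$rb$delta_r,
                      mean_radius = pr$rb$mean_radius,
                      score = pr$rb$score,
                      all_inward = all(pr$rb$report$dr < 0),
                      events = unlist(pr$events)),
    dm = list(final_ncs_cc = dm$ncs_cc, cycles = nrow(dm$trace),
              d_final = dm$trace$d_cut[nrow(dm$trace)],
              aborted = dm$aborted,
              mean_fom = dm$trace$mean_fom[nrow(dm$trace)]),
    config = {
      # echo the scientific parameters only; paths are environment
      cfg_echo <- config[setdiff(names(config), c("out_dir", "force"))]
      cfg_echo[order(names(cfg_echo))]
    },
    manifest = manifest)
  class(report) <- "workflow_report"
  if (!is.null(out_dir)) {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                             pretty = TRUE, dataframe = "columns")
    writeLines(json, file.path(out_dir, "report.json"))
    utils::write.csv(dm$trace, file.path(out_dir, "dm_trace.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf(
    "workflow: %s, n = %d (axis %.0f, %.0f), placement cor %.3f, s = %.4f, DM ncs_cc %.3f\n",
    x$space_group, x$srf$n, x$srf$theta, x$srf$phi,
    x$placement$score, x$rigid_body$s, x$dm$final_ncs_cc))
  invisible(x)
}

# stage-labelled workflow error (CLI maps ambiguity to exit code 2)
stop_workflow <- function(stage, msg, data = NULL) {
  cond <- structure(
    class = c("cyclophase_workflow_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = NULL,
         stage = stage, data = data))
  stop(cond)
}

#' Compare density-modification protocols
#'
#' Runs [run_dm()] once per candidate configuration on identical inputs and
#' returns the configuration with the highest final average NCS correlation
#' (ties within 1e-3 go to the earlier candidate, with a note).
#'
#' @param refl Starting phase set (as for [run_dm()]).
#' @param candidates List of [dm_config()]s.
#' @param ... Remaining arguments passed to [run_dm()] (ops, em_map,
#'   placement, masks, hist_ref).
#' @return List: `best` (the winning config), `table` (per-candidate final
#'   NCS correlation and cycles), `tie`.
#' @export
choose_dm_protocol <- function(refl, candidates, ...) {
  if (!length(candidates)) stop("no candidate configurations")
  if (length(candidates) == 1)
    return(list(best = candidates[[1]],
                table = data.frame(candidate = 1, ncs_cc = NA, cycles = NA),
                tie = FALSE))
  rows <- list()
  results <- list()
  for (i in seq_along(candidates)) {
    res <- tryCatch(run_dm(refl, candidates[[i]], ...),
                    error = function(e) e)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      candidate = i,
      ncs_cc = if (inherits(res, "error")) NA_real_ else res$ncs_cc,
      cycles = if (inherits(res, "error")) NA_integer_ else nrow(res$trace),
      aborted = if (inherits(res, "error")) TRUE else res$aborted)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$ncs_cc)))
    stop("all candidate protocols failed")
  best_cc <- max(tab$ncs_cc, na.rm = TRUE)
  winners <- which(!is.na(tab$ncs_cc) & tab$ncs_cc >= best_cc - 1e-3)
  tie <- length(winners) > 1
  list(best = candidates[[min(winners)]], table = tab, tie = tie)
}
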