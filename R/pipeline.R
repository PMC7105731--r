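## Orchestration: the 48-condition experiment grid at configurable scale, the
## feature-table assembly, the full statistical analysis bundle (correlations,
## single-variable models, flagged 4-predictor models, VIF screening with
## refit), and a small command-line interface.

.vt_sites <- c("LEFT_HALF", "LOWER_LEFT_QUADRANT",
               "RIGHT_HALF", "LOWER_RIGHT_QUADRANT")

#' Experiment-grid specification
#'
#' The cross of g_Ks multipliers and S2 sites defines the case grid (12 x 4 =
#' 48 by default). The desk-scale preset runs the reduced cell model on a
#' small 2D sheet with conduction velocities and durations scaled down from
#' the full-resolution protocol so that a whole grid completes in minutes;
#' `slab3d` stacks a few layers so filament detection has a thickness to work
#' with. The full-resolution experiment is explicitly not the default.
#'
#' @param multipliers g_Ks multiplier ladder (default [gks_grid()]).
#' @param sites S2 site names (default all four region analogues).
#' @param preset `"sheet2d"` (default) or `"slab3d"`.
#' @param model `"reduced"` (default) or `"detailed"`.
#' @param nx,ny,nz grid dimensions; `nz` defaults to 1 (sheet2d) or 5 (slab3d).
#' @param h node spacing (mm).
#' @param plan a [phase_plan()]; the default is the desk-scale plan (see
#'   Details in the package vignette), not the full-resolution one.
#' @param dt integration step override (ms).
#' @param frame_dt frame cadence (ms).
#' @param out_dir optional directory for per-case results (makes the grid
#'   resumable); `NULL` keeps everything in memory.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(multipliers = gks_grid(), sites = .vt_sites,
                      preset = c("sheet2d", "slab3d"),
                      model = c("reduced", "detailed"),
                      nx = 48, ny = nx, nz = NULL, h = 0.25,
                      plan = NULL, dt = NULL, frame_dt = 10, out_dir = NULL) {
  preset <- match.arg(preset)
  model <- match.arg(model)
  stopifnot(all(multipliers > 0), length(multipliers) >= 1,
            all(sites %in% .vt_sites), length(sites) >= 1)
  if (anyDuplicated(multipliers) || anyDuplicated(sites))
    stop("multipliers and sites must be unique (case ids would collide)")
  if (is.null(nz)) nz <- if (preset == "slab3d") 5L else 1L
  if (preset == "sheet2d" && nz != 1) stop("sheet2d preset requires nz = 1")
  if (preset == "slab3d" && nz < 3) stop("slab3d preset requires nz >= 3")
  if (is.null(plan)) plan <- .desk_plan()
  structure(list(multipliers = multipliers, sites = sites, preset = preset,
                 model = model, nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), h = h, plan = plan, dt = dt,
                 frame_dt = frame_dt, out_dir = out_dir),
            class = "grid_spec")
}

# Desk-scale two-phase plan: conduction velocities scaled so that the
# reentrant wavelength (CV x APD, up to ~10 mm at multiplier 1) fits the
# default 12 mm sheet in both phases, and durations long enough for S2 to
# fire (~1.5 s into generation) and for >= 2 s of maintenance signal (the
# dominant-frequency minimum). Chosen empirically: at maintenance CV above
# ~7 cm/s the spiral detaches from the small sheet for some multipliers.
.desk_plan <- function() {
  phase_plan(gen_cv = 5, gen_duration = 3000,
             maint_cv = 6.5, maint_duration = 3000)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", length(x$multipliers), " multipliers x ",
      length(x$sites), " sites = ", length(x$multipliers) * length(x$sites),
      " cases; ", x$preset, ", ", x$model, " model, ",
      x$nx, "x", x$ny, "x", x$nz, " @ ", x$h, " mm\n", sep = "")
  invisible(x)
}

# canonical case ordering: g_Ks ascending within S2 site (the documented
# ordering convention behind the Durbin-Watson statistic)
.grid_cases <- function(spec) {
  cases <- expand.grid(gks_mult = sort(spec$multipliers), s2_site = spec$sites,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cases <- cases[order(match(cases$s2_site, spec$sites), cases$gks_mult), ]
  cases$case <- sprintf("g%03d_%s", cases$gks_mult, cases$s2_site)
  rownames(cases) <- NULL
  cases[c("case", "gks_mult", "s2_site")]
}

# one grid case: generation -> checkpoint -> maintenance -> metrics ->
# mechanics -> one feature row
.run_case <- function(spec, gks_mult, s2_site, D_gen, D_maint) {
  params <- cell_params(spec$model, gKs_mult = gks_mult)
  g_gen <- tissue_grid(spec$nx, spec$ny, spec$nz, h = spec$h, D = D_gen)
  g_mnt <- tissue_grid(spec$nx, spec$ny, spec$nz, h = spec$h, D = D_maint)
  plan <- spec$plan
  gen <- run_s1s2(g_gen, params, stimulus_protocol(s2_site = s2_site),
                  plan = plan, dt = spec$dt, frame_dt = spec$frame_dt)
  mnt <- run_maintenance(gen$checkpoint, g_mnt, params,
                         duration = plan$maint_duration, dt = spec$dt,
                         frame_dt = spec$frame_dt)
  movie <- mnt$movie
  tension <- run_crossbridge(movie)
  act <- activation_from_tension(tension)
  circ <- run_circulation(act$yv, act$times)
  case_metrics(movie, tension = tension, vlv = circ)
}

#' Run the experiment grid
#'
#' Executes every case of the grid (generation phase, checkpoint, maintenance
#' phase, electrical metrics, cross-bridge tension, circulation) and
#' assembles the feature table. The diffusion coefficient is calibrated once
#' per phase at multiplier 1 (the reduced model's conduction velocity is
#' insensitive to its repolarization time scale, and the detailed model's to
#' g_Ks). Per-case failures are logged in the manifest and yield NA metrics,
#' never a silent gap; the run is deterministic, and with `out_dir` set it is
#' resumable (finished cases are skipped on rerun).
#'
#' @param spec a [grid_spec()].
#' @param progress print one line per case.
#' @return list with `table` (the feature table data frame, columns `case,
#'   gks_mult, s2_site, apd_ms, df_hz, ps_count, filament_count, sv_ml,
#'   amptens_kpa`) and `manifest` (per-case status, error string, wall-clock
#'   seconds, and the calibrated diffusion coefficients as attributes).
#' @export
run_grid <- function(spec, progress = interactive()) {
  stopifnot(inherits(spec, "grid_spec"))
  cases <- .grid_cases(spec)
  if (!is.null(spec$out_dir) && !dir.exists(spec$out_dir))
    dir.create(spec$out_dir, recursive = TRUE)
  p1 <- cell_params(spec$model, gKs_mult = 1)
  D_gen <- as.numeric(calibrate_diffusion(p1, spec$plan$gen_cv, h = spec$h,
                                          dt = spec$dt))
  D_maint <- as.numeric(calibrate_diffusion(p1, spec$plan$maint_cv, h = spec$h,
                                            dt = spec$dt))
  rows <- vector("list", nrow(cases))
  status <- character(nrow(cases)); err <- character(nrow(cases))
  secs <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    id <- cases$case[i]
    cache <- if (!is.null(spec$out_dir)) file.path(spec$out_dir,
                                                   paste0(id, ".rds")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      saved <- readRDS(cache)
      rows[[i]] <- saved$row; status[i] <- saved$status
      err[i] <- saved$error; secs[i] <- saved$seconds
      if (progress) message("[", id, "] cached (", saved$status, ")")
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      .run_case(spec, cases$gks_mult[i], cases$s2_site[i], D_gen, D_maint),
      error = function(e) e)
    secs[i] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      status[i] <- "failed"; err[i] <- conditionMessage(res)
      res <- data.frame(apd = NA_real_, df = NA_real_, ps = NA_real_,
                        filament = NA_real_, sv = NA_real_,
                        amptens = NA_real_)
    } else {
      fails <- attr(res, "failures")
      status[i] <- if (length(fails)) "partial" else "ok"
      err[i] <- paste(fails, collapse = "; ")
    }
    rows[[i]] <- res
    if (!is.null(cache))
      saveRDS(list(row = res, status = status[i], error = err[i],
                   seconds = secs[i]), cache)
    if (progress)
      message(sprintf("[%s] %s (%.1f s)%s", id, status[i], secs[i],
                      if (nzchar(err[i])) paste0(" - ", err[i]) else ""))
  }
  m <- do.call(rbind, rows)
  table <- data.frame(case = cases$case, gks_mult = cases$gks_mult,
                      s2_site = cases$s2_site,
                      apd_ms = m$apd, df_hz = m$df, ps_count = m$ps,
                      filament_count = m$filament, sv_ml = m$sv,
                      amptens_kpa = m$amptens, stringsAsFactors = FALSE)
  manifest <- data.frame(case = cases$case, gks_mult = cases$gks_mult,
                         s2_site = cases$s2_site, status = status,
                         error = err, seconds = round(secs, 2),
                         stringsAsFactors = FALSE)
  attr(manifest, "D_gen") <- D_gen
  attr(manifest, "D_maint") <- D_maint
  list(table = table, manifest = manifest)
}

#' Write / read a feature table as CSV
#'
#' Fixed header `case,gks_mult,s2_site,apd_ms,df_hz,ps_count,filament_count,
#' sv_ml,amptens_kpa`.
#' @param table feature table data frame.
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("case", "gks_mult", "s2_site", "apd_ms", "df_hz", "ps_count",
            "filament_count", "sv_ml", "amptens_kpa")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(table[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("case", "gks_mult", "s2_site", "apd_ms", "df_hz", "ps_count",
            "filament_count", "sv_ml", "amptens_kpa")
  miss <- setdiff(cols, names(d))
  if (length(miss)) stop("not a feature table; missing column(s): ",
                         paste(miss, collapse = ", "))
  d[cols]
}

# feature-table columns (external names) -> analysis variable names
.ft_to_vars <- c(apd_ms = "apd", df_hz = "df", ps_count = "ps",
                 filament_count = "filament", sv_ml = "sv",
                 amptens_kpa = "amptens")

# VIF of every predictor straight from the predictor correlation matrix,
# robust to a singular full matrix (each leave-one-in auxiliary solve is 3x3)
.vif_from_r <- function(Rxx) {
  p <- ncol(Rxx)
  vapply(seq_len(p), function(j) {
    r2j <- tryCatch(
      drop(t(Rxx[-j, j]) %*% solve(Rxx[-j, -j], Rxx[-j, j])),
      error = function(e) NA_real_)
    1 / (1 - r2j)
  }, numeric(1))
}

#' Analyze a feature table (or summary statistics)
#'
#' Replicates the full regression workflow on the electrical-instability
#' features: the Pearson correlation matrix, all single-predictor models of
#' stroke volume and tension amplitude, the 4-predictor models (computed but
#' flagged as collinear when any VIF exceeds 10 - expected, since APD and DF
#' are nearly perfectly anticorrelated), and the screened 3-predictor models
#' obtained by dropping the predictor with the highest VIF and refitting.
#' Raw tables are fitted by [ols_fit()] (with Durbin-Watson in the canonical
#' g_Ks-ascending-within-site ordering); [summary_stats()] inputs are fitted
#' by [fit_from_summary()]. When the input is the packaged printed summary,
#' the bundle also carries the [reproduce_printed_stats()] comparison.
#'
#' @param x a feature table data frame (>= 10 complete rows) or a
#'   [summary_stats()] object.
#' @param vif_threshold collinearity screening threshold.
#' @return an object of class `vt_analysis`: list with `summary`,
#'   `single` (list of `vt_fit`), `full` (4-predictor fits + `flagged`,
#'   `vif`), `screened` (dropped predictor + refits), `dropped`, `notes`,
#'   and optionally `reproduction`.
#' @export
analyze <- function(x, vif_threshold = 10) {
  notes <- character(0)
  predictors <- c("apd", "df", "ps", "filament")
  responses <- c("sv", "amptens")
  if (inherits(x, "vt_summary_stats")) {
    s <- x
    fit1 <- function(response, preds) fit_from_summary(s, response, preds)
    if (isTRUE(all.equal(x, printed_summary())))
      repro <- reproduce_printed_stats() else repro <- NULL
  } else {
    stopifnot(is.data.frame(x))
    tab <- x
    # accept external column names as produced by run_grid
    hit <- intersect(names(.ft_to_vars), names(tab))
    names(tab)[match(hit, names(tab))] <- .ft_to_vars[hit]
    # canonical ordering when the design columns are present
    if (all(c("s2_site", "gks_mult") %in% names(tab)))
      tab <- tab[order(match(tab$s2_site, .vt_sites), tab$gks_mult), ]
    vars <- intersect(.vt_vars, names(tab))
    all_na <- vars[vapply(tab[vars], function(v) all(is.na(v)), logical(1))]
    if (length(all_na)) {
      notes <- c(notes, paste("variable(s) with no data dropped:",
                              paste(all_na, collapse = ", ")))
      vars <- setdiff(vars, all_na)
    }
    tab <- tab[stats::complete.cases(tab[vars]), ]
    if (nrow(tab) < 10) stop("need at least 10 complete cases")
    predictors <- intersect(predictors, vars)
    responses <- intersect(responses, vars)
    if (length(predictors) < 2 || !length(responses))
      stop("feature table lacks the analysis variables")
    tab <- tab[vars]
    s <- pearson_matrix(tab)
    fit1 <- function(response, preds) ols_fit(tab, response, preds)
    repro <- NULL
  }
  single <- list()
  for (resp in responses)
    for (pred in predictors)
      single[[paste(resp, pred, sep = "~")]] <- fit1(resp, pred)
  Rxx <- s$r[predictors, predictors, drop = FALSE]
  vif_all <- stats::setNames(.vif_from_r(Rxx), predictors)
  full <- list(vif = vif_all, flagged = any(vif_all > vif_threshold,
                                            na.rm = TRUE))
  for (resp in responses)
    full[[resp]] <- tryCatch(fit1(resp, predictors), error = function(e) {
      notes <<- c(notes, paste0("4-predictor model for ", resp,
                                " not fittable: ", conditionMessage(e)))
      NULL
    })
  screened <- NULL; dropped <- NULL
  if (isTRUE(full$flagged) && length(predictors) > 2) {
    dropped <- predictors[which.max(vif_all)]
    keep <- setdiff(predictors, dropped)
    screened <- list(dropped = dropped, predictors = keep)
    for (resp in responses) screened[[resp]] <- fit1(resp, keep)
    notes <- c(notes, paste0("collinearity screening: dropped '", dropped,
                             "' (VIF = ", signif(max(vif_all, na.rm = TRUE), 4),
                             " > ", vif_threshold, "), refit with ",
                             paste(keep, collapse = " + ")))
  } else {
    notes <- c(notes, paste0("no predictor dropped (all VIF <= ",
                             vif_threshold, ")"))
  }
  structure(list(summary = s, single = single, full = full,
                 screened = screened, dropped = dropped,
                 reproduction = repro, notes = notes),
            class = "vt_analysis")
}

#' @export
print.vt_analysis <- function(x, ...) {
  cat("== correlation structure ==\n"); print(x$summary)
  cat("\n== single-predictor models ==\n")
  for (f in x$single) print(f)
  cat("\n== 4-predictor models (flagged =", x$full$flagged, ") ==\n")
  cat("VIF:", paste(names(x$full$vif), signif(x$full$vif, 4), sep = "=",
                    collapse = "  "), "\n")
  for (nm in intersect(c("sv", "amptens"), names(x$full)))
    if (!is.null(x$full[[nm]])) print(x$full[[nm]])
  if (!is.null(x$screened)) {
    cat("\n== screened models (dropped:", x$screened$dropped, ") ==\n")
    for (nm in intersect(c("sv", "amptens"), names(x$screened)))
      print(x$screened[[nm]])
  }
  if (!is.null(x$reproduction)) {
    cat("\n== printed-table reproduction ==\n"); print(x$reproduction)
  }
  if (length(x$notes)) cat("\nnotes:\n", paste("-", x$notes, collapse = "\n"),
                           "\n")
  invisible(x)
}

# vt_fit -> plain list for JSON serialization
.fit_to_list <- function(f) {
  list(response = f$response, predictors = as.list(f$predictors), n = f$n,
       method = f$method, coefficients = f$coefficients,
       intercept = as.list(f$intercept), model = f$model)
}

#' Write an analysis bundle as JSON
#'
#' @param analysis a `vt_analysis` from [analyze()].
#' @param path file path.
#' @export
write_analysis_json <- function(analysis, path) {
  a <- analysis
  out <- list(
    n = a$summary$n,
    mean = as.list(a$summary$mean), sd = as.list(a$summary$sd),
    correlation = a$summary$r,
    single = lapply(a$single, .fit_to_list),
    full = list(vif = as.list(a$full$vif), flagged = a$full$flagged,
                fits = lapply(Filter(Negate(is.null),
                                     a$full[intersect(c("sv", "amptens"),
                                                      names(a$full))]),
                              .fit_to_list)),
    dropped = a$dropped,
    screened = if (is.null(a$screened)) NULL else
      lapply(a$screened[intersect(c("sv", "amptens"), names(a$screened))],
             .fit_to_list),
    notes = a$notes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

## ------------------------------------------------------------------------
## Command-line interface

.cli_usage <- function() {
  paste(
    "usage: vt_cli <subcommand> [options]",
    "",
    "subcommands:",
    "  reproduce                 recompute the printed regression tables from",
    "                            the packaged summary statistics",
    "  grid [--dry-run] [--out DIR] [--config FILE]",
    "                            run (or list) the experiment grid",
    "  synth spiral|scroll|plane|table [--seed N] [--out FILE]",
    "                            write a synthetic fixture",
    "  stats --table FILE [--out FILE]",
    "                            analyze a feature-table CSV",
    "  simulate --out FILE       run one desk-scale reentry case, save movie",
    "  metrics --movie FILE      per-case electrical metrics of a saved movie",
    "  mechanics --movie FILE    tension/circulation metrics of a saved movie",
    sep = "\n")
}

# tiny flag parser: --name value and bare --flag
.cli_parse <- function(argv, flags, switches = character(0)) {
  out <- list(.pos = character(0))
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      nm <- substring(a, 3)
      if (nm %in% switches) { out[[nm]] <- TRUE; i <- i + 1 }
      else if (nm %in% flags) {
        if (i == length(argv)) stop("missing value for --", nm)
        out[[nm]] <- argv[i + 1]; i <- i + 2
      } else stop("unknown flag: --", nm)
    } else { out$.pos <- c(out$.pos, a); i <- i + 1 }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands listed by the usage message. Returns an exit
#' code instead of quitting so the interface is callable (and testable) in
#' an R session: 0 success, 1 usage error, 2 runtime failure.
#'
#' @param argv character vector of arguments, e.g. `commandArgs(TRUE)`.
#' @return integer exit code, invisibly.
#' @export
vt_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(argv)) { cat(.cli_usage(), "\n"); return(invisible(1L)) }
    sub <- argv[1]; rest <- argv[-1]
    switch(sub,
      reproduce = { print(reproduce_printed_stats()); 0L },
      grid = .cli_grid(rest),
      synth = .cli_synth(rest),
      stats = .cli_stats(rest),
      simulate = .cli_simulate(rest),
      metrics = .cli_metrics(rest, mechanics = FALSE),
      mechanics = .cli_metrics(rest, mechanics = TRUE),
      { cat("unknown subcommand: ", sub, "\n", .cli_usage(), "\n", sep = "")
        1L })
  },
  error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^(unknown flag|missing value|usage)", msg)) {
      cat(msg, "\n", .cli_usage(), "\n", sep = ""); 1L
    } else { cat("error: ", msg, "\n", sep = ""); 2L }
  })
  invisible(code)
}

# grid spec from an optional YAML config file
.cli_grid_spec <- function(opt) {
  args <- list()
  if (!is.null(opt$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for --config")
    args <- yaml::read_yaml(opt$config)
  }
  if (!is.null(opt$out)) args$out_dir <- opt$out
  if (isTRUE(opt$detailed)) args$model <- "detailed"
  do.call(grid_spec, args)
}

.cli_grid <- function(rest) {
  opt <- .cli_parse(rest, flags = c("out", "config"),
                    switches = c("dry-run", "detailed"))
  names(opt)[names(opt) == "dry-run"] <- "dry_run"
  spec <- .cli_grid_spec(opt)
  cases <- .grid_cases(spec)
  if (isTRUE(opt$dry_run)) {
    cat(nrow(cases), "planned cases:\n")
    for (i in seq_len(nrow(cases))) cat("  ", cases$case[i], "\n", sep = "")
    return(0L)
  }
  res <- run_grid(spec, progress = TRUE)
  out_dir <- spec$out_dir %||% "."
  write_feature_table(res$table, file.path(out_dir, "features.csv"))
  write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  cat("wrote ", file.path(out_dir, "features.csv"), " (",
      nrow(res$table), " cases, ", sum(res$manifest$status == "ok"),
      " ok)\n", sep = "")
  0L
}

.cli_synth <- function(rest) {
  if (!length(rest)) stop("usage: synth spiral|scroll|plane|table [--seed N]")
  what <- rest[1]
  opt <- .cli_parse(rest[-1], flags = c("seed", "out"))
  seed <- as.integer(opt$seed %||% 1)
  cores <- data.frame(x0 = 6, y0 = 6, chirality = 1)
  out <- switch(what,
    spiral = list(path = opt$out %||% "spiral.rds",
                  obj = gen_spiral_movie(c(49, 49), 0.25, cores,
                                         period = 100 + seed)),
    scroll = list(path = opt$out %||% "scroll.rds",
                  obj = gen_scroll_movie(c(49, 49), 0.25, cores,
                                         period = 100 + seed, nz = 5)),
    plane = list(path = opt$out %||% "plane.rds",
                 obj = gen_plane_wave_movie(68.5, c(120, 3))),
    table = list(path = opt$out %||% "table.csv",
                 obj = gen_correlated_table(48, seed = seed)),
    stop("usage: unknown synth kind: ", what))
  if (what == "table") {
    write.csv(out$obj, out$path, row.names = FALSE)
  } else saveRDS(out$obj, out$path)
  cat("wrote ", out$path, "\n", sep = "")
  0L
}

.cli_stats <- function(rest) {
  opt <- .cli_parse(rest, flags = c("table", "out"))
  if (is.null(opt$table)) stop("usage: stats requires --table FILE")
  tab <- utils::read.csv(opt$table, stringsAsFactors = FALSE)
  a <- analyze(tab)
  print(a)
  if (!is.null(opt$out)) write_analysis_json(a, opt$out)
  0L
}

.cli_simulate <- function(rest) {
  opt <- .cli_parse(rest, flags = c("out", "seed"))
  if (is.null(opt$out)) stop("usage: simulate requires --out FILE")
  spec <- grid_spec()
  params <- cell_params(spec$model, gKs_mult = 8)
  D <- as.numeric(calibrate_diffusion(params, spec$plan$gen_cv, h = spec$h))
  g <- tissue_grid(spec$nx, spec$ny, spec$nz, h = spec$h, D = D)
  r <- run_s1s2(g, params, plan = spec$plan,
                seed = as.integer(opt$seed %||% 1))
  save_movie(r$movie, opt$out)
  cat("wrote ", opt$out, " (S2 fired at ", r$s2_time, " ms)\n", sep = "")
  0L
}

.cli_metrics <- function(rest, mechanics) {
  opt <- .cli_parse(rest, flags = c("movie", "out"))
  if (is.null(opt$movie)) stop("usage: requires --movie FILE")
  movie <- load_movie(opt$movie)
  if (mechanics) {
    tension <- run_crossbridge(movie)
    act <- activation_from_tension(tension)
    circ <- run_circulation(act$yv, act$times)
    sv <- stroke_volume(circ$vlv, circ$time, aortic_flow = circ$qao)
    cat(sprintf("amptens_kpa = %.6g\nsv_ml = %.6g\n",
                amp_tens(tension), sv$sv))
  } else {
    row <- case_metrics(movie)
    cat(sprintf("apd_ms = %.6g\ndf_hz = %.6g\nps_count = %.6g\n",
                row$apd, row$df, row$ps))
    if (movie$dims[3] > 1) cat(sprintf("filament_count = %.6g\n", row$filament))
  }
  0L
}
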