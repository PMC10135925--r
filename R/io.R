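# Columnar readers/writers. All units are fixed SI (documented in the
# column docs); no unit inference — CFD exports are chronically ambiguous,
# so the contract is strict.

#' Read a flow-field export
#'
#' Reads a CSV/TSV per-cell field export with header columns
#' `volume,k,omega` and optionally `epsilon` and the nine velocity-gradient
#' columns `dudx,dudy,dudz,dvdx,dvdy,dvdz,dwdx,dwdy,dwdz`; SI units
#' throughout. Gzip-compressed files are accepted transparently.
#'
#' @param path File path.
#' @param total_volume Declared liquid volume, m^3; default `sum(volume)`.
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param units_check Log a warning when the implied Kolmogorov lengths fall
#'   outside the plausible 1e-6 to 1e-2 m band (a typical sign of wrong
#'   units), default TRUE.
#' @param fluid Fluid used for the units check.
#' @return A [flow_field()].
#' @export
read_flowfield <- function(path, total_volume = NULL, sep = ",",
                           units_check = TRUE, fluid = fluid_properties()) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("volume")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  has_ko <- all(c("k", "omega") %in% names(df))
  has_eps <- "epsilon" %in% names(df)
  if (!has_ko && !has_eps)
    stop("need either columns k and omega, or column epsilon")
  numcols <- intersect(c("volume", "k", "omega", "epsilon"), names(df))
  for (cn in numcols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop("non-numeric value in column '", cn, "' at data row ", bad[1L])
    df[[cn]] <- as.numeric(df[[cn]])
  }
  gcols <- c("dudx", "dudy", "dudz", "dvdx", "dvdy", "dvdz",
             "dwdx", "dwdy", "dwdz")
  grad <- if (all(gcols %in% names(df))) as.matrix(df[gcols]) else NULL
  field <- flow_field(volume = df$volume,
                      k = if (has_ko) df$k,
                      omega = if (has_ko) df$omega,
                      epsilon = if (has_eps) df$epsilon,
                      grad_v = grad,
                      total_volume = total_volume)
  if (units_check) {
    eps <- field_epsilon(field)
    lam <- suppressWarnings(
      kolmogorov_length(fluid$kinematic_viscosity, eps))
    fin <- lam[is.finite(lam)]
    if (length(fin) && (min(fin) < 1e-6 || max(fin) > 1e-2))
      warning("implied Kolmogorov lengths outside 1e-6 to 1e-2 m; check that the export is in SI units")
  }
  field
}

#' Write a flow field to CSV
#'
#' Emits the same dialect [read_flowfield()] consumes (round-trip safe).
#'
#' @param field A [flow_field()].
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_flowfield <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  df <- data.frame(volume = field$volume)
  if (!is.null(field$k)) df$k <- field$k
  if (!is.null(field$omega)) df$omega <- field$omega
  if (!is.null(field$epsilon)) df$epsilon <- field$epsilon
  if (!is.null(field$grad_v)) {
    g <- as.data.frame(field$grad_v)
    names(g) <- c("dudx", "dudy", "dudz", "dvdx", "dvdy", "dvdz",
                  "dwdx", "dwdy", "dwdz")
    df <- cbind(df, g)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read cluster-size counts from CSV
#'
#' Expects columns `size,count`.
#'
#' @param path File path.
#' @return A [cluster_counts()].
#' @export
read_cluster_counts <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("size", "count") %in% names(df)))
    stop("cluster-count file needs columns size,count")
  cluster_counts(df$size, df$count)
}

#' Read a mesh series from CSV
#'
#' Expects columns `cells,qoi` and optionally `mesh` labels.
#'
#' @param path File path.
#' @param safety_factor GCI safety factor, default 1.25.
#' @return A [mesh_series()].
#' @export
read_mesh_series <- function(path, safety_factor = 1.25) {
  df <- utils::read.csv(path)
  if (!all(c("cells", "qoi") %in% names(df)))
    stop("mesh-series file needs columns cells,qoi")
  mesh_series(df$cells, df$qoi,
              labels = if ("mesh" %in% names(df)) df$mesh,
              safety_factor = safety_factor)
}

#' Read a growth series from CSV
#'
#' Expects columns `time_h,vcd` and optionally `viability`.
#'
#' @param path File path.
#' @return A [growth_series()].
#' @export
read_growth_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "vcd") %in% names(df)))
    stop("growth file needs columns time_h,vcd")
  growth_series(df$time_h, df$vcd,
                viability = if ("viability" %in% names(df)) df$viability)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in their natural order - flow field to
#' hydrodynamic statistics, mesh series to GCI verdict, operating-point
#' correlations, cluster counts to the geometric fit, and the in-silico
#' aggregate prediction from the field's mean Kolmogorov length - and
#' returns a single JSON-serialisable report. Every stage is optional:
#' supply only the inputs you have.
#'
#' @param config A named list (e.g. from [yaml::read_yaml()]) with any of:
#'   `flowfield` (path, or a [flow_field()]), `total_volume`,
#'   `lambda_thresholds`, `mesh_series` (path or object), `clusters`
#'   (path or object), `shaken` / `stirred` (argument lists for
#'   [shaken_spec()] / [stirred_spec()] without the fluid), `oxygen`
#'   (argument list for [oxygen_spec()]), `growth` (path or object),
#'   `fluid` (argument list for [fluid_properties()]), `link`
#'   (list with intercept, slope), `seed`.
#' @param output Optional path: the report is additionally written as JSON.
#' @return The report (a nested list) invisibly when `output` is given,
#'   otherwise visibly.
#' @export
run_pipeline <- function(config, output = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fluid <- stage("fluid", do.call(fluid_properties,
                                  config$fluid %||% list()))
  if (!is.null(config$seed)) set.seed(config$seed)
  report <- list(provenance = list(
    package = "kolmoagg",
    version = as.character(utils::packageVersion("kolmoagg")),
    seed = config$seed,
    inputs = Filter(is.character, config)))

  field <- NULL
  if (!is.null(config$flowfield)) {
    field <- stage("flowfield", {
      if (inherits(config$flowfield, "flow_field")) config$flowfield
      else read_flowfield(config$flowfield,
                          total_volume = config$total_volume,
                          fluid = fluid)
    })
    report$hydro <- stage("hydro", hydro_report(
      field, fluid,
      lambda_thresholds = as.numeric(config$lambda_thresholds %||% numeric()),
      n = config$n, torque = config$torque))
  }
  if (!is.null(config$mesh_series)) {
    ms <- stage("gci", {
      if (inherits(config$mesh_series, "mesh_series")) config$mesh_series
      else read_mesh_series(config$mesh_series,
                            safety_factor = config$safety_factor %||% 1.25)
    })
    g <- stage("gci", analyze_gci(ms))
    report$gci <- list(cases = as.data.frame(g),
                       asymptotic = attr(g, "asymptotic"),
                       recommended_mesh = attr(g, "recommended_mesh"))
  }
  if (!is.null(config$shaken)) {
    report$shaken <- stage("shaken", {
      sp <- do.call(shaken_spec, c(config$shaken, list(fluid = fluid)))
      ph <- phase_number(sp)
      c(ph, list(power_per_volume = buchs_power_unbaffled(sp,
                                                          check_phase = FALSE)))
    })
  }
  if (!is.null(config$stirred)) {
    report$stirred <- stage("stirred", {
      sp <- do.call(stirred_spec, c(config$stirred, list(fluid = fluid)))
      vt <- tip_speed(sp$stirrer_speed, sp$stirrer_diameter)
      pv <- maschke_power(vt)
      list(reynolds = reynolds_stirred(sp), tip_speed = vt,
           power_per_volume = pv,
           newton = newton_number(pv * sp$fill_volume, sp))
    })
  }
  if (!is.null(config$oxygen)) {
    report$oxygen <- stage("oxygen", {
      ox <- do.call(oxygen_spec, config$oxygen)
      list(max_supported_vcd = max_supported_vcd(ox))
    })
  }
  if (!is.null(config$clusters)) {
    report$aggregates <- stage("aggregates", {
      cc <- if (inherits(config$clusters, "cluster_counts")) config$clusters
      else read_cluster_counts(config$clusters)
      fit <- geom_cluster_fit(cc)
      list(p_singles_cell = fit$estimates[["per_cell"]],
           p_singles_cluster = fit$estimates[["per_cluster"]],
           p_mle = fit$estimates[["mle"]],
           chi2 = fit$gof_chi2, g_test = fit$gof_g)
    })
  }
  if (!is.null(config$growth)) {
    report$growth <- stage("growth", {
      gs <- if (inherits(config$growth, "growth_series")) config$growth
      else read_growth_series(config$growth)
      c(mu_max(gs), vcd_max(gs))
    })
  }
  if (!is.null(field)) {
    link <- stage("prediction", {
      if (is.null(config$link)) lambda_link()
      else lambda_link(intercept = config$link$intercept,
                       slope = config$link$slope)
    })
    lam <- report$hydro$lambda_mean
    report$prediction <- stage("prediction", list(
      lambda_mean = lam,
      p = suppressWarnings(predict_p(lam, link)),
      distribution = predict_distribution(lam, link,
                                          n_max = config$n_max %||% 10L)))
  }
  if (!is.null(output)) {
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
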