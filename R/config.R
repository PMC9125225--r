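# Self-describing system configurations (JSON) and the one-shot report
# runner behind the command-line interface.

#' Read a system configuration from JSON
#'
#' Two dialects are accepted.  A builtin reference,
#' `{"builtin": "fig1" | "example2" | "walker", "args": {...}}`, loads
#' the corresponding packaged fixture.  Otherwise the file must describe
#' the system explicitly:
#' `coordinates` (list of `{name, size}`), `reservoirs` (list of
#' `{name, puppets, leaders, rates}` where `rates` is either
#' `{"mode": "explicit", "matrix": [[...]]}` with a destination-puppet by
#' source-leader matrix, or `{"mode": "random", "seed": n, "scale": s}`),
#' an optional `protocol` (list of `{t0, t1, scale}` segments scaling all
#' rates), `units` (list of coordinate-name lists), `initial`
#' (`{"mode": "uniform"}`, `{"mode": "delta", "state": [...]}` or
#' `{"mode": "probs", "probs": [...]}`), `time` (`{ti, tf}`), and an
#' optional `n_steps`.
#'
#' @param path path to the JSON file.
#' @return a `fixture_bundle`.
#' @export
read_system_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(cfg$builtin)) {
    builder <- switch(cfg$builtin,
                      fig1 = build_fig1, example2 = build_example2,
                      walker = build_walker,
                      stop("unknown builtin fixture '", cfg$builtin, "'"))
    args <- lapply(cfg$args %||% list(),
                   function(a) if (is.list(a)) unlist(a) else a)
    return(do.call(builder, args))
  }
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("config is missing '", field, "'")
    cfg[[field]]
  }
  coords <- need("coordinates")
  sizes <- stats::setNames(
    vapply(coords, function(co) as.integer(co$size), 0L),
    vapply(coords, function(co) as.character(co$name), ""))
  sp <- joint_space(sizes)
  protocol <- cfg$protocol
  mk_rates <- function(rspec, puppets, leaders) {
    base <- switch(rspec$mode %||% stop("rates need a 'mode'"),
      explicit = {
        M <- do.call(rbind, lapply(rspec$matrix, as.numeric))
        psub <- subspace(sp, puppets); lsub <- subspace(sp, leaders)
        if (!all(dim(M) == c(psub$n, lsub$n)))
          stop("explicit rate matrix must be ", psub$n, " x ", lsub$n,
               " (destination puppet x source leader)")
        M
      },
      random = {
        set.seed(as.integer(rspec$seed %||% 1))
        random_local_rates(sp, puppets, leaders,
                           as.numeric(rspec$scale %||% 1))
      },
      stop("unknown rates mode '", rspec$mode, "'"))
    if (is.null(protocol)) return(base)
    lapply(protocol, function(sg)
      list(t0 = as.numeric(sg$t0), t1 = as.numeric(sg$t1),
           rates = base * as.numeric(sg$scale %||% 1)))
  }
  rs <- lapply(need("reservoirs"), function(rv) {
    pu <- as.character(unlist(rv$puppets))
    le <- as.character(unlist(rv$leaders))
    reservoir(as.character(rv$name), pu, le, mk_rates(rv$rates, pu, le))
  })
  sys <- composite_system(sp, rs)
  nstar <- unit_structure(lapply(need("units"),
                                 function(u) as.character(unlist(u))),
                          coordinates = sp$names)
  ini <- need("initial")
  p0 <- switch(ini$mode %||% "uniform",
    uniform = uniform_distribution(sp),
    delta = delta_distribution(sp, as.integer(unlist(ini$state))),
    probs = distribution(sp, as.numeric(unlist(ini$probs)),
                         normalize = isTRUE(ini$normalize)),
    stop("unknown initial mode '", ini$mode, "'"))
  tm <- need("time")
  bundle <- new_bundle(sys, nstar, p0, as.numeric(tm$ti),
                       as.numeric(tm$tf), expected = list())
  bundle$n_steps <- as.integer(cfg$n_steps %||% 400)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full validate-evolve-report pipeline from a config file
#'
#' Validates the reservoirs and the unit structure, integrates the master
#' equation, assembles the thermodynamic report, and writes
#' `report.json` (thermodynamics plus validation flags and a log of
#' seeds/tolerances/version), `timeseries.csv` (EF/EP rate time series
#' per scope), and `graph.dot` (the dependency graph) into `out_dir`.
#' Nothing is written if any step fails.
#'
#' @param config_path path to a config JSON file.
#' @param out_dir output directory (created if needed).
#' @param n_steps override the integration grid size.
#' @param quadrature_tol tolerance passed to [integrate_thermo()].
#' @return invisibly, a list with the bundle, the record, the validation
#'   report, the thermo report, and `ok` (all inequality checks passed).
#' @export
run_report <- function(config_path, out_dir, n_steps = NULL,
                       quadrature_tol = 1e-4) {
  bundle <- read_system_config(config_path)
  sys <- bundle$sys
  viol <- unlist(lapply(sys$reservoirs, validate_reservoir,
                        space = sys$space, times = sample_times(sys)))
  if (length(viol))
    stop("invalid reservoir(s): ", paste(viol, collapse = "; "))
  vrep <- validate_structure(sys, bundle$nstar)
  if (!vrep$flags["units_are_units"])
    stop("declared units fail the marginal-independence check")
  ns <- n_steps %||% bundle$n_steps %||% 400
  rec <- evolve(sys, bundle$p0, bundle$ti, bundle$tf, n_steps = ns)
  trep <- integrate_thermo(sys, rec, bundle$nstar, tol = quadrature_tol)
  ineq <- check_inequalities(trep)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    thermodynamics = jsonlite::fromJSON(jsonlite::toJSON(
      list(Q = as.list(trep$Q), sigma = as.list(trep$sigma),
           Q_N = trep$Q_N, sigma_N = trep$sigma_N,
           I_initial = trep$I_initial, I_final = trep$I_final, B = trep$B,
           residuals = trep$residuals, checks = as.list(trep$checks),
           height = trep$height, bound_guaranteed = trep$bound_guaranteed),
      auto_unbox = TRUE, digits = NA)),
    validation = as.list(vrep$flags),
    inequalities_ok = ineq$all_ok,
    log = list(config = basename(config_path),
               n_steps = ns, quadrature_tol = quadrature_tol,
               package_version = as.character(utils::packageVersion("unitssl")),
               timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_rate_series_csv(sys, rec, bundle$nstar,
                        file.path(out_dir, "timeseries.csv"))
  write_graph_dot(bundle$nstar, file.path(out_dir, "graph.dot"))
  invisible(list(bundle = bundle, record = rec, validation = vrep,
                 thermo = trep, ok = ineq$all_ok))
}
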