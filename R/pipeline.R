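#' Assemble and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) of settings for the end-to-end
#' analysis and fills in documented defaults. Unknown keys trigger a
#' warning, never silent ignoring.
#'
#' @param config path to a YAML file, or a named list, or NULL for all
#'   defaults.
#' @return validated config list of class `nr_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    n_lat = 10L, n_lon = 14L, n_level = 1L,
    seed = 1L,
    total_nh3 = 4.4, total_nox = 3.7,
    total_pop = 3e8,
    levels = c(0.3, 0.6, 0.8, 1.0),
    annual_guideline = 5, daily_guideline = 15, daily_cv = 0.4,
    gemm_file = system.file("extdata", "gemm_params_synthetic.csv",
                            package = "nrpathways"),
    chem = list()  # overrides passed to chem_params()
  )
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) user <- config
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  cfg <- utils::modifyList(defaults, user[intersect(names(user), names(defaults))])
  if (cfg$annual_guideline <= 0 || cfg$daily_guideline <= 0)
    stop("guidelines must be > 0", call. = FALSE)
  if (!file.exists(cfg$gemm_file))
    stop("GEMM parameter file not found: ", cfg$gemm_file, call. = FALSE)
  class(cfg) <- "nr_config"
  cfg
}

stage_msg <- function(stage, t0) {
  message(sprintf("[nrpathways] %-12s done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

run_stage <- function(stage, fun) {
  t0 <- as.numeric(Sys.time())
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_msg(stage, t0)
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end -- synthetic domain and ensemble,
#' exposure metrics, health burden, efficiency/regime diagnostics, pathway
#' optimization -- and writes all stage outputs as CSV plus a JSON
#' provenance manifest into `outdir`. Identical config and seed give
#' byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()] input (path, list or NULL).
#' @param outdir output directory (created if missing).
#' @param n_draws Monte Carlo draws for the health CI (reduced from the
#'   10000 default here to keep full runs fast; pass 10000 for final runs).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("nr_run_"),
                         n_draws = 2000L) {
  cfg <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  dom <- run_stage("domain", function() {
    grid <- generate_domain(cfg$n_lat, cfg$n_lon, cfg$n_level, seed = cfg$seed)
    inv <- generate_emissions(grid, cfg$total_nh3, cfg$total_nox,
                              seed = cfg$seed + 1L)
    params <- do.call(chem_params, cfg$chem)
    ens <- generate_scenario_ensemble(inv, params, cfg$levels)
    tabs <- do.call(rbind, lapply(ens$states, field_table))
    write_fields_csv(tabs, file.path(outdir, "ensemble_fields.csv"))
    list(grid = grid, inv = inv, params = params, ens = ens)
  })
  ens <- dom$ens

  metrics <- run_stage("metrics", function() {
    base <- annual_mean(ens$states$Base)
    nonr <- annual_mean(ens$states$S1R100)
    rows <- list()
    for (reg in c("West", "East", "all")) {
      mm <- vapply(NR_MONTHS, function(m)
        area_weighted_mean(ens$states$Base$pm25[, m, 1], dom$grid$cells$area,
                           if (reg == "all") NULL else dom$grid$cells$region == reg), 0)
      daily <- synth_daily_series(mm, cv = cfg$daily_cv, seed = cfg$seed + 2L)
      rows[[reg]] <- data.frame(
        region = reg,
        n_share = regional_n_share(base, nonr, dom$grid, reg),
        annual_achievement = annual_guideline_achievement(base, dom$grid, reg,
                                                          cfg$annual_guideline),
        daily_exceedance = daily_exceedance_fraction(daily, cfg$daily_guideline))
    }
    tab <- do.call(rbind, rows)
    write_fields_csv(tab, file.path(outdir, "exposure_metrics.csv"))
    tab
  })

  health <- run_stage("health", function() {
    ages <- generate_population_mortality(dom$grid, cfg$total_pop,
                                          seed = cfg$seed + 3L)
    gp <- read_gemm_params(cfg$gemm_file)
    res <- monte_carlo_ci(annual_mean(ens$states$Base),
                          annual_mean(ens$states$S1R100), ages, gp,
                          n_draws = n_draws, seed = cfg$seed + 4L)
    tab <- data.frame(metric = "avoided_deaths_phaseout",
                      deaths = res$deaths, ci_low = res$ci_low,
                      ci_high = res$ci_high, n_draws = res$n_draws)
    write_fields_csv(tab, file.path(outdir, "health_burden.csv"))
    res
  })

  eff <- run_stage("efficiency", function() {
    rows <- list(); tp_rows <- list()
    for (reg in c("West", "East")) {
      curves <- lapply(c(Nr = "Nr", NOx = "NOx", NH3 = "NH3"), function(md) {
        ray <- ensemble_ray(ens, md, region = reg)
        interpolate_levels(ray$level, ray$pm25,
                           base_emi = switch(md, NH3 = sum(dom$inv$e_nh3),
                                             NOx = sum(dom$inv$e_nox),
                                             sum(dom$inv$e_nh3) + sum(dom$inv$e_nox)))
      })
      betas <- lapply(curves, instant_efficiency)
      for (md in names(betas))
        rows[[paste(reg, md)]] <- data.frame(region = reg, mode = md,
                                             level = betas[[md]]$levels,
                                             beta = betas[[md]]$beta)
      tp <- tipping_point(betas$NH3$beta - betas$NOx$beta,
                          criterion = "beta_equal")
      tp_rows[[reg]] <- data.frame(region = reg, criterion = "beta_equal",
                                   reduction = tp$reduction,
                                   unreachable = tp$unreachable)
    }
    write_fields_csv(do.call(rbind, rows), file.path(outdir, "beta_series.csv"))
    write_fields_csv(do.call(rbind, tp_rows),
                     file.path(outdir, "tipping_points.csv"))
    rows
  })

  path <- run_stage("pathway", function() {
    sp <- ens$specs
    pm <- vapply(ens$states, regional_mean, 0, region = "West")
    surf <- fit_response_surface(sp$x, sp$y, unname(pm))
    p <- steepest_descent_path(surf)
    write_fields_csv(cbind(step = seq_len(nrow(p$nodes)) - 1L, p$nodes),
                     file.path(outdir, "optimal_pathway_west.csv"))
    list(surface = surf, path = p)
  })

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(
    package = "nrpathways",
    version = as.character(utils::packageVersion("nrpathways")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = sort(list.files(outdir)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, domain = dom, metrics = metrics,
                 health = health, efficiency = eff, pathway = path,
                 manifest = manifest, outdir = outdir))
}
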