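#' Run the full reconstruction pipeline
#'
#' Orchestrates the stages in dependency order — synthetic-data
#' generation (or user-supplied files), sea-level curve fitting and GIA
#' candidate ranking, paleogeography, demography, vegetation/fire — with
#' per-stage caching and a reproducible run manifest.  Stages communicate
#' only through files in `out_dir`, in the formats of
#' [paleoscape_io].
#'
#' A stage is re-run only when the content hash of its parameters and
#' input files changes; otherwise its cached outputs are reused.  The
#' manifest records the config hash, package version, per-stage output
#' checksums and wall-clock seconds.
#'
#' @param config configuration list (see [demo_config()] for the schema)
#'   or path to a YAML file with the same structure.  Unknown keys are
#'   rejected; every stochastic stage takes its seed from the master
#'   `seed`.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prev <- if (file.exists(file.path(out, "manifest.yaml")))
    yaml::read_yaml(file.path(out, "manifest.yaml")) else NULL
  manifest <- list(config_hash = object_hash(cfg),
                   package_version = as.character(
                     utils::packageVersion("paleoscape")),
                   stages = list())
  seed <- cfg$seed

  run_stage <- function(name, params, inputs, outputs, expr) {
    h <- object_hash(list(params, unname(tools::md5sum(inputs))))
    cached <- !is.null(prev$stages[[name]]) &&
      identical(prev$stages[[name]]$hash, h) &&
      all(file.exists(outputs))
    t0 <- proc.time()[["elapsed"]]
    if (!cached) eval.parent(substitute(expr))
    manifest$stages[[name]] <<- list(
      hash = h, cached = cached,
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = as.list(tools::md5sum(outputs)))
    message(sprintf("[paleoscape] stage %-10s %s (%.1fs)", name,
                    if (cached) "cached" else "run",
                    manifest$stages[[name]]$seconds))
  }

  paths <- list(slips = file.path(out, "slips.csv"),
                dem = file.path(out, "dem.asc"),
                tides = file.path(out, "tides.csv"),
                calcurve = file.path(out, "calcurve.csv"),
                dates = file.path(out, "dates.csv"),
                monuments = file.path(out, "monuments.csv"),
                pollen = file.path(out, "pollen.csv"),
                candidates = file.path(out, "candidates"))

  ## ---- synth ----------------------------------------------------------
  if (isTRUE(cfg$synth$enabled)) {
    sp <- cfg$synth
    run_stage("synth", list(sp, seed), character(0), unlist(paths[1:7]), {
        truth <- scilly_like_truth(n_gradient = sp$n_pollen)
        write_slips(sample_slips(truth, sp$n_slips, sp$age_sd, sp$elev_sd,
                                 sp$limiting_fraction, seed = seed),
                    paths$slips)
        write_ascii_grid(make_dem(default_island_shape(),
                                  cell_size = sp$dem_cell_size,
                                  seed = seed), paths$dem)
        write_tides(make_tide_history(0:9), paths$tides)
        cc <- make_calcurve(span = c(0, 12000), step = 10,
                            wiggle_amp = 15, curve_sd = 8)
        write_calcurve(cc, paths$calcurve)
        dts <- do.call(rbind, lapply(names(truth$population_curves),
          function(r) sample_radiocarbon(truth$population_curves[[r]], cc,
                                         n = sp$n_dates, err = sp$c14_err,
                                         sites = sp$sites, seed = seed,
                                         region = r,
                                         support = truth$pop_support)))
        write_dates(dts, paths$dates)
        pw <- data.frame(start_bp = c(6000, 4400, 3500, 1500),
                         end_bp = c(4400, 3500, 2800, 1000),
                         period = c("Neolithic", "EBA", "MLBA", "Medieval"))
        write_monuments(sample_monuments(sp$n_monuments, pw,
                                         mix = c(0.2, 0.45, 0.25, 0.1),
                                         unknown_fraction = sp$unknown_fraction,
                                         seed = seed), paths$monuments)
        truthp <- scilly_like_truth(n_gradient = sp$n_pollen)
        pol <- sample_pollen(truthp$gradient_truth, taxa = sp$pollen_taxa,
                             halophyte_cluster = TRUE, seed = seed)
        write.csv(pol, paths$pollen, row.names = FALSE)
        dir.create(paths$candidates, showWarnings = FALSE)
        tt <- seq(0, 9, by = 0.5)
        base <- truth$rsl_truth(tt)
        for (nm in c("truthlike", "offset_deep", "offset_shallow")) {
          off <- switch(nm, truthlike = 0, offset_deep = -1.5,
                        offset_shallow = 1.5)
          write.csv(data.frame(time_ka = tt, rsl_m = base + off),
                    file.path(paths$candidates, paste0(nm, ".csv")),
                    row.names = FALSE)
        }
    })
  }

  ## ---- sealevel -------------------------------------------------------
  curve_csv <- file.path(out, "sealevel_curve.csv")
  gia_csv <- file.path(out, "gia_rank.csv")
  if (isTRUE(cfg$sealevel$enabled)) {
    sv <- cfg$sealevel
    slip_file <- sv$slips %||% paths$slips
    cand_dir <- sv$candidates %||% paths$candidates
    if (!file.exists(slip_file))
      stop("sealevel stage: missing SLIP file '", slip_file, "'")
    run_stage("sealevel", list(sv, seed), slip_file, c(curve_csv, gia_csv), {
        slips <- read_slips(slip_file)
        fit <- fit_eiv_igp(slips, n_knots = sv$n_knots,
                           n_iter = sv$n_iter, burn = sv$burn,
                           seed = seed)
        write.csv(fit$curve, curve_csv, row.names = FALSE)
        if (dir.exists(cand_dir)) {
          rank <- select_gia(read_gia_candidates(cand_dir), slips)
          write.csv(rank, gia_csv, row.names = FALSE)
        } else write.csv(data.frame(label = character(0),
                                    chi2 = numeric(0)), gia_csv,
                         row.names = FALSE)
    })
  }

  ## ---- paleogeo -------------------------------------------------------
  series_csv <- file.path(out, "landscape_series.csv")
  changes_csv <- file.path(out, "change_metrics.csv")
  if (isTRUE(cfg$paleogeo$enabled)) {
    pg <- cfg$paleogeo
    dem_file <- pg$dem %||% paths$dem
    tide_file <- pg$tides %||% paths$tides
    for (f in c(dem_file, tide_file, curve_csv))
      if (!file.exists(f)) stop("paleogeo stage: missing input '", f, "'")
    run_stage("paleogeo", list(pg), c(dem_file, tide_file, curve_csv),
              c(series_csv, changes_csv), {
        dem <- read_ascii_grid(dem_file)
        cv <- read.csv(curve_csv)
        epochs <- pg$epochs_ka
        epochs <- epochs[epochs >= min(cv$time_ka) &
                           epochs <= max(cv$time_ka)]
        rsl <- data.frame(time_ka = epochs,
                          rsl_m = approx(cv$time_ka, cv$level_mean,
                                         epochs)$y)
        ser <- area_series(dem, rsl, read_tides(tide_file))
        write.csv(as.data.frame(ser), series_csv, row.names = FALSE)
        write.csv(change_metrics(ser, pg$window_years), changes_csv,
                  row.names = FALSE)
    })
  }

  ## ---- demography -----------------------------------------------------
  spd_csv <- file.path(out, "spd_permutation.csv")
  aor_csv <- file.path(out, "aoristic.csv")
  if (isTRUE(cfg$demography$enabled)) {
    dg <- cfg$demography
    date_file <- dg$dates %||% paths$dates
    mon_file <- dg$monuments %||% paths$monuments
    cc_file <- dg$calcurve %||% paths$calcurve
    for (f in c(date_file, mon_file, cc_file))
      if (!file.exists(f)) stop("demography stage: missing input '", f, "'")
    run_stage("demography", list(dg, seed), c(date_file, mon_file, cc_file),
              c(spd_csv, aor_csv), {
        dts <- read_dates(date_file)
        cc <- read_calcurve(cc_file)
        env <- permutation_test(dts, cc, n_perm = dg$n_perm,
                                bin_width = dg$bin_width, seed = seed)
        flat <- do.call(rbind, lapply(names(env), function(r)
          cbind(region = r, as.data.frame(env[[r]]))))
        write.csv(flat, spd_csv, row.names = FALSE)
        write.csv(as.data.frame(
          aoristic_sum(read_monuments(mon_file),
                       bin_width = dg$aoristic_bin)), aor_csv,
          row.names = FALSE)
    })
  }

  ## ---- vegetation -----------------------------------------------------
  veg_csv <- file.path(out, "veg_trend.csv")
  fire_csv <- file.path(out, "charcoal_composite.csv")
  if (isTRUE(cfg$vegetation$enabled)) {
    vg <- cfg$vegetation
    pol_file <- vg$pollen %||% paths$pollen
    if (!file.exists(pol_file))
      stop("vegetation stage: missing input '", pol_file, "'")
    run_stage("vegetation", list(vg, seed), pol_file,
              c(veg_csv, fire_csv), {
        pol <- read.csv(pol_file)
        meta <- c("sample_id", "age_bp", "is_halophyte_truth",
                  "charcoal_gt50", "charcoal_lt50")
        counts <- as.matrix(pol[, setdiff(names(pol), meta)])
        pct <- pollen_percentages(counts)
        cm <- ward_cluster(pct, k = vg$k)
        ft <- phytosociology(cm, pct)
        keep <- screen_halophytes(ft, cm, vg$halophyte_taxa)
        ord <- nmds(pct[keep, , drop = FALSE], seed = seed)
        tr <- veg_index_trend(pol$age_bp[keep], ord$points[, 1])
        write.csv(as.data.frame(tr), veg_csv, row.names = FALSE)
        recs <- lapply(split(pol, cm$cluster), function(g)
          data.frame(age_bp = g$age_bp, value = g$charcoal_gt50 + 0.0))
        recs <- recs[vapply(recs, nrow, 1L) >= 3]
        comp <- charcoal_composite(recs, base_period = vg$base_period,
                                   seed = seed)
        write.csv(comp$composite, fire_csv, row.names = FALSE)
    })
  }

  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param out_dir run directory.
#' @param seed master seed.
#' @param quick smaller problem sizes for smoke tests.
#' @return `demo_config` returns a full synthetic-run configuration list.
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "paleoscape-demo"),
                        seed = 1, quick = FALSE) {
  list(
    seed = seed,
    out_dir = out_dir,
    synth = list(enabled = TRUE, n_slips = if (quick) 30 else 60,
                 age_sd = 0.1, elev_sd = 0.3, limiting_fraction = 0.15,
                 dem_cell_size = if (quick) 200 else 100,
                 n_dates = if (quick) 60 else 150, c14_err = 30,
                 sites = 12, n_monuments = 400, unknown_fraction = 0.1,
                 n_pollen = if (quick) 30 else 50, pollen_taxa = 8),
    sealevel = list(enabled = TRUE, n_iter = if (quick) 800 else 2000,
                    burn = if (quick) 300 else 800,
                    n_knots = if (quick) 15 else 25),
    paleogeo = list(enabled = TRUE, epochs_ka = 0:8, window_years = 70),
    demography = list(enabled = TRUE,
                      n_perm = if (quick) 200 else 1000,
                      bin_width = 50, aoristic_bin = 200),
    vegetation = list(enabled = TRUE, k = NULL,
                      halophyte_taxa = "Halophyte",
                      base_period = c(4000, 6000)))
}

config_schema <- list(
  top = c("seed", "out_dir", "synth", "sealevel", "paleogeo",
          "demography", "vegetation"),
  synth = c("enabled", "n_slips", "age_sd", "elev_sd",
            "limiting_fraction", "dem_cell_size", "n_dates", "c14_err",
            "sites", "n_monuments", "unknown_fraction", "n_pollen",
            "pollen_taxa"),
  sealevel = c("enabled", "slips", "candidates", "n_iter", "burn",
               "n_knots"),
  paleogeo = c("enabled", "dem", "tides", "epochs_ka", "window_years"),
  demography = c("enabled", "dates", "monuments", "calcurve", "n_perm",
                 "bin_width", "aoristic_bin"),
  vegetation = c("enabled", "pollen", "k", "halophyte_taxa",
                 "base_period"))

validate_config <- function(cfg) {
  reject <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  reject(names(cfg), config_schema$top, "top level")
  if (is.null(cfg$seed)) stop("config needs a master 'seed'")
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  for (st in c("synth", "sealevel", "paleogeo", "demography",
               "vegetation"))
    if (!is.null(cfg[[st]]))
      reject(names(cfg[[st]]), config_schema[[st]], st)
  cfg
}

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
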