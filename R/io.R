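## Delimited survey input/output, YAML run configuration, and the pipeline
## runner producing the standard result tables.

.status_levels <- c("lifetime_abstainer", "former", "current")

#' Read survey microdata
#'
#' Expects a comma-delimited file with header columns `id`, `sex`,
#' `age_group`, `ethnicity`, `status`, `grams_per_day` and optional `weight`.
#' Validation mirrors the cleaning a drinkers-only fit needs: rows with a
#' missing volume among current drinkers are dropped (counted and reported),
#' current drinkers reporting exactly zero grams/day are reclassified as
#' lifetime abstainers (counted and reported), negative volumes or unknown
#' status labels are errors naming the offending line.
#'
#' @param path file path.
#' @param quiet suppress the exclusion/reclassification messages.
#' @return A data frame of validated records with attributes
#'   `n_missing_dropped` and `n_zero_reclassified`.
#' @export
read_survey <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("survey file is empty: ", path, call. = FALSE)
  need <- c("id", "sex", "age_group", "ethnicity", "status", "grams_per_day")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"weight" %in% names(raw)) raw$weight <- 1

  bad_status <- which(!raw$status %in% .status_levels)
  if (length(bad_status)) {
    stop("unknown status '", raw$status[bad_status[1]], "' at line ",
         bad_status[1] + 1, call. = FALSE)   # +1 for the header
  }
  neg <- which(!is.na(raw$grams_per_day) & raw$grams_per_day < 0)
  if (length(neg)) {
    stop("negative volume at line ", neg[1] + 1, call. = FALSE)
  }
  noncur_pos <- !is.na(raw$grams_per_day) & raw$grams_per_day > 0 &
    raw$status != "current"
  if (any(noncur_pos)) {
    stop("positive volume for non-drinker at line ",
         which(noncur_pos)[1] + 1, call. = FALSE)
  }

  cur <- raw$status == "current"
  drop <- cur & is.na(raw$grams_per_day)
  n_drop <- sum(drop)
  out <- raw[!drop, , drop = FALSE]
  out$grams_per_day[is.na(out$grams_per_day)] <- 0

  zero <- out$status == "current" & out$grams_per_day == 0
  n_zero <- sum(zero)
  out$status[zero] <- "lifetime_abstainer"

  if (!quiet) {
    by_sex <- function(idx, df) {
      tab <- table(factor(df$sex[idx], levels = c("men", "women")))
      sprintf("men %d; women %d", tab[["men"]], tab[["women"]])
    }
    if (n_drop > 0) {
      message("excluded ", n_drop, " record(s) with missing volume (",
              by_sex(drop, raw), ")")
    }
    if (n_zero > 0) {
      message("reclassified ", n_zero,
              " zero-volume current drinker(s) as abstainers")
    }
  }
  rownames(out) <- NULL
  attr(out, "n_missing_dropped") <- n_drop
  attr(out, "n_zero_reclassified") <- n_zero
  out
}

#' Write survey microdata
#'
#' @param records a survey data frame (as from [generate_survey()] or
#'   [read_survey()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML key-value configuration for [run_pipeline()]. Recognized keys (see
#' the example shipped in `inst/extdata/example_config.yaml`): `survey`
#' (path; omit to generate synthetic data), `synthetic` (list:
#' `underreport`, `n_total`), `percapita_liters`, `ethanol_density_g_per_l`,
#' `days_per_year`, `target_fraction`, `rr` (list: `type` = `loglinear` with
#' `beta`, or `table` with `x`/`rr`, plus `rr_former`), `categories` (list:
#' `men`/`women`, each with `breaks` and `rr`), `cap`, `integration_step`,
#' `bootstrap` (list: `enabled`, `n_reps`), `seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    percapita_liters = 8.75,
    ethanol_density_g_per_l = 789.24,
    days_per_year = 365,
    target_fraction = 1,
    rr = list(type = "loglinear", beta = 0.01, rr_former = 1.3),
    categories = list(
      men   = list(breaks = c(40, 60), rr = c(1.3, 4.0, 9.0)),
      women = list(breaks = c(20, 40), rr = c(1.3, 4.0, 9.0))
    ),
    cap = NULL,
    integration_step = 0.01,
    integration_upper = 300,
    bootstrap = list(enabled = FALSE, n_reps = 1000),
    synthetic = list(underreport = 0.529, n_total = 43000),
    outdir = "upshift-output"
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$seed)) stop("config must supply a seed", call. = FALSE)
  cfg
}

.build_risk <- function(rr_cfg) {
  rrf <- if (is.null(rr_cfg$rr_former)) 1 else rr_cfg$rr_former
  switch(rr_cfg$type,
    loglinear = rr_loglinear(rr_cfg$beta, rr_former = rrf),
    constant  = rr_constant(rr_cfg$r, rr_former = rrf),
    table     = rr_table(unlist(rr_cfg$x), unlist(rr_cfg$rr),
                         rr_former = rrf),
    stop("unknown rr type: ", rr_cfg$type, call. = FALSE)
  )
}

#' Run the full triangulation pipeline
#'
#' Stages: load or simulate the survey; fit the three families per stratum
#' and write the goodness-of-fit summary; compute the coverage rate; upshift
#' the gamma fits; compute continuous and categorical AAFs for original and
#' shifted distributions; optionally bootstrap the shifted continuous AAF.
#' Each output is a comma-delimited UTF-8 table readable by
#' [utils::read.csv()]; a JSON run log records the seed and every resolved
#' constant.
#'
#' @param config a list from [read_run_config()] (or built directly).
#' @param stages character subset of
#'   `c("fit", "gof", "shift", "aaf", "bootstrap")`; `"run"` (default) means
#'   all of them.
#' @param quiet suppress progress messages.
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "run", quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  all_stages <- c("fit", "gof", "shift", "aaf", "bootstrap")
  if (identical(stages, "run")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage <- "load"
  res <- tryCatch({
    if (!is.null(config$survey)) {
      survey <- read_survey(config$survey, quiet = quiet)
    } else {
      say("generating synthetic survey (seed ", config$seed, ")")
      specs <- default_stratum_specs(
        underreport = config$synthetic$underreport,
        n_total = config$synthetic$n_total)
      survey <- generate_survey(specs, seed = config$seed)
      paths$survey <- file.path(config$outdir, "synthetic_survey.csv")
      write_survey(survey, paths$survey)
    }

    strata <- unique(survey[c("sex", "ethnicity", "age_group")])
    strata <- strata[order(strata$sex, strata$ethnicity, strata$age_group), ]
    risk <- .build_risk(config$rr)
    pc <- percapita_gpd(config$percapita_liters,
                        config$ethanol_density_g_per_l,
                        config$days_per_year)

    stratum_rows <- function(i) {
      s <- strata[i, ]
      survey[survey$sex == s$sex & survey$ethnicity == s$ethnicity &
               survey$age_group == s$age_group, ]
    }

    fits <- vector("list", nrow(strata))
    stage <- "fit"
    fit_tab <- NULL
    for (i in seq_len(nrow(strata))) {
      sub <- stratum_rows(i)
      vols <- sub$grams_per_day[sub$status == "current"]
      fam_fits <- lapply(setNames(.families, .families), function(fam) {
        fit_consumption(vols, fam)
      })
      fits[[i]] <- list(strata = strata[i, ], fits = fam_fits,
                        pop = population_structure(
                          mean(sub$status == "lifetime_abstainer"),
                          mean(sub$status == "former"),
                          mean(sub$status == "current")))
      fit_tab <- rbind(fit_tab, do.call(rbind, lapply(.families, function(fam) {
        f <- fam_fits[[fam]]
        # parameter names differ by family; keep them as (name, value) pairs
        cbind(strata[i, ], family = fam,
              par1_name = names(f$params)[1], par1 = f$params[[1]],
              par2_name = names(f$params)[2], par2 = f$params[[2]],
              n_obs = f$n_obs, loglik = f$loglik,
              mean = f$mean, sd = f$sd, row.names = NULL)
      })))
    }
    if ("fit" %in% stages) {
      paths$fits <- file.path(config$outdir, "fits.csv")
      write.csv(fit_tab, paths$fits, row.names = FALSE)
      say("wrote ", paths$fits)
    }

    if ("gof" %in% stages) {
      stage <- "gof"
      gof_tab <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        sub <- stratum_rows(i)
        vols <- sub$grams_per_day[sub$status == "current"]
        g <- gof_table(vols, fits[[i]]$fits)
        cbind(strata[i, ],
              as.data.frame(as.list(setNames(
                c(g$totals, g$sub_top_totals),
                c(paste0("chisq_", names(g$totals)),
                  paste0("chisq_sub_", names(g$sub_top_totals)))))),
              best = rank_families(g$totals)[1], row.names = NULL)
      }))
      paths$gof <- file.path(config$outdir, "gof.csv")
      write.csv(gof_tab, paths$gof, row.names = FALSE)
      say("wrote ", paths$gof)
    }

    stage <- "shift"
    coverage <- coverage_rate(survey, pc)
    sc <- shift_config(coverage, target_fraction = config$target_fraction)
    shifts <- lapply(seq_len(nrow(strata)), function(i) {
      sexn <- as.integer(strata$sex[i] == "women")
      shift_distribution(fits[[i]]$fits$gamma, sexn, sc)
    })
    if ("shift" %in% stages) {
      shift_tab <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        sh <- shifts[[i]]
        cbind(strata[i, ],
              k = sh$original$params[["shape"]],
              theta = sh$original$params[["scale"]],
              mean_shifted = sh$shifted_mean, sd_shifted = sh$shifted_sd,
              k_shifted = sh$shifted$params[["shape"]],
              theta_shifted = sh$shifted$params[["scale"]],
              row.names = NULL)
      }))
      paths$shift <- file.path(config$outdir, "shift.csv")
      write.csv(shift_tab, paths$shift, row.names = FALSE)
      say("wrote ", paths$shift, " (coverage ", round(coverage, 4), ")")
    }

    if ("aaf" %in% stages) {
      stage <- "aaf"
      aaf_tab <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        pop <- fits[[i]]$pop
        sh <- shifts[[i]]
        cat_cfg <- config$categories[[strata$sex[i]]]
        scheme <- category_scheme(unlist(cat_cfg$breaks),
                                  unlist(cat_cfg$rr),
                                  rr_former = risk$rr_former)
        a <- function(d) aaf_continuous(pop, risk, d, cap = config$cap,
                                        upper = config$integration_upper,
                                        step = config$integration_step)$aaf
        cbind(strata[i, ],
              aaf_continuous_original = a(sh$original),
              aaf_continuous_shifted = a(sh$shifted),
              aaf_categorical_original =
                aaf_categorical(pop, scheme, sh$original)$aaf,
              aaf_categorical_shifted =
                aaf_categorical(pop, scheme, sh$shifted)$aaf,
              row.names = NULL)
      }))
      paths$aaf <- file.path(config$outdir, "aaf.csv")
      write.csv(aaf_tab, paths$aaf, row.names = FALSE)
      say("wrote ", paths$aaf)
    }

    if ("bootstrap" %in% stages && isTRUE(config$bootstrap$enabled)) {
      stage <- "bootstrap"
      boot_tab <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        sub <- stratum_rows(i)
        b <- bootstrap_aaf(sub$status, sub$grams_per_day,
                           as.integer(strata$sex[i] == "women"),
                           risk, sc, n_reps = config$bootstrap$n_reps,
                           seed = config$seed + i,
                           cap = config$cap,
                           upper = config$integration_upper,
                           step = config$integration_step)
        cbind(strata[i, ], aaf = b$point, se = b$se,
              ci_low = b$ci_low, ci_high = b$ci_high,
              n_reps = b$n_reps, row.names = NULL)
      }))
      paths$bootstrap <- file.path(config$outdir, "bootstrap.csv")
      write.csv(boot_tab, paths$bootstrap, row.names = FALSE)
      say("wrote ", paths$bootstrap)
    }

    stage <- "log"
    log <- list(
      package_version = as.character(utils::packageVersion("upshift")),
      r_version = R.version.string,
      seed = config$seed,
      percapita_liters = config$percapita_liters,
      percapita_gpd = pc,
      ethanol_density_g_per_l = config$ethanol_density_g_per_l,
      days_per_year = config$days_per_year,
      coverage = coverage,
      target_fraction = config$target_fraction,
      sd_slope = sc$sd_slope,
      sd_sex_coef = sc$sd_sex_coef,
      integration_step = config$integration_step,
      integration_upper = config$integration_upper,
      cap = config$cap,
      rr = config$rr,
      n_records = nrow(survey),
      n_strata = nrow(strata)
    )
    paths$log <- file.path(config$outdir, "run_log.json")
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
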