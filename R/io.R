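#' Read a breeding-record table
#'
#' CSV with header `female_id,year,nestbox,laying_date,age_class,recruits,
#' manipulated`. An empty/NA `female_id` marks an unknown-identity record
#' (its age class is forced to `"unknown"` if absent); laying dates are on
#' the April-day scale (April 1 = 1). Validation errors name the offending
#' row.
#'
#' @param path CSV path.
#' @return typed data.frame.
#' @export
read_breeding_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("female_id", "year", "nestbox", "laying_date", "age_class",
            "recruits", "manipulated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$female_id <- as.character(df$female_id)
  for (col in c("year", "laying_date", "recruits")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("unparseable ", col, " in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(v))
      stop("missing ", col, " in row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[col]] <- v
  }
  df$year <- as.integer(df$year)
  if (any(df$recruits < 0))
    stop("negative recruit count in row(s): ",
         paste(utils::head(which(df$recruits < 0), 5), collapse = ", "))
  if (any(!is.finite(df$laying_date)))
    stop("non-finite laying date in row(s): ",
         paste(utils::head(which(!is.finite(df$laying_date)), 5), collapse = ", "))
  df$age_class[is.na(df$age_class)] <- "unknown"
  df$age_class[is.na(df$female_id)] <- "unknown"
  ok_age <- df$age_class %in% c("first-year", "older", "unknown")
  if (!all(ok_age))
    stop("invalid age_class in row(s): ",
         paste(utils::head(which(!ok_age), 5), collapse = ", "))
  df$manipulated <- as.logical(df$manipulated)
  known <- !is.na(df$female_id)
  dup <- duplicated(df[known, c("female_id", "year")])
  if (any(dup))
    stop("duplicate female x year record(s): ",
         paste(utils::head(df$female_id[known][dup], 5), collapse = ", "))
  df
}

#' Write a breeding-record table
#' @param records data.frame; @param path CSV path.
#' @export
write_breeding_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree
#'
#' CSV with columns `id,dam,sire` (missing parents empty or NA) and
#' optionally `cohort`, `sex`. Row order is irrelevant; the pedigree is
#' validated (unique ids, parents present, acyclic, cohort ordering).
#'
#' @param path CSV path.
#' @return validated pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(c("id", "dam", "sire"), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("id", "dam", "sire")) df[[col]] <- as.character(df[[col]])
  validate_pedigree(df)
  df
}

#' @rdname read_pedigree
#' @param pedigree data.frame to write.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write the annual environment table
#'
#' CSV `year,cue_temp,peak_date,optimal_laying_date,excluded`; a missing
#' `optimal_laying_date` is recomputed from the peak when possible.
#' @param path CSV path; @param offset rearing lag for the recomputation.
#' @export
read_environments <- function(path, offset = 33) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(c("year", "cue_temp"), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$peak_date)) df$peak_date <- NA_real_
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  if (is.null(df$optimal_laying_date))
    df$optimal_laying_date <- NA_real_
  fix <- is.na(df$optimal_laying_date) & !is.na(df$peak_date)
  df$optimal_laying_date[fix] <- optimal_laying_date(df$peak_date[fix], offset)
  df
}

#' @rdname read_environments
#' @param environments data.frame to write.
#' @export
write_environments <- function(environments, path) {
  utils::write.csv(environments, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a daily temperature series
#'
#' Two-column CSV (`date` ISO-8601, `temperature`); `year` and `doy` are
#' derived.
#' @param path CSV path.
#' @export
read_daily_temperatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "temperature"), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  d <- as.Date(df$date)
  if (anyNA(d))
    stop("unparseable date in row(s): ",
         paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  data.frame(year = as.integer(format(d, "%Y")),
             doy = as.integer(format(d, "%j")),
             date = d, temperature = as.numeric(df$temperature))
}

#' Run the full synthetic-analysis pipeline
#'
#' simulate -> optimum regression -> random-regression animal model ->
#' annual selection gradients -> breeder's-equation trajectory, writing
#' every artifact as CSV/JSON under `out_dir` with a provenance block
#' (seed, package version, stage timings). Any stage failure halts with
#' the stage name; previously written artifacts remain as the partial
#' manifest. All randomness derives from `seed` (stage seeds are
#' `seed + small fixed offsets`).
#'
#' @param config an [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed root seed (default: the config's).
#' @param n_boot bootstrap iterations for the optimum fit.
#' @param n_boot_gradients parametric-bootstrap iterations per annual
#'   gradient (the expensive stage; default 200).
#' @param mcmc settings for the animal model.
#' @param baseline_years how many initial years form the baseline period.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("rnevo_"),
                         seed = config$seed, n_boot = 200,
                         n_boot_gradients = 200,
                         mcmc = mcmc_settings(), baseline_years = 15,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(obj, file, writer = utils::write.csv) {
    p <- file.path(out_dir, file)
    if (identical(writer, utils::write.csv)) {
      utils::write.csv(obj, p, row.names = FALSE, na = "")
    } else writer(obj, p)
    manifest[[file]] <<- p
    p
  }

  d <- stage("simulate", simulate_dataset(config, seed = seed))
  emit(d$records, "records.csv")
  emit(d$pedigree, "pedigree.csv")
  emit(d$environments, "environments.csv")
  emit(d$truth, "truth.csv")
  emit(p_recr_by_year(d$breeders), "p_recr.csv")

  n_per <- 3
  yrs <- d$environments$year
  cut1 <- yrs[1] + baseline_years - 1
  rest <- setdiff(yrs, yrs[yrs <= cut1])
  mid <- if (length(rest) >= 2) rest[ceiling(length(rest) / 2)] else max(yrs)
  periods <- period_definition(list(c(min(yrs), cut1),
                                    c(cut1 + 1, mid),
                                    c(mid + 1, max(yrs))))

  opt <- stage("optimum", fit_optimum_by_period(
    d$environments, periods, n_boot = n_boot, seed = seed + 1L))
  emit(opt$estimates, "optimum_fit.csv")

  fit <- stage("fit-rram", fit_model(
    d$records, d$environments, model_spec("rram"), pedigree = d$pedigree,
    mcmc = mcmc, seed = seed + 2L))
  emit(fit$summary, "rram_summary.csv")

  grad <- stage("gradients", annual_gradients(
    d$records, n_boot = n_boot_gradients, seed = seed + 3L))
  emit(as.data.frame(grad), "gradients.csv")

  traj <- stage("predict", {
    g <- extract_G(fit)
    predict_trajectory(g$G, g$se_G, grad, d$environments,
                       p_recr_by_year(d$breeders),
                       baseline_period = c(periods$first[1], periods$last[1]),
                       grand_mean_temp = g$grand_mean_temp)
  })
  emit(traj$by_year, "trajectory.csv")

  prov <- list(seed = seed, package_version = as.character(utils::packageVersion("rnevo")),
               started = format(t0), finished = format(Sys.time()),
               files = names(manifest))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: ", out_dir)
  invisible(list(dataset = d, optimum = opt, rram = fit, gradients = grad,
                 trajectory = traj, manifest = manifest, out_dir = out_dir))
}
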