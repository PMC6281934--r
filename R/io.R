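validate_counts <- function(d, source = "calf-count data") {
  need <- c("year", "site", "count")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(source, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  d$year <- suppressWarnings(as.integer(d$year))
  d$site <- as.character(d$site)
  cnt <- suppressWarnings(as.numeric(d$count))
  # data line numbers: +1 for the header row
  line <- seq_len(nrow(d)) + 1L
  bad <- which(is.na(d$year) | is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    stop(source, ": invalid year or count (counts must be nonnegative ",
         "integers) on line(s) ", paste(line[bad], collapse = ", "))
  }
  d$count <- as.integer(cnt)
  dup <- which(duplicated(d[c("year", "site")]))
  if (length(dup)) {
    stop(source, ": duplicate (year, site) pair(s) on line(s) ",
         paste(line[dup], collapse = ", "))
  }
  d[need]
}

#' Read and write annual calf-count tables
#'
#' `read_counts()` reads a delimited file with header columns `year`,
#' `site`, `count` (the standard shape of a calving-series supplement) and
#' validates it: counts must be nonnegative integers and `(year, site)`
#' pairs unique; offending rows are reported with their file line numbers.
#' `write_counts()` writes the same format; the two round-trip.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return `read_counts()` returns a validated data frame with columns
#'   `year`, `site`, `count`; `write_counts()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_counts(generate_counts(trend_scenario(), seed = 1), f)
#' head(read_counts(f))
#' @export
read_counts <- function(path, sep = ",") {
  if (!file.exists(path)) stop("count file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  validate_counts(d, source = path)
}

#' @rdname read_counts
#' @param data A data frame with columns `year`, `site`, `count`.
#' @export
write_counts <- function(data, path, sep = ",") {
  d <- validate_counts(data)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The run-level constants of the reference analysis: the vital-rate block
#' (survivals, durations, calving interval, sex ratio), the projection
#' block (123 starting females in 1990, 25-year horizon, 1000 replicates)
#' and an optional trend block naming a calf-count file. Shipped as
#' `inst/extdata/default_config.yaml`; [run_paper_analysis()] uses it when
#' no config is given.
#'
#' @return A nested list with elements `vital_rates`, `projection` and
#'   `trend`.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "rwdemog"))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full demographic and trend analysis
#'
#' Executes the whole pipeline from one configuration: build the projection
#' matrix from the vital rates, compute its asymptotic analysis, allocate
#' the starting females by the stable stage distribution, project the
#' population both deterministically and with demographic stochasticity,
#' summarise the ensemble, and -- if a calf-count table is configured or
#' supplied -- fit the negative-binomial trend model with per-site growth
#' rates and FDR-adjusted pairwise slope contrasts. Progress is logged to
#' standard error; all machine-readable outputs embed the seed and a hash
#' of the configuration.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure; `NULL` uses the default.
#' @param output_dir Directory for output files; `NULL` skips writing and
#'   just returns the bundle.
#' @param counts Optional calf-count data frame, overriding any
#'   `trend$counts_file` in the config.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with elements `config`, `config_hash`,
#'   `matrix`, `analysis`, `start_vector`, `deterministic`, `ensemble`,
#'   `ensemble_summary`, `summary` and (when counts are available) `trend`
#'   (`fit`, `rates`, `contrasts`).
#' @examples
#' cfg <- default_config()
#' cfg$projection$reps <- 50
#' res <- run_paper_analysis(cfg, quiet = TRUE)
#' res$summary$lambda
#' @export
run_paper_analysis <- function(config = NULL, output_dir = NULL,
                               counts = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- default_config()
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config)

  vr <- do.call(vital_rates, config$vital_rates)
  A <- build_matrix(vr)
  say("matrix built")
  an <- analyze(A)
  say(sprintf("lambda = %.4f", an$lambda))

  pj <- config$projection
  v0 <- initial_vector_from_ssd(pj$start_total, an)
  say(sprintf("start vector (%d): %s", pj$start_total,
              paste(v0, collapse = "/")))
  det <- project_deterministic(A, v0, pj$years, start_year = pj$start_year)
  ens <- project_stochastic(vr, v0, years = pj$years, reps = pj$reps,
                            seed = pj$seed, start_year = pj$start_year)
  qs <- pj$quantiles %||% c(0.025, 0.975)
  esum <- ensemble_summary(ens, quantiles = qs)
  say(sprintf("ensemble: %d reps, year-%d median total = %.0f",
              pj$reps, pj$start_year + pj$years,
              esum$median_total[nrow(esum)]))

  trend <- NULL
  if (is.null(counts) && !is.null(config$trend$counts_file) &&
      nzchar(config$trend$counts_file)) {
    counts <- read_counts(config$trend$counts_file)
  }
  if (!is.null(counts)) {
    fit <- fit_nb_glm(counts)
    say(sprintf("trend fit: theta = %.2f, converged = %s",
                fit$theta, fit$converged))
    trend <- list(fit = fit, rates = site_growth_rates(fit),
                  contrasts = pairwise_slope_contrasts(fit))
  }

  summary <- list(
    seed = pj$seed, config_hash = hash,
    lambda = an$lambda,
    elasticity = as.list(stats::setNames(
      an$elasticity[an$elasticity > 0],
      outer(rownames(A), colnames(A), paste, sep = "<-")[an$elasticity > 0])),
    start_vector = as.list(stats::setNames(as.integer(v0), names(v0))),
    final_year = pj$start_year + pj$years,
    final_median_total = esum$median_total[nrow(esum)],
    final_quantiles = as.list(stats::setNames(
      as.numeric(esum[nrow(esum), grep("^q", names(esum))]),
      grep("^q", names(esum), value = TRUE))),
    deterministic_final_total = sum(det[nrow(det), ])
  )
  if (!is.null(trend)) {
    summary$site_pct_per_year <- as.list(stats::setNames(
      trend$rates$pct_per_year, trend$rates$site))
    summary$theta <- trend$fit$theta
  }

  bundle <- list(config = config, config_hash = hash, matrix = A,
                 analysis = an, start_vector = v0, deterministic = det,
                 ensemble = ens, ensemble_summary = esum, trend = trend,
                 summary = summary)
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  meta <- sprintf("# seed: %s  config_hash: %s",
                  bundle$config$projection$seed %||% "none",
                  bundle$config_hash)
  write_csv_meta <- function(x, f, row_names = FALSE) {
    con <- file(p(f), "w")
    on.exit(close(con))
    writeLines(meta, con)
    utils::write.csv(x, con, row.names = row_names)
  }
  write_csv_meta(bundle$matrix, "projection_matrix.csv", row_names = TRUE)
  an <- bundle$analysis
  report <- c(
    meta,
    sprintf("lambda: %.6f", an$lambda),
    sprintf("ssd_%s: %.6f", names(an$ssd), an$ssd),
    sprintf("repro_value_%s: %.6f", names(an$repro_value), an$repro_value),
    sprintf("elasticity_%s_%s: %.6f",
            rep(rownames(an$elasticity), 3),
            rep(colnames(an$elasticity), each = 3), an$elasticity)
  )
  writeLines(report, p("analysis_report.txt"))
  write_csv_meta(as.data.frame(bundle$deterministic), "deterministic_trajectory.csv",
                 row_names = TRUE)
  write_csv_meta(bundle$ensemble_summary, "ensemble_summary.csv")
  traj <- bundle$ensemble$trajectories
  long <- expand.grid(replicate = seq_len(dim(traj)[1]),
                      year = as.integer(dimnames(traj)[[2]]),
                      stage = dimnames(traj)[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$count <- as.vector(traj)
  write_csv_meta(long, "ensemble_trajectories.csv")
  if (!is.null(bundle$trend)) {
    write_csv_meta(bundle$trend$rates, "trend_rates.csv")
    write_csv_meta(as.data.frame(bundle$trend$contrasts), "trend_contrasts.csv")
  }
  yaml::write_yaml(bundle$summary, p("summary.yaml"))
  invisible(output_dir)
}
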