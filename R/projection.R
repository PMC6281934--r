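#' Allocate a total population across stages by the stable stage distribution
#'
#' Splits `total_females` across stages proportionally to the stable stage
#' distribution `w`, returning whole animals. Rounding uses the
#' largest-remainder rule: each stage gets `floor(total * w_i)` and the
#' leftover animals go to the stages with the largest fractional remainders,
#' so the stage counts always sum exactly to the requested total. For the
#' default right whale matrix, 123 females allocate to 8 calves, 46
#' immatures and 69 adults.
#'
#' @param total_females Nonnegative whole number of females to allocate.
#' @param analysis An [analyze()] result (or any object with an `ssd`
#'   element summing to 1).
#' @return An integer vector, one count per stage, summing to
#'   `total_females`.
#' @examples
#' initial_vector_from_ssd(123, analyze(build_matrix(vital_rates())))
#' @export
initial_vector_from_ssd <- function(total_females, analysis) {
  if (!is.numeric(total_females) || length(total_females) != 1L ||
      is.na(total_females) || total_females < 0) {
    stop("'total_females' must be a single nonnegative number")
  }
  total <- round(total_females)
  w <- analysis$ssd
  raw <- total * w
  n <- floor(raw)
  leftover <- total - sum(n)
  if (leftover > 0) {
    take <- order(raw - n, decreasing = TRUE)[seq_len(leftover)]
    n[take] <- n[take] + 1
  }
  out <- as.integer(n)
  names(out) <- names(w)
  out
}

#' Deterministic multi-year projection
#'
#' Iterates `v[t+1] = A %*% v[t]` for `years` annual steps. Counts are
#' real-valued (expected numbers); row 1 is the unchanged start vector.
#'
#' @param A Projection matrix.
#' @param v0 Start vector, one nonnegative count per stage.
#' @param years Number of annual steps (>= 0).
#' @param start_year Calendar year label for `v0` (used for row names).
#' @return A `(years + 1) x nstage` numeric matrix; rows are years
#'   (`start_year` onwards), columns are stages.
#' @examples
#' A <- build_matrix(vital_rates())
#' traj <- project_deterministic(A, c(8, 46, 69), 25, start_year = 1990)
#' rowSums(traj)[c(1, 26)]
#' @export
project_deterministic <- function(A, v0, years, start_year = 0L) {
  stopifnot(is.matrix(A), length(v0) == ncol(A))
  if (years < 0) stop("'years' must be >= 0")
  if (any(v0 < 0)) stop("start vector must be nonnegative")
  out <- matrix(NA_real_, years + 1, ncol(A),
                dimnames = list(start_year + 0:years,
                                colnames(A) %||% seq_len(ncol(A))))
  v <- as.numeric(v0)
  out[1, ] <- v
  for (t in seq_len(years)) {
    v <- as.numeric(A %*% v)
    out[t + 1, ] <- v
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demographically stochastic projection ensemble
#'
#' Projects integer stage vectors forward with pure demographic
#' stochasticity: each individual's annual fate is a random draw at the
#' fixed stage rates. For a stage with annual survival `sigma`, retention
#' `P` and advancement `G` (`P + G = sigma`), each individual dies with
#' probability `1 - sigma`, remains with `P` and advances with `G`
#' (a trinomial fate, drawn as survival then advancement-given-survival).
#' Adults are retained with probability `P_adult` only; the `G_adult`
#' outflow is death at maximum longevity and leaves the population. Births
#' are a binomial draw at the matrix fecundity `f = female_fraction /
#' calving_interval`; with the default `birth_timing = "pre_survival"` the
#' draw is on the adults present at the start of the year, so the expected
#' step reproduces the projection matrix exactly and the ensemble mean
#' converges on the deterministic trajectory. `"post_survival"` instead
#' draws births from the adults that survived the year.
#'
#' @param vr A [vital_rates()] object.
#' @param v0 Integer start vector `(calf, immature, adult)`.
#' @param years Number of annual steps.
#' @param reps Number of replicate trajectories.
#' @param seed Integer seed; identical `(seed, parameters)` give a
#'   bit-identical ensemble.
#' @param birth_timing `"pre_survival"` (default) or `"post_survival"`.
#' @param start_year Calendar year label of `v0`.
#' @return An object of class `"projection_ensemble"`: a list with
#'   `trajectories` (integer array `reps x (years + 1) x 3`), `totals`
#'   (`reps x (years + 1)` matrix of all-stage sums), and the `seed`,
#'   `vital_rates`, `birth_timing` and `start_year` used.
#' @examples
#' vr <- vital_rates()
#' ens <- project_stochastic(vr, c(8, 46, 69), years = 25, reps = 200,
#'                           seed = 1, start_year = 1990)
#' stats::median(ens$totals[, "2015"])
#' @export
project_stochastic <- function(vr, v0, years, reps = 1000, seed = NULL,
                               birth_timing = c("pre_survival", "post_survival"),
                               start_year = 0L) {
  stopifnot(inherits(vr, "vital_rates"), length(v0) == 3L)
  birth_timing <- match.arg(birth_timing)
  if (any(v0 < 0) || any(v0 != round(v0))) {
    stop("stochastic projection requires a nonnegative integer start vector")
  }
  if (reps < 1) stop("'reps' must be >= 1")
  if (years < 0) stop("'years' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  f <- fecundity(vr$calving_interval, vr$female_fraction)
  sig <- c(vr$sigma_calf, vr$sigma_juv)
  G <- c(stage_transition_prob(vr$sigma_calf, vr$d_calf),
         stage_transition_prob(vr$sigma_juv, vr$d_juv))
  adv_given_surv <- pmin(1, ifelse(sig > 0, G / sig, 0))
  P_adult <- stage_retention_prob(vr$sigma_adult, vr$d_adult)

  traj <- array(NA_integer_, c(reps, years + 1, 3),
                dimnames = list(NULL, start_year + 0:years, STAGES))
  n <- matrix(rep(as.integer(round(v0)), each = reps), reps, 3)
  traj[, 1, ] <- n
  for (t in seq_len(years)) {
    adult_survivors <- rbinom(reps, n[, 3], P_adult)
    birth_pool <- if (birth_timing == "pre_survival") n[, 3] else adult_survivors
    births <- rbinom(reps, birth_pool, f)
    calf_surv <- rbinom(reps, n[, 1], sig[1])
    calf_adv <- rbinom(reps, calf_surv, adv_given_surv[1])
    juv_surv <- rbinom(reps, n[, 2], sig[2])
    juv_adv <- rbinom(reps, juv_surv, adv_given_surv[2])
    n <- cbind(births + (calf_surv - calf_adv),
               calf_adv + (juv_surv - juv_adv),
               juv_adv + adult_survivors)
    traj[, t + 1, ] <- n
  }
  totals <- matrix(traj[, , 1] + traj[, , 2] + traj[, , 3], reps, years + 1,
                   dimnames = list(NULL, start_year + 0:years))
  structure(
    list(trajectories = traj, totals = totals, reps = reps, years = years,
         seed = seed, vital_rates = vr, birth_timing = birth_timing,
         start_year = as.integer(start_year)),
    class = "projection_ensemble"
  )
}

#' @export
print.projection_ensemble <- function(x, ...) {
  last <- ncol(x$totals)
  cat(sprintf(
    "Stochastic projection ensemble: %d replicates x %d years (seed %s)\n",
    x$reps, x$years, x$seed %||% "none"))
  cat(sprintf("  final-year total females: median %.0f (2.5%%-97.5%%: %.0f-%.0f)\n",
              stats::median(x$totals[, last]),
              stats::quantile(x$totals[, last], 0.025),
              stats::quantile(x$totals[, last], 0.975)))
  invisible(x)
}

#' Per-year summary of a projection ensemble
#'
#' @param e A [project_stochastic()] ensemble.
#' @param quantiles Probabilities for quantiles of the all-stage total
#'   (default the central 95% interval).
#' @return A data frame with one row per year: `year`, `median_total`, one
#'   `q<p>` column per requested quantile, `mean_total`, and per-stage mean
#'   counts.
#' @export
ensemble_summary <- function(e, quantiles = c(0.025, 0.975)) {
  stopifnot(inherits(e, "projection_ensemble"))
  if (e$reps < 1) stop("empty ensemble")
  yrs <- as.integer(colnames(e$totals))
  qmat <- t(apply(e$totals, 2, stats::quantile, probs = quantiles, names = FALSE))
  qmat <- matrix(qmat, ncol = length(quantiles))
  colnames(qmat) <- paste0("q", vapply(quantiles, format, ""))
  stage_mean <- function(s) colMeans(matrix(e$trajectories[, , s], e$reps))
  data.frame(
    year = yrs,
    median_total = apply(e$totals, 2, stats::median),
    qmat,
    mean_total = colMeans(e$totals),
    mean_calf = stage_mean("calf"),
    mean_immature = stage_mean("immature"),
    mean_adult = stage_mean("adult"),
    row.names = NULL, check.names = FALSE
  )
}
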