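STAGES <- c("calf", "immature", "adult")

#' Build the three-stage female projection matrix
#'
#' Assembles the stage-structured projection matrix (stages calf, immature,
#' adult; birth-pulse, annual time step) from a set of vital rates. The calf
#' row carries the fecundity `f = female_fraction / calving_interval` in the
#' adult column, undiscounted by adult survival. Calves advance with
#' probability `G_calf`, immatures remain with `P_juv` and advance with
#' `G_juv`, and adults remain with `P_adult`; the adult outflow `G_adult`
#' (death at maximum longevity) leaves the modelled population.
#'
#' @param vr A [vital_rates()] object.
#' @return A 3x3 numeric matrix with `dimnames` `c("calf", "immature",
#'   "adult")` on both margins. Column `j` gives the per-capita annual
#'   contributions of stage `j` to each stage.
#' @examples
#' A <- build_matrix(vital_rates())
#' round(A, 5)
#' @export
build_matrix <- function(vr) {
  stopifnot(inherits(vr, "vital_rates"))
  A <- matrix(0, 3, 3, dimnames = list(STAGES, STAGES))
  A["calf", "adult"] <- fecundity(vr$calving_interval, vr$female_fraction)
  A["immature", "calf"] <- stage_transition_prob(vr$sigma_calf, vr$d_calf)
  A["calf", "calf"] <- stage_retention_prob(vr$sigma_calf, vr$d_calf)
  A["immature", "immature"] <- stage_retention_prob(vr$sigma_juv, vr$d_juv)
  A["adult", "immature"] <- stage_transition_prob(vr$sigma_juv, vr$d_juv)
  A["adult", "adult"] <- stage_retention_prob(vr$sigma_adult, vr$d_adult)
  A
}

#' Asymptotic analysis of a projection matrix
#'
#' Computes the dominant eigenvalue (the asymptotic annual multiplier
#' lambda), the stable stage distribution `w` (dominant right eigenvector,
#' normalised to sum to 1), the reproductive-value vector `v` (dominant left
#' eigenvector, scaled so that `sum(v * w) = 1`), the sensitivity matrix
#' `s_ij = v_i * w_j`, and the elasticity matrix `e_ij = (a_ij / lambda) *
#' s_ij`. Elasticities are proportional sensitivities and sum to one, so each
#' entry reads directly as the share of proportional change in lambda
#' attributable to that matrix entry.
#'
#' @param A A square nonnegative projection matrix, irreducible on its
#'   nonzero pattern (so a real, simple dominant root with a positive
#'   eigenvector exists).
#' @return An object of class `"asymptotic_analysis"`: a list with elements
#'   `lambda`, `ssd`, `repro_value`, `sensitivity`, `elasticity` and
#'   `matrix`.
#' @examples
#' an <- analyze(build_matrix(vital_rates()))
#' an$lambda          # about 1.040
#' round(an$elasticity, 5)
#' @export
analyze <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("'A' must be a square matrix")
  if (any(!is.finite(A)) || any(A < 0)) stop("'A' must be nonnegative and finite")
  n <- nrow(A)
  ev <- eigen(A)
  k <- which.max(Mod(ev$values))
  lambda <- ev$values[k]
  if (abs(Im(lambda)) > 1e-9 * max(1, Mod(lambda))) {
    stop("no real dominant eigenvalue: matrix may be reducible or cyclic")
  }
  lambda <- Re(lambda)
  if (lambda <= 0) stop("dominant eigenvalue is not positive")
  w <- Re(ev$vectors[, k])
  w <- w / sum(w)
  if (any(w < -1e-9)) {
    stop("dominant right eigenvector is not positive: matrix reducible?")
  }
  w <- pmax(w, 0)
  evl <- eigen(t(A))
  kl <- which.max(Mod(evl$values))
  v <- Re(evl$vectors[, kl])
  v <- v / sum(v * w)
  if (any(v < -1e-9)) {
    stop("dominant left eigenvector is not positive: matrix reducible?")
  }
  v <- pmax(v, 0)
  S <- outer(v, w)
  E <- (A / lambda) * S
  dn <- dimnames(A)
  if (!is.null(dn)) {
    names(w) <- names(v) <- dn[[1]]
    dimnames(S) <- dimnames(E) <- dn
  }
  structure(
    list(lambda = lambda, ssd = w, repro_value = v,
         sensitivity = S, elasticity = E, matrix = A),
    class = "asymptotic_analysis"
  )
}

#' @export
print.asymptotic_analysis <- function(x, digits = 5, ...) {
  cat(sprintf("Asymptotic analysis: lambda = %.*f (%.2f%% per year)\n",
              digits, x$lambda, 100 * (x$lambda - 1)))
  cat("Stable stage distribution:\n")
  print(round(x$ssd, digits))
  cat("Reproductive values (scaled so <v, w> = 1):\n")
  print(round(x$repro_value, digits))
  cat("Elasticities (sum to 1):\n")
  print(round(x$elasticity, digits))
  invisible(x)
}
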