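#' Ranking and error metrics against experimental affinities
#'
#' Pairs calculated and experimental binding free energies by system id and
#' computes:
#' \itemize{
#' \item RMSE \eqn{= \sqrt{\mathrm{mean}((\Delta G_{calc} -
#'   \Delta G_{exp})^2)}}
#' \item MSE (mean signed error) \eqn{= \mathrm{mean}(\Delta G_{exp} -
#'   \Delta G_{calc})}: positive when calculation overestimates binding
#'   strength (calculated values more negative than experiment)
#' \item Kendall \eqn{\tau}-b (tie-corrected) rank correlation
#' \item Pearlman predictive index
#'   \eqn{PI = \sum_{i<j} w_{ij} C_{ij} / \sum_{i<j} w_{ij}} with weights
#'   \eqn{w_{ij} = |\Delta G_{calc,j} - \Delta G_{calc,i}|} and
#'   \eqn{C_{ij} = \pm 1} for concordant/discordant pairs (0 on ties).
#' }
#'
#' @param exp an [experiment table][read_experiment_csv()] (columns `id`,
#'   `dg_exp_kcal`) or a named numeric vector of experimental affinities
#' @param calc named numeric vector of calculated affinities, kcal/mol
#' @return list of class `"quality_metrics"` with `rmse`, `mse`,
#'   `kendall_tau`, `pearlman_pi`, `n_systems`
#' @export
compute_metrics <- function(exp, calc) {
  if (inherits(exp, "data.frame")) {
    e <- stats::setNames(exp$dg_exp_kcal, exp$id)
  } else e <- exp
  ids <- intersect(names(e), names(calc))
  if (length(ids) < 2)
    stop("compute_metrics: need at least 2 systems shared between exp and calc")
  ev <- as.numeric(e[ids]); cv <- as.numeric(calc[ids])
  if (length(unique(ev)) == 1)
    stop("compute_metrics: all experimental values equal; ranking metrics undefined")
  if (length(unique(cv)) == 1)
    stop("compute_metrics: all calculated values equal; PI undefined")
  rmse <- sqrt(mean((cv - ev)^2))
  mse <- mean(ev - cv)
  tau <- stats::cor(ev, cv, method = "kendall")
  pearlman_pi <- pearlman_pi_impl(ev, cv)
  structure(list(rmse = rmse, mse = mse, kendall_tau = tau,
                 pearlman_pi = pearlman_pi, n_systems = length(ids)),
            class = "quality_metrics")
}

pearlman_pi_impl <- function(ev, cv) {
  n <- length(ev)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- abs(cv[j] - cv[i])
    s <- (ev[j] - ev[i]) * (cv[j] - cv[i])
    cij <- if (s > 0) 1 else if (s < 0) -1 else 0
    num <- num + w * cij
    den <- den + w
  }
  num / den
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("Quality metrics over %d systems:\n", x$n_systems))
  cat(sprintf("  RMSE        %8.3f kcal/mol\n", x$rmse))
  cat(sprintf("  MSE         %8.3f kcal/mol (exp - calc)\n", x$mse))
  cat(sprintf("  Kendall tau %8.3f\n", x$kendall_tau))
  cat(sprintf("  Pearlman PI %8.3f\n", x$pearlman_pi))
  invisible(x)
}

#' @export
as.data.frame.quality_metrics <- function(x, ...) {
  data.frame(rmse = x$rmse, mse = x$mse, kendall_tau = x$kendall_tau,
             pearlman_pi = x$pearlman_pi, n_systems = x$n_systems)
}
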