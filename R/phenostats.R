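#' Synapsis rate with a Wilson binomial interval
#'
#' @param nuclei_synapsed,nuclei_total Counts (vectors allowed);
#'   `nuclei_total` must be positive.
#' @param conf_level Confidence level.
#' @return data.frame with `rate`, `ci_low`, `ci_high`.
#' @export
synapsis_rate <- function(nuclei_synapsed, nuclei_total, conf_level = 0.95) {
  if (any(nuclei_total < 1)) stop("nuclei_total must be >= 1")
  if (any(nuclei_synapsed > nuclei_total))
    stop("nuclei_synapsed exceeds nuclei_total")
  ci <- wilson_interval(nuclei_synapsed, nuclei_total, conf_level)
  data.frame(rate = nuclei_synapsed / nuclei_total,
             ci_low = ci$low, ci_high = ci$high)
}

#' Testis weight normalised to lean body mass
#'
#' @param testis_weight Paired testes weight in mg.
#' @param lean_body_weight Lean body weight in g (positive).
#' @return mg per g of lean mass.
#' @export
normalize_testis <- function(testis_weight, lean_body_weight) {
  if (any(lean_body_weight <= 0)) stop("lean_body_weight must be positive")
  if (any(testis_weight < 0)) stop("testis_weight must be nonnegative")
  testis_weight / lean_body_weight
}

#' Welch two-sample t-test between genotype groups
#'
#' Thin wrapper around [stats::t.test()] (Welch, unequal variances,
#' two-sided by default) that handles the degenerate zero-variance case:
#' two constant groups with equal means give t = 0, p = 1 by convention;
#' constant groups with different means give p = 0.
#'
#' @param a,b Numeric measurement vectors, each of length >= 2.
#' @param alternative Passed to [stats::t.test()].
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
group_ttest <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Fit the cliff-edge (threshold) model of sperm production vs synapsis
#'
#' Sperm counts are analysed on the log10 scale, with zero counts given a
#' floor of `pseudo_count` (the plotting convention for azoospermic
#' mice).  A step model
#' `E[log10 sperm] = m_below 1(x < tau) + m_above 1(x >= tau)`
#' over synapsis rate x is fitted by exhaustive search of tau over the
#' midpoints between consecutive distinct observed synapsis values,
#' minimising the sum of squared errors.  A bootstrap over mice gives a
#' percentile interval for tau.
#'
#' @param records Phenotype table with `nuclei_synapsed`, `nuclei_total`,
#'   `sperm_count` (e.g. from [simulate_phenotypes()]).
#' @param pseudo_count Sperm count assigned to azoospermic mice.
#' @param n_boot Bootstrap replicates (0 skips the interval).
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `cliff_edge_fit`: `tau_hat`, `mean_below`,
#'   `mean_above` (log10 scale), `sse`, `ci_tau` (length 2), `degenerate`
#'   (TRUE when all candidate thresholds fit equally well or all mice lie
#'   on one side), `x`, `y` (the fitted data).
#' @export
fit_cliff_edge <- function(records, pseudo_count = 2, n_boot = 1000L,
                           seed = 1L) {
  x <- records$nuclei_synapsed / records$nuclei_total
  y <- log10(ifelse(records$sperm_count == 0, pseudo_count,
                    records$sperm_count))
  fit <- step_fit(x, y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && !fit$degenerate) {
    set.seed(as.integer(seed))
    n <- length(x)
    taus <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      step_fit(x[i], y[i])$tau_hat
    }, numeric(1L))
    ci <- unname(stats::quantile(taus, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(c(fit, list(ci_tau = ci, x = x, y = y)),
            class = "cliff_edge_fit")
}

# Exhaustive step-model fit over midpoints of sorted distinct x values.
step_fit <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    return(list(tau_hat = NA_real_, mean_below = NA_real_,
                mean_above = mean(y), sse = sum((y - mean(y))^2),
                degenerate = TRUE))
  }
  cand <- (ux[-1L] + ux[-length(ux)]) / 2
  sse <- vapply(cand, function(tau) {
    below <- x < tau
    sum((y[below] - mean(y[below]))^2) + sum((y[!below] - mean(y[!below]))^2)
  }, numeric(1L))
  degenerate <- diff(range(sse)) < 1e-12
  best <- which.min(sse)
  tau <- cand[best]
  below <- x < tau
  list(tau_hat = tau, mean_below = mean(y[below]),
       mean_above = mean(y[!below]), sse = sse[best],
       degenerate = degenerate)
}

#' @export
print.cliff_edge_fit <- function(x, ...) {
  cat("Cliff-edge threshold fit\n")
  cat(sprintf("  tau_hat     : %.3f (95%% bootstrap CI %.3f-%.3f)\n",
              x$tau_hat, x$ci_tau[1], x$ci_tau[2]))
  cat(sprintf("  mean log10 sperm below/above: %.2f / %.2f\n",
              x$mean_below, x$mean_above))
  cat(sprintf("  SSE %.3f%s\n", x$sse,
              if (x$degenerate) "  [degenerate fit]" else ""))
  invisible(x)
}
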