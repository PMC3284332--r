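#' Joint maximum-likelihood fit of conversion rate and tract length
#'
#' Fits the two-parameter model of noncrossover gene conversion on a
#' hemizygous chromosome: DSBs arise per bp per transmitted chromatid at
#' rate \eqn{\lambda} and convert a tract that extends left and right by
#' independent geometric lengths with cessation probability \eqn{p}.  The
#' data are the histogram of no-conversion inter-marker spans and the
#' observed conversion conformations (see [span_histogram()] and
#' [as_conformations()]); both visible events and the absence of events
#' between markers inform the fit, which is what corrects the rate estimate
#' for conversions that fall entirely between genotyped markers.
#'
#' Maximization is a coarse log-spaced grid over \eqn{(\lambda, p)}
#' followed by Nelder-Mead refinement on transformed coordinates
#' (log lambda, logit p); grid ties are broken toward smaller
#' \eqn{\lambda}.
#'
#' @param spans A [span_histogram()] or data frame with `length`/`count`
#'   columns.
#' @param conformations A [gc_conformation()] data frame, or a
#'   conversion-event data frame (coerced via [as_conformations()]), or
#'   `NULL` for no observed events.
#' @param lambda_range,p_range Search ranges.
#' @param grid_size Number of grid points per parameter.
#' @param refine Run local refinement after the grid search.
#' @param arm_length,genome_length,co_per_meiosis Geometry used by
#'   [summary.gcml()] and [derived_rates()] for derived rate quantities.
#' @return An object of class `gcml` with components `lambda`, `p`,
#'   `logLik`, `tract_mean` (one-sided, (1-p)/p), `grid` (the evaluated
#'   surface), `converged`, `boundary` (TRUE when the estimate sits on the
#'   edge of the search range, e.g. with zero observed conversions), and
#'   the data.  Methods: `print`, `summary`, `coef`, `logLik`, `confint`
#'   (profile likelihood), `plot` (surface contour), `simulate`
#'   (parametric re-simulation), `predict` (expected DSB counts).
#' @examples
#' spans <- data.frame(length = c(100, 300, 900), count = c(400, 250, 80))
#' confs <- gc_conformation(span = 700, left_offset = 220, right_offset = 180)
#' fit <- gcml(spans, confs, grid_size = c(25, 25))
#' coef(fit)
#' @export
gcml <- function(spans, conformations = NULL,
                 lambda_range = c(1e-10, 1e-6), p_range = c(1e-4, 1),
                 grid_size = c(60, 60), refine = TRUE,
                 arm_length = 22.4e6, genome_length = 119e6,
                 co_per_meiosis = 5) {
  counts <- if (inherits(spans, "span_histogram")) spans$counts else spans
  if (!is.null(conformations) && !inherits(conformations, "gc_conformation")) {
    conformations <- as_conformations(conformations)
  }
  n_spans <- if (is.null(counts)) 0 else sum(counts$count)
  n_confs <- if (is.null(conformations)) 0 else nrow(conformations)
  stop_if(n_spans + n_confs == 0, "need at least one span or conformation")

  lg <- exp(seq(log(lambda_range[1]), log(lambda_range[2]), length.out = grid_size[1]))
  pg <- exp(seq(log(p_range[1]), log(p_range[2]), length.out = grid_size[2]))
  lnL <- matrix(-Inf, length(lg), length(pg))
  for (jp in seq_along(pg)) {
    for (jl in seq_along(lg)) {
      lnL[jl, jp] <- gc_loglik(counts, conformations, lg[jl], pg[jp])
    }
  }
  best <- which(lnL == max(lnL), arr.ind = TRUE)
  best <- best[order(best[, 1]), , drop = FALSE][1, ]  # ties -> smaller lambda
  lambda_hat <- lg[best[1]]
  p_hat <- pg[best[2]]
  max_lnL <- lnL[best[1], best[2]]
  converged <- TRUE

  if (refine) {
    obj <- function(theta) {
      lam <- exp(theta[1])
      pp <- 1 / (1 + exp(-theta[2]))
      if (lam < lambda_range[1] || lam > lambda_range[2] ||
          pp < p_range[1] || pp > p_range[2]) return(1e12)
      -gc_loglik(counts, conformations, lam, pp)
    }
    start <- c(log(lambda_hat), log(p_hat / (1 - min(p_hat, 1 - 1e-12))))
    opt <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.finite(opt$value) && -opt$value >= max_lnL) {
      lambda_hat <- exp(opt$par[1])
      p_hat <- 1 / (1 + exp(-opt$par[2]))
      max_lnL <- -opt$value
      converged <- opt$convergence == 0
    }
  }

  boundary <- best[1] %in% c(1L, length(lg)) && n_confs == 0 ||
    lambda_hat <= lambda_range[1] * 1.0001 || lambda_hat >= lambda_range[2] * 0.9999

  structure(list(
    lambda = lambda_hat, p = p_hat, logLik = max_lnL,
    tract_mean = (1 - p_hat) / p_hat,
    grid = list(lambda = lg, p = pg, lnL = lnL),
    converged = converged, boundary = boundary,
    lambda_range = lambda_range, p_range = p_range,
    spans = counts, conformations = conformations,
    n_spans = n_spans, n_conformations = n_confs,
    arm_length = arm_length, genome_length = genome_length,
    co_per_meiosis = co_per_meiosis
  ), class = "gcml")
}

#' @export
print.gcml <- function(x, ...) {
  cat("Joint ML fit of gene-conversion rate and tract length\n")
  cat(sprintf("  data: %d no-conversion spans, %d conversion events\n",
              x$n_spans, x$n_conformations))
  cat(sprintf("  lambda (DSB rate/bp/chromatid): %.3g\n", x$lambda))
  cat(sprintf("  p (cessation): %.4g;  mean one-sided tract: %.0f bp;  total: %.0f bp\n",
              x$p, x$tract_mean, 2 * x$tract_mean))
  cat(sprintf("  ln-likelihood: %.3f%s%s\n", x$logLik,
              if (!x$converged) "  [not converged]" else "",
              if (x$boundary) "  [boundary estimate]" else ""))
  invisible(x)
}

#' @export
coef.gcml <- function(object, ...) {
  c(lambda = object$lambda, p = object$p)
}

#' @export
logLik.gcml <- function(object, ...) {
  structure(object$logLik, df = 2, class = "logLik")
}

#' Profile-likelihood confidence intervals for a gcml fit
#'
#' Bounds are the parameter values at which the log-likelihood, with the
#' other parameter held at its MLE, drops `delta_lnL` units below the
#' maximum (2 units approximates a 95\% interval).  The interval for
#' `"tract_mean"` is obtained by profiling `p` and transforming the bounds
#' of (1 - p)/p.  Bounds that run into the search range are returned as
#' `NA` (open-ended) with a warning.
#'
#' @param object A [gcml()] fit.
#' @param parm `"lambda"`, `"p"`, `"tract_mean"`, or several.
#' @param level Ignored (the interval is defined by `delta_lnL`); present
#'   for the generic's signature.
#' @param delta_lnL Log-likelihood drop defining the bounds.
#' @param ... Unused.
#' @return Matrix with `lower`/`upper` columns.
#' @export
confint.gcml <- function(object, parm = c("lambda", "tract_mean"),
                         level = 0.95, delta_lnL = 2, ...) {
  parm <- match.arg(parm, c("lambda", "p", "tract_mean"), several.ok = TRUE)
  target <- object$logLik - delta_lnL
  prof <- function(which) {
    if (which == "lambda") {
      f <- function(v) gc_loglik(object$spans, object$conformations, v, object$p) - target
      hat <- object$lambda; rng <- object$lambda_range
    } else {
      f <- function(v) gc_loglik(object$spans, object$conformations, object$lambda, v) - target
      hat <- object$p; rng <- object$p_range
    }
    bound <- function(lo, hi) {
      flo <- f(lo); fhi <- f(hi)
      if (flo * fhi > 0) return(NA_real_)  # no crossing inside range
      suppressWarnings(uniroot(f, c(lo, hi), tol = min(hat, 1e-4) * 1e-6)$root)
    }
    lower <- if (f(rng[1]) > 0) NA_real_ else bound(rng[1], hat)
    upper <- if (f(rng[2]) > 0) NA_real_ else bound(hat, rng[2])
    c(lower, upper)
  }
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (pp in parm) {
    ci <- switch(pp,
                 lambda = prof("lambda"),
                 p = prof("p"),
                 tract_mean = {
                   ci_p <- prof("p")
                   rev((1 - ci_p) / ci_p)  # tract mean decreases in p
                 })
    out[pp, ] <- ci
  }
  if (anyNA(out)) warning("profile bound(s) outside the search range; interval open-ended")
  out
}

#' @export
summary.gcml <- function(object, delta_lnL = 2, ...) {
  ci <- suppressWarnings(confint(object, c("lambda", "tract_mean"),
                                 delta_lnL = delta_lnL))
  structure(list(fit = object, ci = ci,
                 rates = derived_rates(object$lambda, object$p,
                                       object$arm_length, object$genome_length,
                                       object$co_per_meiosis)),
            class = "summary.gcml")
}

#' @export
print.summary.gcml <- function(x, ...) {
  print(x$fit)
  cat("\nProfile confidence intervals (2 ln-likelihood units):\n")
  print(signif(x$ci, 3))
  cat("\n")
  print(x$rates)
  invisible(x)
}

#' @export
plot.gcml <- function(x, n_levels = 12, ...) {
  finite <- x$grid$lnL[is.finite(x$grid$lnL)]
  lv <- quantile(finite, seq(0.5, 1, length.out = n_levels))
  contour(log10(x$grid$lambda), log10(x$grid$p), x$grid$lnL, levels = lv,
          xlab = expression(log[10] ~ lambda), ylab = expression(log[10] ~ p),
          main = "ln-likelihood surface", ...)
  points(log10(x$lambda), log10(x$p), pch = 19, col = 2)
  invisible(x)
}

#' @export
predict.gcml <- function(object, length_bp = object$arm_length,
                         n_chromatids = 1, ...) {
  object$lambda * length_bp * n_chromatids
}

#' Parametric re-simulation from a fitted conversion model
#'
#' Draws new meiosis datasets from [simulate_meiosis()] with the fitted
#' `lambda` and `p`, leaving the crossover and observation parameters of
#' `params` untouched; useful for parametric-bootstrap checks.
#'
#' @param object A [gcml()] fit.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param map Marker map to simulate on.
#' @param params Template [meiosis_params()].
#' @param ... Unused.
#' @return A list of `meiosis_sim` objects.
#' @export
simulate.gcml <- function(object, nsim = 1, seed = 1, map,
                          params = meiosis_params(), ...) {
  lapply(seq_len(nsim), function(s) {
    pp <- params
    pp$nco_dsb_rate <- object$lambda
    pp$tract_p <- object$p
    pp$seed <- substream_seed(seed, s)
    simulate_meiosis(map, pp)
  })
}

#' Likelihood-ratio test of a constrained total recombination rate
#'
#' Tests whether the fitted conversion rate is consistent with a stated
#' total number of recombination events per meiosis (for example the
#' cytological DSB count): \eqn{\lambda} is fixed so that the implied
#' genome-wide conversion events per meiosis equal
#' `total_events - co_per_meiosis`, `p` is re-fitted freely, and the
#' statistic 2(lnL_free - lnL_constrained) is referred to chi-square with
#' 1 df.
#'
#' @param object A [gcml()] fit.
#' @param total_events Constrained total (CO + GC) events per meiosis.
#' @param co_per_meiosis,genome_length Geometry; default from the fit.
#' @return A list of class `gcml_lrt` with `statistic`, `df`, `p.value`,
#'   `lambda_constrained` and the constrained log-likelihood.
#' @export
lrt_event_total <- function(object, total_events,
                            co_per_meiosis = object$co_per_meiosis,
                            genome_length = object$genome_length) {
  stop_if(total_events < co_per_meiosis,
          "constrained total must be at least the CO count")
  lambda0 <- (total_events - co_per_meiosis) / (4 * genome_length)
  f <- function(logit_p) {
    -gc_loglik(object$spans, object$conformations, lambda0,
               1 / (1 + exp(-logit_p)))
  }
  opt <- suppressWarnings(
    optim(log(object$p / (1 - min(object$p, 1 - 1e-12))), f,
          method = "Brent", lower = -12, upper = 12))
  lnL0 <- -opt$value
  stat <- 2 * (object$logLik - lnL0)
  stop_if(stat < -1e-6, "constrained likelihood exceeds the free maximum; optimizer failure")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = 1,
                 p.value = pchisq(stat, df = 1, lower.tail = FALSE),
                 lambda_constrained = lambda0, logLik_constrained = lnL0,
                 total_events = total_events),
            class = "gcml_lrt")
}

#' @export
print.gcml_lrt <- function(x, ...) {
  cat(sprintf("LRT against %g total events per meiosis: chi^2(1) = %.3f, P = %.3g\n",
              x$total_events, x$statistic, x$p.value))
  invisible(x)
}

#' Rates derived from the fitted conversion parameters
#'
#' Converts the per-bp DSB rate and tract parameter into the quantities a
#' recombination study reports: mean one-sided and total tract lengths,
#' the per-nucleotide conversion rate (lambda times total mean tract), the
#' expected events per chromosome arm and per haploid genome, the
#' per-meiosis rate (four haploid products per meiosis), and the ratio of
#' conversion to crossover events per meiosis.
#'
#' @param lambda DSB rate per bp per transmitted chromatid.
#' @param p Geometric cessation probability.
#' @param arm_length,genome_length Lengths in bp.
#' @param co_per_meiosis Crossover events per meiosis for the GC:CO ratio
#'   (set to `NA` or 0 to leave the ratio undefined).
#' @return A list of class `gc_rates`.
#' @examples
#' derived_rates(1.8e-8, 1 / 239)
#' @export
derived_rates <- function(lambda, p, arm_length = 22.4e6,
                          genome_length = 119e6, co_per_meiosis = 5) {
  stop_if(lambda < 0, "lambda must be >= 0")
  stop_if(p <= 0 || p > 1, "p must be in (0, 1]")
  one_sided <- (1 - p) / p
  total <- 2 * one_sided
  per_meiosis <- 4 * lambda * genome_length
  ratio <- if (is.na(co_per_meiosis) || co_per_meiosis <= 0) NA_real_
           else per_meiosis / co_per_meiosis
  structure(list(
    lambda = lambda, p = p,
    one_sided_mean_tract = one_sided,
    total_mean_tract = total,
    per_bp_conversion_rate = lambda * total,
    per_arm_rate = lambda * arm_length,
    genome_haploid_rate = lambda * genome_length,
    per_meiosis_rate = per_meiosis,
    gc_co_ratio = ratio,
    arm_length = arm_length, genome_length = genome_length,
    co_per_meiosis = co_per_meiosis
  ), class = "gc_rates")
}

#' @export
print.gc_rates <- function(x, ...) {
  cat("Derived conversion rates\n")
  cat(sprintf("  mean tract: %.0f bp one-sided, %.0f bp total\n",
              x$one_sided_mean_tract, x$total_mean_tract))
  cat(sprintf("  per-bp conversion rate: %.3g per meiosis\n",
              x$per_bp_conversion_rate))
  cat(sprintf("  events per %.3g-bp arm: %.3f;  per haploid genome (%.3g bp): %.3f\n",
              x$arm_length, x$per_arm_rate, x$genome_length, x$genome_haploid_rate))
  cat(sprintf("  events per meiosis (4 products): %.2f;  GC:CO ratio: %s\n",
              x$per_meiosis_rate,
              if (is.na(x$gc_co_ratio)) "undefined" else sprintf("%.2f", x$gc_co_ratio)))
  invisible(x)
}
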