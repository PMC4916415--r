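# Type-I error, power and QQ-band evaluation over replicated simulations.

#' QQ summary of a p-value set against the uniform null
#'
#' For the i-th smallest of n p-values the expected quantile is the median of
#' the i-th uniform order statistic, a Beta(i, n - i + 1) law; the pointwise
#' band comes from the `(1 - band_level)/2` and `(1 + band_level)/2`
#' quantiles of that same Beta distribution, i.e. the envelope within which
#' each ordered p-value falls with probability `band_level` when p-values are
#' drawn independently from uniform(0, 1). All quantities are reported on the
#' -log10 scale.
#'
#' @param p_values P-values in (0, 1\]; exact zeros are floored at the
#'   smallest positive double before the log transform.
#' @param band_level Pointwise band coverage, in (0, 1); default 0.95.
#' @return A `qq_summary` data frame with one row per rank, ascending in
#'   expected -log10(p): `rank`, `expected`, `observed`, `band_lower`,
#'   `band_upper`, plus an `n_tests` attribute.
#' @examples
#' qq <- qq_summary(runif(100))
#' mean(qq$observed >= qq$band_lower & qq$observed <= qq$band_upper)
#' @export
qq_summary <- function(p_values, band_level = 0.95) {
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  stopifnot(is.numeric(p_values), !anyNA(p_values),
            all(p_values >= 0), all(p_values <= 1),
            is.numeric(band_level), length(band_level) == 1L,
            band_level > 0, band_level < 1)
  n <- length(p_values)
  p <- pmax(sort(p_values), .Machine$double.xmin)
  i <- seq_len(n)
  alpha <- (1 - band_level) / 2
  # i-th smallest p-value ~ Beta(i, n - i + 1) under the uniform null
  out <- data.frame(
    rank = rev(i),
    expected = rev(-log10(stats::qbeta(0.5, i, n - i + 1))),
    observed = rev(-log10(p)),
    band_lower = rev(-log10(stats::qbeta(1 - alpha, i, n - i + 1))),
    band_upper = rev(-log10(stats::qbeta(alpha, i, n - i + 1)))
  )
  attr(out, "n_tests") <- n
  attr(out, "band_level") <- band_level
  class(out) <- c("qq_summary", "data.frame")
  out
}

#' Empirical rejection rate with exact binomial confidence interval
#'
#' The fraction of p-values below `alpha`, with a Clopper-Pearson 95%
#' interval. Applied to null tests this estimates the type-I error rate; to
#' alternative tests, power.
#'
#' @param p_values P-values in \[0, 1\].
#' @param alpha Nominal level in (0, 1).
#' @return A `rate_estimate`: `alpha`, `n_tests`, `n_rejections`, `rate`,
#'   `ci_low`, `ci_high`.
#' @export
estimate_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  stopifnot(is.numeric(p_values), !anyNA(p_values),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  n <- length(p_values)
  x <- sum(p_values < alpha)
  ci <- stats::binom.test(x, n)$conf.int
  structure(
    list(
      alpha = alpha, n_tests = n, n_rejections = x,
      rate = x / n, ci_low = ci[1], ci_high = ci[2]
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rejection rate at alpha = %g: %d / %d = %.4f (95%% CI %.4f-%.4f)\n",
    x$alpha, x$n_rejections, x$n_tests, x$rate, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' Run a replicated simulate-inject-test experiment
#'
#' Orchestrates the full pipeline for a grid of error conditions over a fixed
#' panel: per replicate, simulate a trio cohort (ascertained on an affected
#' offspring when the panel carries a disease model), inject errors, tally
#' transmissions from the observed layer, and run the gene-collapsed TDT.
#' Gene p-values are pooled across replicates per condition; each condition
#' reports its aggregate tallies, rejection rate and QQ summary. Fully
#' reproducible from `seed`: sub-seeds are derived for the panel and for each
#' replicate-by-condition cell, and the same cohort realisation underlies all
#' conditions of a replicate (differences between conditions are purely the
#' injected errors).
#'
#' @param panel A `variant_panel`; if it carries a disease model, cohorts are
#'   ascertained with [simulate_affected_trios()].
#' @param conditions A named list of [error_spec()] objects (use
#'   `error_spec(2, 0)` style entries for a no-error reference).
#' @param n_trios Trios per cohort.
#' @param n_replicates Independent cohort replicates per condition.
#' @param alpha Nominal level for the rejection-rate estimate.
#' @param seed Integer seed for the whole experiment.
#' @return An `experiment_result`: per condition, a list with `spec`,
#'   `totals` (summed `P`, `Q` over replicates), `n_excluded`, `rate`
#'   (a [estimate_rate()] result over pooled gene p-values), `qq`
#'   (a [qq_summary()]), and `tally_text` (a formatted tally row); plus a
#'   `manifest` recording the configuration digest and seeds.
#' @export
run_experiment <- function(panel, conditions, n_trios = 100,
                           n_replicates = 20, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(panel, "variant_panel"), is.list(conditions),
            length(conditions) >= 1L)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("`conditions` must be a fully named list of error_spec objects",
         call. = FALSE)
  }
  for (cs in conditions) stopifnot(inherits(cs, "error_spec"))
  ascertained <- !is.null(attr(panel, "disease_model"))

  seeds <- derive_seeds(seed, n_replicates * (length(conditions) + 1L))
  cohort_seeds <- seeds[seq_len(n_replicates)]
  inject_seeds <- matrix(seeds[-seq_len(n_replicates)],
                         nrow = n_replicates, ncol = length(conditions))

  acc <- lapply(conditions, function(.) {
    list(P = 0, Q = 0, n_excluded = 0, p_values = vector("list", n_replicates))
  })

  for (r in seq_len(n_replicates)) {
    cohort <- if (ascertained) {
      simulate_affected_trios(panel, n_trios, seed = cohort_seeds[r])
    } else {
      simulate_trios(panel, n_trios, seed = cohort_seeds[r])
    }
    for (j in seq_along(conditions)) {
      spec <- conditions[[j]]
      injected <- if (spec$r1 > 0 || spec$r2 > 0) {
        inject_errors(cohort, spec, seed = inject_seeds[r, j])
      } else {
        cohort
      }
      counts <- tally(injected, layer = "observed")
      genes <- gene_tdt(counts, panel)
      nm <- names(conditions)[j]
      acc[[nm]]$P <- acc[[nm]]$P + counts$totals[["P"]]
      acc[[nm]]$Q <- acc[[nm]]$Q + counts$totals[["Q"]]
      acc[[nm]]$n_excluded <- acc[[nm]]$n_excluded + counts$n_excluded
      acc[[nm]]$p_values[[r]] <- genes$p_value
    }
  }

  results <- lapply(names(conditions), function(nm) {
    a <- acc[[nm]]
    pv <- unlist(a$p_values)
    list(
      condition = nm,
      spec = conditions[[nm]],
      totals = c(P = a$P, Q = a$Q),
      n_excluded = a$n_excluded,
      rate = estimate_rate(pv, alpha),
      qq = qq_summary(pv),
      tally_text = format_tally_cells(a$P, a$Q)
    )
  })
  names(results) <- names(conditions)
  structure(
    list(
      results = results,
      manifest = list(
        config_digest = digest_config(list(
          panel = as.data.frame(panel), conditions = conditions,
          n_trios = n_trios, n_replicates = n_replicates, alpha = alpha
        )),
        seed = seed,
        n_trios = n_trios,
        n_replicates = n_replicates,
        ascertained = ascertained
      )
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d condition(s), %d replicates of %d trios\n",
              length(x$results), x$manifest$n_replicates, x$manifest$n_trios))
  for (res in x$results) {
    cat(sprintf("  %-24s %s | rejection rate %.4f\n",
                res$condition,
                paste(res$tally_text, collapse = " / "),
                res$rate$rate))
  }
  invisible(x)
}
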