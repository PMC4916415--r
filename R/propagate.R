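# Closed-form expectations for how each calling-error scenario shifts the
# aggregate transmitted (T) / non-transmitted (U) allele tallies.

#' Nearest-integer transmitted percentage
#'
#' `100 * T / (T + U)` rounded to the nearest integer, ties away from zero —
#' the convention used when reporting tally tables.
#'
#' @param T,U Non-negative transmitted / non-transmitted totals with
#'   `T + U > 0`.
#' @return Integer percentage.
#' @examples
#' percent_transmitted(374502, 427972) # 47
#' percent_transmitted(1, 1)           # 50
#' @export
percent_transmitted <- function(T, U) {
  stop_if_not_count(T, "T"); stop_if_not_count(U, "U")
  if (T + U <= 0) stop("T + U must be positive", call. = FALSE)
  as.integer(floor(100 * T / (T + U) + 0.5))
}

#' Expected post-error transmission tallies under each scenario
#'
#' Propagates baseline aggregate tallies through one error scenario in
#' expectation, ignoring terms that require two rare alleles in a trio
#' (second order in allele frequency for rare panels):
#'
#' * **scenario 1** (`r1` in parents): a miscalled het parent's transmission
#'   becomes a Mendelian exclusion and its non-transmission becomes
#'   uninformative, thinning both tallies — `T' = (1-r1) T`,
#'   `U' = (1-r1) U`. The transmitted percentage is invariant.
#' * **scenario 2** (`r1` in offspring): a het child miscalled 0/0 converts a
#'   transmission into an apparent non-transmission — `T' = (1-r1) T`,
#'   `U' = U + r1 T`; the total is conserved and the apparent transmission
#'   rate drops below one half, inflating the TDT in the under-transmitted
#'   direction.
#' * **scenario 3** (`r2` in parents): every hom-ref targeted-parent cell
#'   miscalled het adds exactly one apparent non-transmission, whatever the
#'   child genotype — `T' = T`, `U' = U + r2 * homref_exposures`.
#' * **scenario 4** (`r2` in offspring): a hom-ref child with a het parent
#'   miscalled het converts a non-transmission into an apparent
#'   transmission — `T' = T + r2 U`, `U' = (1-r2) U`; double-hom-ref trios
#'   turned inconsistent contribute nothing.
#'
#' @param T,U Baseline transmitted / non-transmitted totals.
#' @param spec An [error_spec()].
#' @param homref_exposures Number of (targeted parent, variant) cells whose
#'   parent is hom-ref; required for scenario 3 only (see
#'   [count_homref_exposures()]).
#' @return A `propagation_result`: `T_in`, `U_in`, `T_out`, `U_out`,
#'   `pct_transmitted` (nearest-integer percentage of `T_out`), and the spec.
#' @examples
#' propagate(374502, 427972, error_spec(2, 0.10)) # 42% transmitted
#' @export
propagate <- function(T, U, spec, homref_exposures = NULL) {
  stop_if_not_count(T, "T"); stop_if_not_count(U, "U")
  stopifnot(inherits(spec, "error_spec"))
  out <- switch(spec$scenario,
    c(T_out = (1 - spec$r1) * T, U_out = (1 - spec$r1) * U),
    c(T_out = (1 - spec$r1) * T, U_out = U + spec$r1 * T),
    {
      if (is.null(homref_exposures)) {
        stop("scenario 3 requires `homref_exposures`", call. = FALSE)
      }
      stop_if_not_count(homref_exposures, "homref_exposures")
      c(T_out = T, U_out = U + spec$r2 * homref_exposures)
    },
    c(T_out = T + spec$r2 * U, U_out = (1 - spec$r2) * U)
  )
  structure(
    list(
      T_in = T, U_in = U,
      T_out = unname(out["T_out"]), U_out = unname(out["U_out"]),
      pct_transmitted = percent_transmitted(out[["T_out"]], out[["U_out"]]),
      spec = spec
    ),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "scenario %d: T %s -> %s, U %s -> %s (%d%% transmitted)\n",
    x$spec$scenario,
    format(x$T_in, big.mark = ","), format(round(x$T_out, 1), big.mark = ","),
    format(x$U_in, big.mark = ","), format(round(x$U_out, 1), big.mark = ","),
    x$pct_transmitted
  ))
  invisible(x)
}

# Per-cell (t, u) contributions for dosage matrices, 0 where the triple is
# incomplete or Mendelian-inconsistent.
cell_counts <- function(f, m, c_) {
  complete <- !(is.na(f) | is.na(m) | is.na(c_))
  cmin <- (f == 2L) + (m == 2L)
  cmax <- (f >= 1L) + (m >= 1L)
  ok <- complete & c_ >= cmin & c_ <= cmax
  k <- (f == 1L) + (m == 1L)
  t <- c_ - cmin
  u <- k - t
  t[!ok] <- 0L; u[!ok] <- 0L
  list(t = t, u = u)
}

#' Exact expected post-error tallies for a specific cohort
#'
#' Where [propagate()] works from aggregate baseline tallies alone (the
#' printed-table setting) and is first-order in allele frequency,
#' `expected_tally()` uses the cohort itself: for every eligible cell of a
#' targeted member (het for an `r1` flip, hom-ref for an `r2` flip) it
#' enumerates the tally change the flip would cause in that trio, and sums
#' `rate * change`. The result is the exact expectation of the post-injection
#' tally up to within-trio double-flip interactions, which are O(rate^2).
#'
#' @param cohort An unperturbed `trio_cohort`.
#' @param spec An [error_spec()].
#' @return A `propagation_result` (see [propagate()]) with an `exact`
#'   attribute set.
#' @export
expected_tally <- function(cohort, spec) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(spec, "error_spec"))
  if (isTRUE(cohort$perturbed)) {
    stop("expected_tally() needs the unperturbed baseline cohort", call. = FALSE)
  }
  g <- cohort$true
  base <- cell_counts(g$father, g$mother, g$child)
  T0 <- sum(base$t); U0 <- sum(base$u)
  dT <- 0; dU <- 0

  flip_delta <- function(member, from, to, rate) {
    eligible <- !is.na(g[[member]]) & g[[member]] == from
    if (!any(eligible) || rate == 0) return(c(0, 0))
    alt <- g
    alt[[member]][eligible] <- to
    post <- cell_counts(alt$father, alt$mother, alt$child)
    rate * c(sum((post$t - base$t)[eligible]),
             sum((post$u - base$u)[eligible]))
  }

  for (member in spec$targets) {
    if (spec$r1 > 0) {
      d <- flip_delta(member, 1L, 0L, spec$r1)
      dT <- dT + d[1]; dU <- dU + d[2]
    }
    if (spec$r2 > 0) {
      d <- flip_delta(member, 0L, 1L, spec$r2)
      dT <- dT + d[1]; dU <- dU + d[2]
    }
  }

  structure(
    list(
      T_in = T0, U_in = U0,
      T_out = T0 + dT, U_out = U0 + dU,
      pct_transmitted = percent_transmitted(T0 + dT, U0 + dU),
      spec = spec,
      exact = TRUE
    ),
    class = "propagation_result"
  )
}

#' Count hom-ref exposure cells for scenario-3 propagation
#'
#' The number of (targeted member, variant) cells whose true genotype is
#' hom-ref — each such cell, if miscalled het, adds one apparent
#' non-transmission to the tally.
#'
#' @param cohort A `trio_cohort`.
#' @param spec An [error_spec()]; its targets define the exposed members.
#' @return Integer count.
#' @export
count_homref_exposures <- function(cohort, spec) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(spec, "error_spec"))
  sum(vapply(
    spec$targets,
    function(m) sum(cohort$true[[m]] == 0L, na.rm = TRUE),
    numeric(1)
  ))
}
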