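# Genotype-calling error injection: the two dominant miscall modes at rare
# sites, applied to parents or offspring.

#' Specify a genotype-calling error scenario
#'
#' The two miscall modes modelled are `r1`, the probability that a true
#' heterozygote 0/1 is called reference homozygote 0/0 (the dominant error at
#' rare sites), and `r2`, the probability that a true 0/0 is called 0/1.
#' The four canonical scenarios apply one mode to one side of the trio:
#'
#' * scenario 1 — `r1` in parents (`r2 = 0`)
#' * scenario 2 — `r1` in offspring (`r2 = 0`)
#' * scenario 3 — `r2` in parents (`r1 = 0`)
#' * scenario 4 — `r2` in offspring (`r1 = 0`)
#'
#' @param scenario Integer 1-4.
#' @param rate The active rate (`r1` for scenarios 1-2, `r2` for 3-4), in
#'   \[0, 1\].
#' @return An `error_spec` with fields `scenario`, `r1`, `r2`, `targets`.
#' @examples
#' error_spec(2, 0.10) # 10% het -> hom-ref miscalls in offspring
#' @export
error_spec <- function(scenario, rate) {
  stopifnot(
    is.numeric(scenario), length(scenario) == 1L, scenario %in% 1:4,
    is.numeric(rate), length(rate) == 1L, rate >= 0, rate <= 1
  )
  scenario <- as.integer(scenario)
  targets <- if (scenario %in% c(1L, 3L)) c("father", "mother") else "child"
  structure(
    list(
      scenario = scenario,
      r1 = if (scenario <= 2L) rate else 0,
      r2 = if (scenario >= 3L) rate else 0,
      targets = targets
    ),
    class = "error_spec"
  )
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf("error_spec: scenario %d (r1 = %g, r2 = %g in %s)\n",
              x$scenario, x$r1, x$r2,
              if (identical(x$targets, "child")) "offspring" else "parents"))
  invisible(x)
}

#' Inject calling errors into the observed genotype layer
#'
#' For each targeted individual-variant cell independently: an observed 0/1
#' becomes 0/0 with probability `r1`; an observed 0/0 becomes 0/1 with
#' probability `r2`. Hom-alt calls (dosage 2) and missing calls are never
#' altered, non-targeted members are untouched, and the true layer is
#' preserved. Errors are applied once: injecting into an already-perturbed
#' cohort is a protocol error.
#'
#' @param cohort A `trio_cohort` whose observed layer is still pristine.
#' @param spec An [error_spec()].
#' @param seed Optional integer seed; the same seed reproduces the flips.
#' @return The cohort with its observed layer perturbed and `perturbed = TRUE`;
#'   an `error_spec` attribute records the applied scenario.
#' @export
inject_errors <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(spec, "error_spec"))
  if (isTRUE(cohort$perturbed)) {
    stop("cohort already perturbed: errors are applied exactly once",
         call. = FALSE)
  }
  with_seed(seed, {
    for (member in spec$targets) {
      g <- cohort$observed[[member]]
      # masks computed on the unperturbed genotypes so the two flip types
      # cannot chain within one injection
      het <- !is.na(g) & g == 1L
      hom <- !is.na(g) & g == 0L
      if (spec$r1 > 0 && any(het)) {
        flip <- het & stats::runif(length(g)) < spec$r1
        g[flip] <- 0L
      }
      if (spec$r2 > 0 && any(hom)) {
        flip <- hom & stats::runif(length(g)) < spec$r2
        g[flip] <- 1L
      }
      cohort$observed[[member]] <- g
    }
    cohort$perturbed <- TRUE
    attr(cohort, "error_spec") <- spec
    cohort
  })
}

#' Tabulate the genotype flips an injection produced
#'
#' Compares the true and observed layers and returns one row per changed
#' cell, for audit of an [inject_errors()] run.
#'
#' @param cohort A perturbed `trio_cohort`.
#' @return A data frame with columns `member`, `trio`, `variant_id`,
#'   `true_dosage`, `observed_dosage`.
#' @export
flip_log <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  out <- lapply(names(cohort$true), function(member) {
    d <- which(cohort$true[[member]] != cohort$observed[[member]], arr.ind = TRUE)
    if (nrow(d) == 0L) return(NULL)
    data.frame(
      member = member,
      trio = d[, 1L],
      variant_id = cohort$variant_ids[d[, 2L]],
      true_dosage = cohort$true[[member]][d],
      observed_dosage = cohort$observed[[member]][d],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      member = character(), trio = integer(), variant_id = character(),
      true_dosage = integer(), observed_dosage = integer(),
      stringsAsFactors = FALSE
    )
  }
  out
}
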