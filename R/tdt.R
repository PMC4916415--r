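# Mendelian screening, transmitted/non-transmitted allele counting from
# heterozygous parents, and the single-marker TDT.

#' Mendelian consistency of a trio genotype triple
#'
#' A triple is consistent when the child dosage is attainable from one allele
#' of each parent: each parent contributes 1 rare allele if hom-alt, 0 if
#' hom-ref, and either if heterozygous.
#'
#' @param father,mother,child Rare-allele dosages in \{0, 1, 2\}; vectors are
#'   recycled to a common length. `NA` yields `NA`.
#' @return Logical vector.
#' @examples
#' mendelian_consistent(0, 0, 1) # FALSE: 0/0 x 0/0 cannot yield a carrier
#' mendelian_consistent(1, 0, 2) # FALSE: hom-alt child needs alt from both
#' @export
mendelian_consistent <- function(father, mother, child) {
  cmin <- (father == 2L) + (mother == 2L)
  cmax <- (father >= 1L) + (mother >= 1L)
  child >= cmin & child <= cmax
}

#' Transmission contribution of one consistent trio triple
#'
#' Only heterozygous parents are informative for transmission. Each het
#' parent either transmitted the rare allele (a `t` event) or did not (a `u`
#' event); with `k` het parents and a fixed contribution of one rare allele
#' from each hom-alt parent, the child dosage determines `t = child - fixed`
#' and `u = k - t`, the same for every parental transmission compatible with
#' the child. The double-het ambiguous triple (1,1,1) therefore contributes
#' (1,1), the classical TDT convention.
#'
#' @inheritParams mendelian_consistent
#' @return A two-column integer matrix with columns `t` (transmitted) and `u`
#'   (non-transmitted). Triples must be complete and Mendelian-consistent;
#'   others are rejected.
#' @examples
#' count_transmissions(1, 0, 0) # het parent did not transmit: (0, 1)
#' count_transmissions(1, 1, 2) # both het parents transmitted: (2, 0)
#' @export
count_transmissions <- function(father, mother, child) {
  n <- max(length(father), length(mother), length(child))
  father <- rep_len(father, n); mother <- rep_len(mother, n)
  child <- rep_len(child, n)
  if (anyNA(father) || anyNA(mother) || anyNA(child)) {
    stop("missing dosages: screen completeness before counting", call. = FALSE)
  }
  ok <- mendelian_consistent(father, mother, child)
  if (!all(ok)) {
    stop(sprintf("Mendelian-inconsistent triple(s) at position(s) %s",
                 paste(utils::head(which(!ok), 5L), collapse = ", ")),
         call. = FALSE)
  }
  k <- (father == 1L) + (mother == 1L)
  fixed <- (father == 2L) + (mother == 2L)
  t <- as.integer(child - fixed)
  cbind(t = t, u = as.integer(k - t))
}

#' Tally transmissions across a cohort
#'
#' Per variant, sums [count_transmissions()] over the trios whose genotype
#' triple at that variant is complete and Mendelian-consistent. Inconsistent
#' trio-variant combinations are excluded at that variant only (the trio
#' remains in the tally elsewhere) and counted in `n_excluded`;
#' missing-genotype combinations are dropped without imputation.
#'
#' @param cohort A `trio_cohort`.
#' @param layer `"observed"` (default) or `"true"`: which genotype layer to
#'   tally. Comparing the two isolates the effect of injected errors.
#' @return A `transmission_counts` object: `per_variant` data frame
#'   (`variant_id`, `p`, `q`, `n_excluded`), `totals = c(P, Q)` and the total
#'   `n_excluded`.
#' @export
tally <- function(cohort, layer = c("observed", "true")) {
  stopifnot(inherits(cohort, "trio_cohort"))
  layer <- match.arg(layer)
  g <- if (layer == "observed") cohort$observed else cohort$true
  f <- g$father; m <- g$mother; c_ <- g$child

  complete <- !(is.na(f) | is.na(m) | is.na(c_))
  cmin <- (f == 2L) + (m == 2L)
  cmax <- (f >= 1L) + (m >= 1L)
  consistent <- complete & c_ >= cmin & c_ <= cmax

  k <- (f == 1L) + (m == 1L)
  t <- c_ - cmin           # cmin == fixed hom-alt contribution
  u <- k - t
  t[!consistent] <- 0L
  u[!consistent] <- 0L

  p <- colSums(t)
  q <- colSums(u)
  excl <- colSums(complete & !consistent)

  structure(
    list(
      per_variant = data.frame(
        variant_id = cohort$variant_ids,
        p = as.integer(p),
        q = as.integer(q),
        n_excluded = as.integer(excl),
        stringsAsFactors = FALSE
      ),
      totals = c(P = sum(p), Q = sum(q)),
      n_excluded = sum(excl),
      layer = layer
    ),
    class = "transmission_counts"
  )
}

#' @export
print.transmission_counts <- function(x, ...) {
  tot <- x$totals
  cat(sprintf(
    "transmission_counts (%s layer): %d variants; P = %s, Q = %s (%d%% transmitted); %d Mendelian exclusions\n",
    x$layer, nrow(x$per_variant),
    format(tot[["P"]], big.mark = ","), format(tot[["Q"]], big.mark = ","),
    percent_transmitted(tot[["P"]], tot[["Q"]]), x$n_excluded
  ))
  invisible(x)
}

#' Single-marker transmission disequilibrium test
#'
#' The TDT statistic is `(p - q)^2 / (p + q)` for `p` transmitted and `q`
#' non-transmitted rare alleles from heterozygous parents, referred to the
#' upper tail of a 1-df chi-square under the null of fair transmission.
#' Uninformative inputs (`p + q = 0`) get an `NA` statistic and p-value 1.
#'
#' @param p,q Non-negative counts; vectors are accepted and recycled.
#' @return A data frame with columns `statistic` and `p_value`.
#' @examples
#' tdt_test(10, 0) # statistic 10
#' tdt_test(5, 5)  # statistic 0, p-value 1
#' @export
tdt_test <- function(p, q) {
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  if (any(p < 0 | q < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- p + q
  stat <- ifelse(tot > 0, (p - q)^2 / tot, NA_real_)
  pval <- ifelse(tot > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  data.frame(statistic = stat, p_value = pval)
}

#' Per-variant TDT results from a tally
#'
#' @param counts A [tally()] result.
#' @return The `per_variant` table with `statistic` and `p_value` appended.
#' @export
tdt_results <- function(counts) {
  stopifnot(inherits(counts, "transmission_counts"))
  cbind(counts$per_variant, tdt_test(counts$per_variant$p, counts$per_variant$q))
}
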