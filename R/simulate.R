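# Trio cohort simulation: Hardy-Weinberg parents, random transmission,
# optional affected-offspring ascertainment under a logistic disease model.

new_trio_cohort <- function(true, transmitted, affected, variant_ids, n_trios) {
  for (m in names(true)) {
    dimnames(true[[m]]) <- NULL
    storage.mode(true[[m]]) <- "integer"
  }
  structure(
    list(
      n_trios = n_trios,
      variant_ids = variant_ids,
      true = true,
      observed = true,
      transmitted = transmitted,
      affected = affected,
      perturbed = FALSE
    ),
    class = "trio_cohort"
  )
}

# Draw one batch of trios at the given frequencies. Returns parent dosage
# matrices, transmitted-allele matrices and child dosages (n_trios x n_var).
sim_trio_batch <- function(freqs, n_trios) {
  m <- length(freqs)
  draw <- function() {
    matrix(
      stats::rbinom(n_trios * m, 1L, rep(freqs, each = n_trios)),
      nrow = n_trios, ncol = m
    )
  }
  fa1 <- draw(); fa2 <- draw()
  mo1 <- draw(); mo2 <- draw()
  # which of the two parental alleles is transmitted, chosen uniformly
  pickf <- matrix(stats::rbinom(n_trios * m, 1L, 0.5), n_trios, m)
  pickm <- matrix(stats::rbinom(n_trios * m, 1L, 0.5), n_trios, m)
  tf <- fa1 * pickf + fa2 * (1L - pickf)
  tm <- mo1 * pickm + mo2 * (1L - pickm)
  list(
    father = fa1 + fa2,
    mother = mo1 + mo2,
    child = tf + tm,
    trans_father = tf,
    trans_mother = tm
  )
}

#' Simulate unascertained trios over a variant panel
#'
#' Parental rare-allele dosages are drawn independently per variant under
#' Hardy-Weinberg equilibrium at the panel frequency; each child receives one
#' allele from each parent, chosen uniformly at random. Variants are
#' independent (no linkage). The transmitted allele from each parent is
#' recorded so that transmission counts can be checked against the
#' construction.
#'
#' The observed genotype layer is initialized equal to the true layer; use
#' [inject_errors()] to perturb it.
#'
#' @param panel A [sample_panel()] result.
#' @param n_trios Number of trios (>= 1).
#' @param seed Optional integer seed.
#' @return A `trio_cohort`: true and observed dosage matrices
#'   (`n_trios x n_variants`, entries 0/1/2) for `father`, `mother`, `child`;
#'   transmitted-allele matrices per parent; an `affected` flag per child
#'   (all `TRUE`: trio designs ascertain on the offspring, which is vacuous
#'   when no disease model acts).
#' @examples
#' panel <- sample_panel(2, 3, maf_spectrum = maf_spectrum_fixed(0.1), seed = 1)
#' coh <- simulate_trios(panel, 50, seed = 2)
#' all(mendelian_consistent(coh$true$father, coh$true$mother, coh$true$child))
#' @export
simulate_trios <- function(panel, n_trios, seed = NULL) {
  stopifnot(inherits(panel, "variant_panel"),
            is.numeric(n_trios), length(n_trios) == 1L, n_trios >= 1)
  n_trios <- as.integer(n_trios)
  with_seed(seed, {
    b <- sim_trio_batch(panel$rare_allele_freq, n_trios)
    new_trio_cohort(
      true = list(father = b$father, mother = b$mother, child = b$child),
      transmitted = list(father = b$trans_father, mother = b$trans_mother),
      affected = rep(TRUE, n_trios),
      variant_ids = panel$variant_id,
      n_trios = n_trios
    )
  })
}

#' Simulate trios ascertained for an affected offspring
#'
#' Repeatedly simulates candidate trios and retains those whose child is
#' affected under the panel's logistic disease model: the affection
#' probability is `plogis(qlogis(baseline_prevalence) + beta * k)` where `k`
#' is the child's causal rare-allele count. Exactly `n_trios` affected trios
#' are returned.
#'
#' Because variants are independent and affection depends only on causal
#' variants, candidates are screened on the causal subset of the panel and
#' non-causal genotypes are filled in for accepted trios afterwards; the
#' retained joint distribution is identical to screening full trios.
#'
#' @param panel A panel with [attach_disease_model()] applied.
#' @param n_trios Number of affected trios to return.
#' @param seed Optional integer seed.
#' @param max_attempts Candidate-trio budget; the function fails with a clear
#'   message if the acceptance probability is too low to reach `n_trios`
#'   within it.
#' @return A `trio_cohort` of affected trios (see [simulate_trios()]).
#' @export
simulate_affected_trios <- function(panel, n_trios, seed = NULL,
                                    max_attempts = 1000L * n_trios) {
  stopifnot(inherits(panel, "variant_panel"),
            is.numeric(n_trios), length(n_trios) == 1L, n_trios >= 1)
  model <- attr(panel, "disease_model")
  if (is.null(model)) {
    stop("panel has no attached disease model; see attach_disease_model()",
         call. = FALSE)
  }
  n_trios <- as.integer(n_trios)
  causal <- which(panel$is_causal)
  intercept <- stats::qlogis(model$baseline_prevalence)

  with_seed(seed, {
    n_var <- nrow(panel)
    mats <- list(
      father = matrix(NA_integer_, n_trios, n_var),
      mother = matrix(NA_integer_, n_trios, n_var),
      child = matrix(NA_integer_, n_trios, n_var)
    )
    trans <- list(
      father = matrix(NA_integer_, n_trios, n_var),
      mother = matrix(NA_integer_, n_trios, n_var)
    )

    accepted <- 0L
    attempts <- 0L
    batch <- max(n_trios, ceiling(n_trios / model$baseline_prevalence / 4))
    while (accepted < n_trios) {
      if (attempts >= max_attempts) {
        stop(sprintf(
          paste0("affected-trio acceptance too low: %d accepted after %d ",
                 "candidates; raise max_attempts or baseline_prevalence"),
          accepted, attempts
        ), call. = FALSE)
      }
      nb <- as.integer(min(batch, max_attempts - attempts))
      b <- sim_trio_batch(panel$rare_allele_freq[causal], nb)
      attempts <- attempts + nb
      k <- if (length(causal)) rowSums(b$child) else rep(0L, nb)
      p_aff <- stats::plogis(intercept + model$beta * k)
      keep <- which(stats::runif(nb) < p_aff)
      if (length(keep) == 0L) next
      keep <- keep[seq_len(min(length(keep), n_trios - accepted))]
      rows <- accepted + seq_along(keep)
      mats$father[rows, causal] <- b$father[keep, , drop = FALSE]
      mats$mother[rows, causal] <- b$mother[keep, , drop = FALSE]
      mats$child[rows, causal] <- b$child[keep, , drop = FALSE]
      trans$father[rows, causal] <- b$trans_father[keep, , drop = FALSE]
      trans$mother[rows, causal] <- b$trans_mother[keep, , drop = FALSE]
      accepted <- accepted + length(keep)
    }

    noncausal <- setdiff(seq_len(n_var), causal)
    if (length(noncausal)) {
      b <- sim_trio_batch(panel$rare_allele_freq[noncausal], n_trios)
      mats$father[, noncausal] <- b$father
      mats$mother[, noncausal] <- b$mother
      mats$child[, noncausal] <- b$child
      trans$father[, noncausal] <- b$trans_father
      trans$mother[, noncausal] <- b$trans_mother
    }

    new_trio_cohort(
      true = mats,
      transmitted = trans,
      affected = rep(TRUE, n_trios),
      variant_ids = panel$variant_id,
      n_trios = n_trios
    )
  })
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(
    "trio_cohort: %d trios x %d variants (%s)\n",
    x$n_trios, length(x$variant_ids),
    if (x$perturbed) "observed layer perturbed" else "error-free"
  ))
  invisible(x)
}
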