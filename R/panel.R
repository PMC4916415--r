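#' Rare-allele frequency spectra for panel simulation
#'
#' Factories returning sampling functions `function(n, cap)` that draw `n`
#' rare-allele frequencies bounded above by `cap`. These are the
#' `maf_spectrum` argument of [sample_panel()].
#'
#' `maf_spectrum_neutral()` draws from the density proportional to `1/f`
#' truncated to `[1/(2 * n_eff), cap]`, the shape expected for neutral sites
#' in a population of effective size `n_eff`; it is dominated by very rare
#' variants, as observed in sequencing panels. `maf_spectrum_fixed()` is a
#' point mass. `maf_spectrum_table()` resamples an explicit frequency table
#' (e.g. frequencies estimated from a reference cohort), discarding entries
#' above `cap`.
#'
#' @param n_eff Effective population size controlling the lower frequency
#'   bound `1/(2 * n_eff)`.
#' @param f A single frequency in (0, 0.5].
#' @param freqs Numeric vector of frequencies to resample from.
#' @return A function `(n, cap)` returning `n` frequencies in `(0, cap]`.
#' @examples
#' spec <- maf_spectrum_neutral(n_eff = 5000)
#' f <- spec(1000, 0.05)
#' range(f)
#' @export
maf_spectrum_neutral <- function(n_eff = 5000) {
  stopifnot(is.numeric(n_eff), length(n_eff) == 1L, n_eff >= 1)
  function(n, cap) {
    lo <- 1 / (2 * n_eff)
    if (lo >= cap) {
      stop("maf spectrum has zero mass: 1/(2*n_eff) >= maf_cap", call. = FALSE)
    }
    # inverse CDF of density 1/f on [lo, cap]
    lo * (cap / lo)^stats::runif(n)
  }
}

#' @rdname maf_spectrum_neutral
#' @export
maf_spectrum_fixed <- function(f) {
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 0.5)
  function(n, cap) {
    if (f > cap) stop("fixed frequency exceeds maf_cap", call. = FALSE)
    rep(f, n)
  }
}

#' @rdname maf_spectrum_neutral
#' @export
maf_spectrum_table <- function(freqs) {
  stopifnot(is.numeric(freqs), length(freqs) >= 1L, all(freqs > 0))
  function(n, cap) {
    keep <- freqs[freqs <= cap]
    if (length(keep) == 0L) {
      stop("maf spectrum has zero mass below maf_cap", call. = FALSE)
    }
    sample(keep, n, replace = TRUE)
  }
}

#' Simulate a rare-variant gene panel
#'
#' Builds the variant/gene structure over which trio cohorts are simulated:
#' each variant belongs to exactly one gene and carries a fixed rare-allele
#' frequency drawn from `maf_spectrum`. The rare allele is defined at panel
#' creation and is never re-estimated from a sample.
#'
#' @param n_genes Number of genes (>= 1).
#' @param variants_per_gene Either a single positive integer (all genes equal),
#'   an integer vector of length `n_genes`, or a function `(n_genes)` returning
#'   such a vector.
#' @param maf_spectrum A sampling function `(n, cap)` such as those returned by
#'   [maf_spectrum_neutral()], [maf_spectrum_fixed()] or [maf_spectrum_table()].
#' @param maf_cap Upper bound on rare-allele frequency, in (0, 0.5]. Panels of
#'   the kind used in type-I studies cap at 0.05; stricter rare-variant power
#'   panels cap at 0.01.
#' @param seed Optional integer seed; the same seed reproduces the panel
#'   exactly.
#' @return A `variant_panel`: a data frame with columns `variant_id`,
#'   `gene_id`, `chrom`, `position`, `rare_allele_freq`, `is_causal`, plus a
#'   `maf_cap` attribute. `is_causal` is all-`FALSE` until a disease model is
#'   attached with [attach_disease_model()].
#' @seealso [simulate_trios()], [attach_disease_model()]
#' @examples
#' panel <- sample_panel(10, variants_per_gene = 5, maf_cap = 0.05, seed = 1)
#' table(panel$gene_id)
#' @export
sample_panel <- function(n_genes,
                         variants_per_gene = 10L,
                         maf_spectrum = maf_spectrum_neutral(),
                         maf_cap = 0.05,
                         seed = NULL) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1)
  n_genes <- as.integer(n_genes)
  if (!is.numeric(maf_cap) || length(maf_cap) != 1L ||
      maf_cap <= 0 || maf_cap > 0.5) {
    stop("`maf_cap` must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.function(maf_spectrum)) {
    stop("`maf_spectrum` must be a sampling function (n, cap)", call. = FALSE)
  }

  with_seed(seed, {
    counts <- if (is.function(variants_per_gene)) {
      variants_per_gene(n_genes)
    } else if (length(variants_per_gene) == 1L) {
      rep(as.integer(variants_per_gene), n_genes)
    } else {
      as.integer(variants_per_gene)
    }
    if (length(counts) != n_genes || any(is.na(counts)) || any(counts < 1)) {
      stop("`variants_per_gene` must yield one positive count per gene",
           call. = FALSE)
    }
    n_var <- sum(counts)
    freqs <- maf_spectrum(n_var, maf_cap)
    if (length(freqs) != n_var || any(!is.finite(freqs)) ||
        any(freqs <= 0) || any(freqs > maf_cap)) {
      stop("`maf_spectrum` must return frequencies in (0, maf_cap]",
           call. = FALSE)
    }
    gene_id <- rep(sprintf("gene%04d", seq_len(n_genes)), counts)
    panel <- data.frame(
      variant_id = sprintf("var%07d", seq_len(n_var)),
      gene_id = gene_id,
      chrom = "1",
      position = seq_len(n_var) * 100L,
      rare_allele_freq = freqs,
      is_causal = FALSE,
      stringsAsFactors = FALSE
    )
    attr(panel, "maf_cap") <- maf_cap
    class(panel) <- c("variant_panel", "data.frame")
    validate_panel(panel)
    panel
  })
}

#' Disease model for ascertained (affected-offspring) trio simulation
#'
#' A logistic penetrance model: the log-odds of the offspring being affected
#' is `qlogis(baseline_prevalence) + beta * (causal rare-allele count)`, so a
#' child carrying no causal alleles is affected with probability
#' `baseline_prevalence` and each causal allele multiplies the odds by
#' `exp(beta)`.
#'
#' @param causal_fraction Fraction of panel variants flagged causal, in
#'   \[0, 1\].
#' @param beta Per-causal-allele log odds ratio; `log(4)` is a typical strong
#'   rare-variant effect.
#' @param baseline_prevalence Disease probability for a causal-allele-free
#'   child, in (0, 1). The default 0.01 matches the order of magnitude of the
#'   neuropsychiatric traits trio studies target and keeps the effective
#'   per-allele odds ratio close to `exp(beta)` (a high baseline attenuates
#'   it).
#' @return A `disease_model` object.
#' @export
disease_model <- function(causal_fraction = 0.30,
                          beta = log(4),
                          baseline_prevalence = 0.01) {
  stopifnot(
    is.numeric(causal_fraction), length(causal_fraction) == 1L,
    causal_fraction >= 0, causal_fraction <= 1,
    is.numeric(beta), length(beta) == 1L, is.finite(beta),
    is.numeric(baseline_prevalence), length(baseline_prevalence) == 1L,
    baseline_prevalence > 0, baseline_prevalence < 1
  )
  structure(
    list(
      causal_fraction = causal_fraction,
      beta = beta,
      baseline_prevalence = baseline_prevalence
    ),
    class = "disease_model"
  )
}

#' Attach a disease model to a panel
#'
#' Flags `round(causal_fraction * nrow(panel))` randomly chosen variants as
#' causal and records the model on the panel. Required before
#' [simulate_affected_trios()].
#'
#' @param panel A [sample_panel()] result.
#' @param model A [disease_model()].
#' @param seed Optional integer seed for the causal-variant draw.
#' @return The panel with `is_causal` set and a `disease_model` attribute.
#' @export
attach_disease_model <- function(panel, model, seed = NULL) {
  stopifnot(inherits(panel, "variant_panel"), inherits(model, "disease_model"))
  n_causal <- round(model$causal_fraction * nrow(panel))
  with_seed(seed, {
    panel$is_causal <- FALSE
    panel$is_causal[sample.int(nrow(panel), n_causal)] <- TRUE
    attr(panel, "disease_model") <- model
    validate_panel(panel)
    panel
  })
}

#' Validate panel invariants
#'
#' Checks that every frequency lies in `(0, maf_cap]`, every variant belongs
#' to exactly one gene, and causal flags are only present when a disease model
#' is attached. Called internally by the constructors; exported for use on
#' panels read from disk.
#'
#' @param panel A `variant_panel`.
#' @return The panel, invisibly; errors describe the first violated invariant.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "variant_panel"))
  cap <- attr(panel, "maf_cap")
  f <- panel$rare_allele_freq
  skeleton <- isTRUE(attr(panel, "skeleton"))
  if (!skeleton && (any(!is.finite(f)) || any(f <= 0) || any(f > cap))) {
    stop("panel frequencies must lie in (0, maf_cap]", call. = FALSE)
  }
  if (anyDuplicated(panel$variant_id)) {
    stop("duplicate variant ids: each variant maps to exactly one gene",
         call. = FALSE)
  }
  if (any(panel$is_causal) && is.null(attr(panel, "disease_model"))) {
    stop("causal flags present without an attached disease model",
         call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf(
    "variant_panel: %d variants in %d genes (MAF cap %g)%s\n",
    nrow(x), length(unique(x$gene_id)), attr(x, "maf_cap"),
    if (is.null(attr(x, "disease_model"))) "" else
      sprintf(", %d causal", sum(x$is_causal))
  ))
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
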