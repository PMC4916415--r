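# Brute-force transmission oracle: enumerate the parental allele choices for
# each of the 27 dosage triples, independent of the package's closed-form
# counting logic.
oracle_triples <- function() {
  alleles <- function(d) switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  grid <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  grid$consistent <- FALSE
  grid$t <- NA_integer_
  grid$u <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    fa <- alleles(grid$f[i])
    mo <- alleles(grid$m[i])
    k <- (grid$f[i] == 1L) + (grid$m[i] == 1L)
    tu <- NULL
    for (af in fa) {
      for (am in mo) {
        if (af + am == grid$c[i]) {
          t <- (grid$f[i] == 1L) * af + (grid$m[i] == 1L) * am
          tu <- rbind(tu, c(t, k - t))
        }
      }
    }
    if (!is.null(tu)) {
      grid$consistent[i] <- TRUE
      # every compatible transmission yields the same contribution
      stopifnot(nrow(unique(tu)) == 1L)
      grid$t[i] <- tu[1L, 1L]
      grid$u[i] <- tu[1L, 2L]
    }
  }
  grid
}

# Minimal cohort with hand-set genotypes, for targeted tally checks.
manual_cohort <- function(father, mother, child, variant_ids = NULL) {
  father <- as.matrix(father); mother <- as.matrix(mother)
  child <- as.matrix(child)
  storage.mode(father) <- "integer"
  storage.mode(mother) <- "integer"
  storage.mode(child) <- "integer"
  ids <- variant_ids
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(ncol(father)))
  structure(
    list(
      n_trios = nrow(father),
      variant_ids = ids,
      true = list(father = father, mother = mother, child = child),
      observed = list(father = father, mother = mother, child = child),
      transmitted = NULL,
      affected = rep(TRUE, nrow(father)),
      perturbed = FALSE
    ),
    class = "trio_cohort"
  )
}
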