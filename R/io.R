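# VCF / PED / gene-map readers and writers, and tally-table formatting.
# Dialects: VCF v4.2 with GT only, unphased "0/1" notation; 6-column
# PLINK-compatible PED; gene map as a two-column TSV.

dosage_to_gt <- c("0/0", "0/1", "1/1")

gt_to_dosage <- function(gt) {
  gt <- sub("\\|", "/", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt == "1/1"] <- 2L
  bad <- !is.na(gt) & is.na(out) & !gt %in% c("./.", ".")
  if (any(bad)) {
    stop(sprintf("malformed GT value(s): %s",
                 paste(utils::head(unique(gt[bad]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

trio_sample_ids <- function(n_trios) {
  fam <- sprintf("fam%04d", seq_len(n_trios))
  list(
    family = fam,
    father = paste0(fam, "_fa"),
    mother = paste0(fam, "_mo"),
    child = paste0(fam, "_ch")
  )
}

#' Write a trio cohort as VCF + PED + gene map
#'
#' Emits `prefix.vcf` (VCF v4.2, one sample per individual, GT only, missing
#' genotypes as `./.`), `prefix.ped` (6-column PLINK-style pedigree; children
#' of ascertained cohorts are coded affected) and, when a panel is given,
#' `prefix.genes.tsv` (tab-separated `gene_id`, `variant_id`). Every file
#' header embeds an MD5 digest of the generating configuration for
#' provenance.
#'
#' @param cohort A `trio_cohort`.
#' @param prefix Output path prefix.
#' @param panel Optional `variant_panel` supplying positions and the gene
#'   map; without it, positions are consecutive.
#' @param layer Which genotype layer to write (`"observed"` or `"true"`).
#' @return Invisibly, the paths written.
#' @export
write_trio_cohort <- function(cohort, prefix, panel = NULL,
                              layer = c("observed", "true")) {
  stopifnot(inherits(cohort, "trio_cohort"))
  layer <- match.arg(layer)
  g <- if (layer == "observed") cohort$observed else cohort$true
  n <- cohort$n_trios
  m <- length(cohort$variant_ids)
  ids <- trio_sample_ids(n)
  digest <- digest_config(list(
    n_trios = n, variant_ids = cohort$variant_ids,
    perturbed = cohort$perturbed, layer = layer
  ))

  chrom <- if (is.null(panel)) rep("1", m) else panel$chrom
  pos <- if (is.null(panel)) seq_len(m) else panel$position

  # genotype block: variants in rows, samples father/mother/child per trio
  gt_block <- matrix("./.", nrow = m, ncol = 3L * n)
  for (k in seq_len(3L)) {
    member <- c("father", "mother", "child")[k]
    dm <- g[[member]]
    cols <- seq.int(k, by = 3L, length.out = n)
    gt <- matrix(dosage_to_gt[dm + 1L], nrow = n, ncol = m)
    gt[is.na(dm)] <- "./."
    gt_block[, cols] <- t(gt)
  }
  sample_names <- character(3L * n)
  sample_names[seq.int(1L, by = 3L, length.out = n)] <- ids$father
  sample_names[seq.int(2L, by = 3L, length.out = n)] <- ids$mother
  sample_names[seq.int(3L, by = 3L, length.out = n)] <- ids$child

  vcf_path <- paste0(prefix, ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triotdt",
    paste0("##triotdt_config_digest=", digest),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- paste(
    chrom, pos, cohort$variant_ids, "A", "C", ".", ".", ".", "GT",
    apply(gt_block, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), vcf_path)

  ped_path <- paste0(prefix, ".ped")
  ped <- data.frame(
    family = rep(ids$family, each = 3L),
    individual = as.vector(rbind(ids$father, ids$mother, ids$child)),
    father = as.vector(rbind("0", "0", ids$father)),
    mother = as.vector(rbind("0", "0", ids$mother)),
    sex = rep(c(1L, 2L, 0L), n),
    affection = as.vector(rbind(1L, 1L, ifelse(cohort$affected, 2L, 1L))),
    stringsAsFactors = FALSE
  )
  writeLines(
    c(paste0("# triotdt_config_digest=", digest),
      do.call(paste, c(ped, sep = "\t"))),
    ped_path
  )

  paths <- c(vcf = vcf_path, ped = ped_path)
  if (!is.null(panel) && !all(is.na(panel$gene_id))) {
    gm_path <- paste0(prefix, ".genes.tsv")
    writeLines(
      c(paste0("# triotdt_config_digest=", digest),
        "gene_id\tvariant_id",
        paste(panel$gene_id, panel$variant_id, sep = "\t")),
      gm_path
    )
    paths <- c(paths, gene_map = gm_path)
  }
  invisible(paths)
}

#' Read a 6-column pedigree file
#'
#' Whitespace-separated PLINK-style PED, `#` comments allowed. Families must
#' be trios: exactly one child whose father and mother ids appear in the same
#' family, parents founders.
#'
#' @param path PED file path.
#' @return A data frame of pedigree records with a `role` column
#'   (father/mother/child), ordered family by family.
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(
    path, header = FALSE, comment.char = "#", stringsAsFactors = FALSE,
    col.names = c("family", "individual", "father", "mother", "sex", "affection"),
    colClasses = c(rep("character", 4L), "integer", "integer")
  )
  if (anyDuplicated(ped$individual)) {
    stop("duplicate individual ids in PED", call. = FALSE)
  }
  if (any(ped$father == ped$individual | ped$mother == ped$individual)) {
    stop("individual listed as its own parent in PED", call. = FALSE)
  }
  ped$role <- NA_character_
  for (fam in unique(ped$family)) {
    rows <- which(ped$family == fam)
    sub <- ped[rows, ]
    kids <- which(sub$father != "0" & sub$mother != "0")
    founders <- which(sub$father == "0" & sub$mother == "0")
    ok <- length(rows) == 3L && length(kids) == 1L && length(founders) == 2L &&
      all(c(sub$father[kids], sub$mother[kids]) %in% sub$individual)
    if (!ok) {
      stop(sprintf("family %s is not a trio (one child, both parents present)",
                   fam), call. = FALSE)
    }
    ped$role[rows[kids]] <- "child"
    ped$role[rows[sub$individual == sub$father[kids]]] <- "father"
    ped$role[rows[sub$individual == sub$mother[kids]]] <- "mother"
  }
  ped
}

#' Read a trio cohort from VCF + PED
#'
#' Loads biallelic GT records, maps them to rare-allele (ALT) dosages, and
#' arranges them in PED trio order. Multiallelic records are rejected with
#' their positions listed; VCF/PED sample mismatches are named explicitly.
#' Both genotype layers of the returned cohort hold the genotypes as read
#' (for real data the truth is unknown; injection treats the as-read layer as
#' the baseline).
#'
#' @param vcf_path,ped_path Input file paths.
#' @return A list: `cohort` (a `trio_cohort`), `panel` (a skeleton
#'   `variant_panel` with positions but no frequencies) and `ped`.
#' @export
read_trio_vcf <- function(vcf_path, ped_path) {
  ped <- read_ped(ped_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix # always a character matrix, even for one record
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop(sprintf("multiallelic record(s) not supported at: %s",
                 paste(utils::head(
                   paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 5L
                 ), collapse = ", ")),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)
  missing_in_vcf <- setdiff(ped$individual, vcf_samples)
  if (length(missing_in_vcf)) {
    stop(sprintf("PED individual(s) absent from VCF: %s",
                 paste(missing_in_vcf, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(vcf_samples, ped$individual)
  if (length(extra)) {
    stop(sprintf("VCF sample(s) absent from PED: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }

  m <- nrow(gt)
  variant_ids <- fix[, "ID"]
  if (any(is.na(variant_ids) | variant_ids == ".")) {
    variant_ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  }
  roles <- c("father", "mother", "child")
  fams <- unique(ped$family)
  mats <- lapply(roles, function(role) {
    role_ind <- ped$individual[ped$role == role]
    ind <- role_ind[match(fams, ped$family[ped$role == role])]
    d <- gt_to_dosage(as.vector(gt[, ind, drop = FALSE]))
    t(matrix(d, nrow = m, ncol = length(fams)))
  })
  names(mats) <- roles

  cohort <- new_trio_cohort(
    true = mats,
    transmitted = NULL,
    affected = ped$affection[ped$role == "child"][
      match(fams, ped$family[ped$role == "child"])] == 2L,
    variant_ids = unname(variant_ids),
    n_trios = length(fams)
  )
  panel <- data.frame(
    variant_id = unname(variant_ids),
    gene_id = NA_character_,
    chrom = unname(fix[, "CHROM"]),
    position = as.integer(fix[, "POS"]),
    rare_allele_freq = NA_real_,
    is_causal = FALSE,
    stringsAsFactors = FALSE
  )
  attr(panel, "maf_cap") <- NA_real_
  attr(panel, "skeleton") <- TRUE
  class(panel) <- c("variant_panel", "data.frame")
  list(cohort = cohort, panel = panel, ped = ped)
}

#' Read a two-column gene map
#'
#' @param path TSV with header columns `gene_id`, `variant_id`.
#' @return A data frame.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "variant_id") %in% names(gm))) {
    stop("gene map needs `gene_id` and `variant_id` columns", call. = FALSE)
  }
  gm
}

format_tally_cells <- function(T, U) {
  pct <- percent_transmitted(T, U)
  c(
    transmitted = sprintf("%s (%d%%)", format(round(T), big.mark = ","), pct),
    non_transmitted = sprintf("%s (%d%%)",
                              format(round(U), big.mark = ","), 100L - pct)
  )
}

#' Format aggregate tallies as a two-row table
#'
#' Renders transmitted / non-transmitted totals as thousands-separated counts
#' with nearest-integer percentages, one column per condition — the standard
#' presentation for trio transmission tallies.
#'
#' @param totals A list (or single vector) of `c(P, Q)` total pairs, or
#'   [tally()] results; one column each.
#' @param labels Optional column labels (defaults to the list names).
#' @param file Optional path; when given the table is also written as TSV.
#' @return A character matrix with rows `Transmitted` and `Non-transmitted`.
#' @examples
#' write_tally_table(list(Null = c(P = 374502, Q = 427972)))
#' @export
write_tally_table <- function(totals, labels = NULL, file = NULL) {
  if (inherits(totals, "transmission_counts") ||
      (is.numeric(totals) && length(totals) == 2L)) {
    totals <- list(totals)
  }
  cells <- vapply(totals, function(x) {
    if (inherits(x, "transmission_counts")) x <- x$totals
    format_tally_cells(x[[1L]], x[[2L]])
  }, character(2L))
  cells <- matrix(cells, nrow = 2L,
                  dimnames = list(c("Transmitted", "Non-transmitted"),
                                  labels %||% names(totals)))
  if (!is.null(file)) {
    utils::write.table(cells, file, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  cells
}
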