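# File formats (panel TSV, dosage TSV, phenotype CSV, VCF 4.2) and the
# end-to-end pipeline driver.

PHENOTYPE_COLUMNS <- c("sample_id", "outcome", "age", "centre", "density_cat",
                       "first_delivery_cat", "menopause_cat", "menarche_cat",
                       "family_cat")

#' Write a SNP panel as TSV
#' @param panel A `snp_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  df <- panel[, c("rsid", "effect_allele", "other_allele", "or_value",
                  "eaf", "status")]
  names(df)[4] <- "or"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a SNP panel from TSV
#' @param path TSV with columns rsid, effect_allele, other_allele, or, eaf,
#'   status.
#' @return A `snp_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "effect_allele", "other_allele", "or", "eaf")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing panel column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  names(df)[names(df) == "or"] <- "or_value"
  snp_panel(df)
}

#' Write a dosage matrix as TSV
#'
#' Rows are samples, columns are rsIDs, values 0/1/2 with missing calls as
#' empty cells.
#' @param gt Samples x SNPs genotype matrix.
#' @param path Output path.
#' @export
write_dosage <- function(gt, path) {
  df <- data.frame(sample_id = rownames(gt), gt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Read a dosage matrix from TSV
#' @param path TSV written by [write_dosage()].
#' @return Samples x SNPs numeric matrix with `NA` for empty cells.
#' @export
read_dosage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  if (names(df)[1] != "sample_id") {
    stop(path, ": first dosage column must be sample_id", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  bad <- m[!is.na(m)]
  if (any(!bad %in% c(0, 1, 2))) {
    stop(path, ": dosage values must be 0, 1, 2 or empty", call. = FALSE)
  }
  rownames(m) <- df$sample_id
  m
}

#' Write a phenotype table as CSV
#' @param phenotypes Data frame with the standard phenotype columns.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes[, PHENOTYPE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
}

#' Read a phenotype table from CSV
#' @param path CSV with header sample_id, outcome, age, centre, density_cat,
#'   first_delivery_cat, menopause_cat, menarche_cat, family_cat.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PHENOTYPE_COLUMNS, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing phenotype column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write genotypes as a VCF 4.2 file
#'
#' One record per panel SNP, REF = other allele, ALT = effect allele, GT-only
#' FORMAT; missing calls are "./.". Positions are synthetic (record order).
#'
#' @param gt Samples x SNPs genotype matrix of effect-allele counts.
#' @param panel A `snp_panel` covering the matrix columns.
#' @param path Output path.
#' @export
write_vcf <- function(gt, panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  panel <- panel[match(colnames(gt), panel$rsid), ]
  if (anyNA(panel$rsid)) {
    stop("panel does not cover all genotype columns", call. = FALSE)
  }
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gt)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(gt)), function(j) {
    calls <- gt_str[as.character(gt[, j])]
    calls[is.na(calls)] <- "./."
    paste(c("1", j * 1000L, panel$rsid[j], panel$other_allele[j],
            panel$effect_allele[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read effect-allele dosages from a VCF
#'
#' Parses GT fields and orients each record to the panel's effect allele:
#' ALT = effect allele counts the ALT alleles, REF = effect allele counts
#' `2 - ALT`, and records matching only after an A<->T / C<->G complement
#' flip are flipped and logged. Palindromic A/T and C/G SNPs are
#' strand-ambiguous (their complement is the same allele pair, so a flip can
#' never be detected): they are taken at face value when the alleles match
#' directly, but always flagged in the `ambiguous` attribute.
#'
#' @param path VCF 4.2 file.
#' @param panel A `snp_panel`.
#' @return Samples x SNPs matrix of effect-allele counts, with attributes
#'   `flipped` (rsids resolved by complement flip) and `ambiguous`
#'   (strand-ambiguous rsids).
#' @export
read_vcf_dosage <- function(path, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  # ALT allele count from GT strings such as 0/1, 1|1, ./.
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  counts <- apply(gt, 2, alt_count)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, colnames(gt)))
  flipped <- character(0)
  ambiguous <- character(0)
  out <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(panel),
                dimnames = list(colnames(gt), panel$rsid))
  for (k in seq_len(nrow(panel))) {
    i <- match(panel$rsid[k], ids)
    if (is.na(i)) next
    ea <- panel$effect_allele[k]
    oa <- panel$other_allele[k]
    palindromic <- COMPLEMENT[[ea]] == oa
    if (palindromic) ambiguous <- c(ambiguous, panel$rsid[k])
    if (alt[i] == ea && ref[i] == oa) {
      out[, k] <- counts[i, ]
    } else if (ref[i] == ea && alt[i] == oa) {
      out[, k] <- 2 - counts[i, ]
    } else if (!palindromic &&
               alt[i] == COMPLEMENT[[ea]] && ref[i] == COMPLEMENT[[oa]]) {
      out[, k] <- counts[i, ]
      flipped <- c(flipped, panel$rsid[k])
    } else if (!palindromic &&
               ref[i] == COMPLEMENT[[ea]] && alt[i] == COMPLEMENT[[oa]]) {
      out[, k] <- 2 - counts[i, ]
      flipped <- c(flipped, panel$rsid[k])
    } else {
      stop(sprintf("%s: alleles of %s (%s/%s) do not match the panel (%s/%s)",
                   path, panel$rsid[k], ref[i], alt[i], ea, oa), call. = FALSE)
    }
  }
  attr(out, "flipped") <- flipped
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Write a complete simulated fixture to disk
#'
#' Writes the panel TSV, the dosage TSV, the VCF and the phenotype CSV for a
#' cohort so that [read_inputs()] round-trips them at the value level.
#'
#' @param cohort A `cohort`.
#' @param panel A `snp_panel`.
#' @param directory Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture <- function(cohort, panel, directory) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort$phenotypes) > 0)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    panel = file.path(directory, "panel.tsv"),
    dosage = file.path(directory, "dosages.tsv"),
    vcf = file.path(directory, "genotypes.vcf"),
    phenotypes = file.path(directory, "phenotypes.csv")
  )
  write_panel(panel, paths$panel)
  write_dosage(cohort$genotypes, paths$dosage)
  write_vcf(cohort$genotypes, panel, paths$vcf)
  write_phenotypes(cohort$phenotypes, paths$phenotypes)
  invisible(paths)
}

#' Read and reconcile pipeline inputs
#'
#' Reads the panel, the genotypes (VCF when the path ends in `.vcf`, dosage
#' TSV otherwise) and the phenotype CSV, and intersects sample ids across the
#' genotype and phenotype tables.
#'
#' @param panel_path,genotype_path,phenotype_path Input files.
#' @return List with `panel`, `cohort` (a `cohort` with aligned phenotypes
#'   and genotypes) and `n_dropped` (samples present in only one table).
#' @export
read_inputs <- function(panel_path, genotype_path, phenotype_path) {
  panel <- read_panel(panel_path)
  gt <- if (grepl("\\.vcf$", genotype_path)) {
    read_vcf_dosage(genotype_path, panel)
  } else {
    read_dosage(genotype_path)
  }
  phen <- read_phenotypes(phenotype_path)
  common <- intersect(phen$sample_id, rownames(gt))
  if (length(common) == 0) {
    stop("no sample ids shared between genotype and phenotype tables",
         call. = FALSE)
  }
  n_dropped <- (nrow(phen) - length(common)) + (nrow(gt) - length(common))
  phen <- phen[match(common, phen$sample_id), , drop = FALSE]
  rownames(phen) <- NULL
  cohort <- structure(list(phenotypes = phen,
                           genotypes = gt[common, , drop = FALSE]),
                      class = "cohort")
  list(panel = panel, cohort = cohort, n_dropped = n_dropped)
}
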