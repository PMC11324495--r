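#' Read a genotype dosage matrix
#'
#' Reads risk-allele dosages (0/1/2, `NA` for missing) for the SNPs of a
#' panel. Two formats are supported:
#'
#' * `"tsv"` — a delimited table, first column `id`, one column per rsid,
#'   entries already counted in risk alleles. Columns whose rsid is not on
#'   the panel are dropped with a warning.
#' * `"vcf"` — a VCF with hard-call `GT` fields (requires the vcfR package).
#'   Dosages are oriented toward the panel's risk allele: if the risk allele
#'   is ALT the dosage is the ALT count, if it is REF the dosage is
#'   `2 - ALT count`. A record whose REF/ALT pair does not contain the risk
#'   allele is a strand/allele mismatch and raises an error naming the
#'   offending rsids (silent flips would corrupt the PRS sign, so no
#'   auto-correction is attempted).
#'
#' @param path File path.
#' @param panel SNP panel tibble with `rsid` and `risk_allele` columns.
#' @param format `"tsv"` or `"vcf"`.
#' @return Integer matrix, participants x panel SNPs, with dimnames.
#' @export
read_genotypes <- function(path, panel, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Genotype file not found: %s", path))
  switch(format,
    tsv = read_genotypes_tsv(path, panel),
    vcf = read_genotypes_vcf(path, panel)
  )
}

read_genotypes_tsv <- function(path, panel) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""))
  if (!"id" %in% names(df)) abort("Genotype TSV must have an `id` column.")
  rsids <- setdiff(names(df), "id")
  unknown <- setdiff(rsids, panel$rsid)
  if (length(unknown)) {
    warn(sprintf(
      "Dropping %d genotype column(s) not on the panel: %s",
      length(unknown), paste(head(unknown, 5), collapse = ", ")
    ))
    rsids <- setdiff(rsids, unknown)
  }
  absent <- setdiff(panel$rsid, rsids)
  if (length(absent)) {
    abort(sprintf(
      "Panel SNP(s) missing from genotype file: %s",
      paste(head(absent, 5), collapse = ", ")
    ))
  }
  G <- as.matrix(df[panel$rsid])
  storage.mode(G) <- "integer"
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) G[bad] <- NA_integer_
  rownames(G) <- as.character(df$id)
  G
}

read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF genotypes requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm) # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(fix$ID, names(gt)))

  keep <- fix$ID %in% panel$rsid
  unknown <- unique(fix$ID[!keep])
  if (length(unknown)) {
    warn(sprintf(
      "Dropping %d VCF record(s) not on the panel: %s",
      length(unknown), paste(head(unknown, 5), collapse = ", ")
    ))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  idx <- match(panel$rsid, fix$ID)
  if (anyNA(idx)) {
    abort(sprintf(
      "Panel SNP(s) missing from VCF: %s",
      paste(head(panel$rsid[is.na(idx)], 5), collapse = ", ")
    ))
  }
  fix <- fix[idx, , drop = FALSE]
  gt <- gt[idx, , drop = FALSE]

  mismatch <- !(panel$risk_allele == fix$REF | panel$risk_allele == fix$ALT)
  if (any(mismatch)) {
    abort(sprintf(
      "Risk allele not among REF/ALT (possible strand flip) for: %s",
      paste(panel$rsid[mismatch], collapse = ", ")
    ))
  }

  # ALT allele count from hard-call GT; anything unparseable becomes missing
  alt_count <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- grepl("^[01]([/|][01])?$", x)
    out[ok] <- vapply(
      strsplit(x[ok], "[/|]"),
      function(a) sum(a == "1"), integer(1)
    )
    out
  }
  A <- apply(gt, 2, alt_count)
  if (is.null(dim(A))) A <- matrix(A, nrow = nrow(gt), dimnames = dimnames(gt))
  risk_is_alt <- panel$risk_allele == fix$ALT
  D <- ifelse(matrix(risk_is_alt, nrow(A), ncol(A)), A, 2L - A)
  G <- t(D)
  storage.mode(G) <- "integer"
  colnames(G) <- panel$rsid
  G
}

#' Impute missing genotypes with the control-group major allele
#'
#' Each missing dosage is replaced by the homozygous dosage of the allele
#' that is the major allele among controls (participants without cancer) for
#' that SNP: 2 if the risk-allele frequency among controls exceeds 0.5,
#' otherwise 0. Non-missing entries are never changed.
#'
#' @param G Dosage matrix (participants x SNPs), risk-allele counts with
#'   `NA` for missing.
#' @param is_control Logical/0-1 vector, one per participant; `TRUE` for
#'   controls.
#' @return The matrix with every missing entry filled.
#' @examples
#' G <- rbind(c(0L, NA), c(0L, 2L), c(1L, 2L))
#' colnames(G) <- c("rs1", "rs2")
#' impute_missing(G, is_control = c(TRUE, TRUE, TRUE))
#' @export
impute_missing <- function(G, is_control) {
  is_control <- as.logical(is_control)
  stopifnot(length(is_control) == nrow(G), !anyNA(is_control))
  if (!any(is_control)) abort("At least one control participant is required.")
  if (!anyNA(G)) return(G)

  Gc <- G[is_control, , drop = FALSE]
  n_obs <- colSums(!is.na(Gc))
  if (any(n_obs == 0)) {
    abort(sprintf(
      "All control genotypes missing for SNP(s): %s",
      paste(colnames(G)[n_obs == 0], collapse = ", ")
    ))
  }
  risk_freq <- colSums(Gc, na.rm = TRUE) / (2 * n_obs)
  fill <- ifelse(risk_freq > 0.5, 2L, 0L)

  miss <- which(is.na(G), arr.ind = TRUE)
  G[miss] <- fill[miss[, "col"]]
  G
}
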