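#' Variant table: sites x samples with alleles, AD and DP
#'
#' In-memory representation of a (possibly multiallelic) variant call set
#' with per-sample allelic depths. Multiallelic records are kept un-split.
#'
#' @param scaffold,pos Character / integer vectors, one entry per site.
#' @param alleles List of character vectors (reference allele first).
#' @param ad List of integer matrices, one per site, `samples x alleles`
#'   (rownames = sample ids, columns in allele order). `NA` marks missing.
#' @param dp Integer matrix `sites x samples` of total depths.
#' @param samples Character vector of sample ids (column order is fixed).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(scaffold, pos, alleles, ad, dp, samples) {
  n <- length(pos)
  stopifnot(length(scaffold) == n, length(alleles) == n, length(ad) == n,
            nrow(dp) == n || n == 0L)
  for (i in seq_len(n)) {
    if (length(alleles[[i]]) < 2L)
      stop("site ", i, ": a variant site needs >= 2 alleles")
    if (!is.matrix(ad[[i]]) || ncol(ad[[i]]) != length(alleles[[i]]) ||
        nrow(ad[[i]]) != length(samples))
      stop("site ", i, ": AD matrix must be samples x alleles")
    bad <- which(rowSums(ad[[i]]) > dp[i, ] + 1e-9)
    if (length(bad))
      stop("site ", i, ": sum(AD) exceeds DP for sample(s) ",
           paste(samples[bad], collapse = ", "))
  }
  dpm <- matrix(as.integer(dp), nrow = n, ncol = length(samples),
                dimnames = list(NULL, samples))
  structure(list(scaffold = as.character(scaffold), pos = as.integer(pos),
                 alleles = alleles, ad = ad, dp = dpm, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d site(s) x %d sample(s)\n",
              n_sites(x), length(x$samples)))
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt A `variant_table`.
#' @export
n_sites <- function(vt) length(vt$pos)

#' Subset a variant table to a region
#'
#' @param vt A `variant_table`.
#' @param region A `genomic_interval` (or `NULL` for no-op).
#' @return A `variant_table` with only the sites inside `region`; the sample
#'   list is preserved even when no site remains.
#' @export
subset_region <- function(vt, region) {
  if (is.null(region)) return(vt)
  keep <- in_interval(region, vt$scaffold, vt$pos)
  variant_table(vt$scaffold[keep], vt$pos[keep], vt$alleles[keep],
                vt$ad[keep], vt$dp[keep, , drop = FALSE], vt$samples)
}

#' Read a VCF into a variant table
#'
#' Uses `vcfR` to parse a VCF 4.x file carrying per-sample `AD` and `DP`
#' FORMAT fields. Multiallelic records are preserved un-split; samples keep
#' their header order. A sample missing AD or DP at a site is flagged as
#' missing (`NA`), never an error.
#'
#' @param path Path to a plain-text or bgzipped VCF.
#' @param region Optional `genomic_interval` to restrict to.
#' @return A `variant_table`.
#' @export
read_variant_table <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  nrec <- nrow(fix)
  if (nrec == 0L) {
    return(variant_table(character(0), integer(0), list(), list(),
                         matrix(integer(0), 0, length(samples),
                                dimnames = list(NULL, samples)), samples))
  }
  scaffold <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  if (anyNA(pos)) stop("malformed VCF record at line(s): ",
                       paste(which(is.na(pos)), collapse = ", "))
  alleles <- lapply(seq_len(nrec), function(i) {
    a <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    a[!is.na(a) & a != "."]
  })
  adm <- vcfR::extract.gt(v, element = "AD")
  dpm <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (is.null(adm)) adm <- matrix(NA_character_, nrec, length(samples))
  if (is.null(dpm)) dpm <- matrix(NA_real_, nrec, length(samples))
  ad <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    k <- length(alleles[[i]])
    m <- matrix(NA_integer_, length(samples), k,
                dimnames = list(samples, NULL))
    for (j in seq_along(samples)) {
      s <- adm[i, j]
      if (!is.na(s) && nzchar(s) && s != ".") {
        vals <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
        m[j, seq_len(min(k, length(vals)))] <- vals[seq_len(min(k, length(vals)))]
      }
    }
    ad[[i]] <- m
  }
  dp <- matrix(as.integer(dpm), nrec, length(samples),
               dimnames = list(NULL, samples))
  # DP missing but AD present: fall back to sum(AD)
  for (i in seq_len(nrec)) {
    miss <- is.na(dp[i, ]) & !is.na(ad[[i]][, 1])
    if (any(miss)) dp[i, miss] <- as.integer(rowSums(ad[[i]][miss, , drop = FALSE]))
  }
  vt <- variant_table(scaffold, pos, alleles, ad, dp, samples)
  subset_region(vt, region)
}

#' Write a variant table as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT:AD:DP per sample (GT written as `.`;
#' the pipeline works from allelic depths). Round-trips through
#' [read_variant_table()] field-by-field.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")), con)
  for (i in seq_len(n_sites(vt))) {
    al <- vt$alleles[[i]]
    gt <- vapply(seq_along(vt$samples), function(j) {
      adv <- vt$ad[[i]][j, ]
      if (anyNA(adv)) "./.:.:." else
        sprintf("./.:%s:%d", paste(adv, collapse = ","), vt$dp[i, j])
    }, character(1))
    writeLines(paste(c(vt$scaffold[i], vt$pos[i], ".", al[1],
                       paste(al[-1], collapse = ","), ".", "PASS", ".",
                       "GT:AD:DP", gt), collapse = "\t"), con)
  }
  invisible(path)
}
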