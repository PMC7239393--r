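#' Gene model
#'
#' @param gene Gene name.
#' @param scaffold Scaffold id.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with 1-based inclusive `start`, `end`; exons are
#'   sorted and must not overlap.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, scaffold, strand, exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("gene ", gene, ": exons overlap")
  structure(list(gene = gene, scaffold = scaffold, strand = strand,
                 exons = exons,
                 span = genomic_interval(scaffold, min(exons$start),
                                         max(exons$end))),
            class = "gene_model")
}

#' Read gene models from BED12 or GFF3
#'
#' Parsing is delegated to `rtracklayer`; BED's 0-based half-open
#' coordinates are converted to the package's 1-based inclusive convention
#' on read. For GFF3, `exon` features are grouped by their `Parent` (or
#' `gene`/`ID`) attribute.
#'
#' @param path Path to a `.bed` (BED12) or `.gff`/`.gff3` file.
#' @return List of `gene_model` (empty list for an empty file).
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (file.size(path) == 0L ||
      (fmt == "gff3" && !any(!startsWith(readLines(path, warn = FALSE), "#"))))
    return(list())
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0L) return(list())
  if (fmt == "bed") {
    out <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- if (!is.null(g$blocks) && length(g$blocks[[1]]) > 0)
        g$blocks[[1]] else IRanges::IRanges(1, GenomicRanges::width(g))
      abs_start <- GenomicRanges::start(g) + IRanges::start(blocks) - 1L
      abs_end <- GenomicRanges::start(g) + IRanges::end(blocks) - 1L
      gene_model(as.character(g$name),
                 as.character(GenomicRanges::seqnames(g)),
                 as.character(GenomicRanges::strand(g)),
                 data.frame(start = abs_start, end = abs_end))
    })
  } else {
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0L) ex <- gr
    key <- if (!is.null(ex$Parent) && any(lengths(ex$Parent) > 0))
      vapply(as.list(ex$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    else if (!is.null(ex$gene)) as.character(ex$gene)
    else as.character(ex$ID)
    out <- lapply(split(seq_along(ex), key), function(idx) {
      e <- ex[idx]
      gene_model(unique(key[idx]),
                 as.character(GenomicRanges::seqnames(e))[1],
                 as.character(GenomicRanges::strand(e))[1],
                 data.frame(start = GenomicRanges::start(e),
                            end = GenomicRanges::end(e)))
    })
    names(out) <- NULL
  }
  out
}

#' Sample sheet with sex-aware Z baselines
#'
#' Reads a CSV of `id,phenotype,sex` and attaches the Z-chromosome baseline
#' copy number implied by avian sex chromosomes: females (ZW) are hemizygous
#' and carry 1 Z, males (ZZ) carry 2.
#'
#' @param path Path to the CSV.
#' @param phenotypes Accepted phenotype labels.
#' @return Data frame of class `sample_sheet` with columns
#'   `id,phenotype,sex,z_baseline`.
#' @export
read_sample_sheet <- function(path,
                              phenotypes = c("Almond", "non-Almond",
                                             "Qualmond", "Faded", "Sandy",
                                             "Frosty", "Chalky", "White Out",
                                             "Hickory")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "phenotype", "sex")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sample_sheet(df$id, df$phenotype, df$sex, phenotypes = phenotypes)
}

#' @rdname read_sample_sheet
#' @param id,phenotype,sex Vectors building the sheet in code.
#' @export
sample_sheet <- function(id, phenotype, sex,
                         phenotypes = c("Almond", "non-Almond", "Qualmond",
                                        "Faded", "Sandy", "Frosty", "Chalky",
                                        "White Out", "Hickory")) {
  sex_norm <- c(f = "female", female = "female", F = "female",
                m = "male", male = "male", M = "male")[as.character(sex)]
  bad_sex <- which(is.na(sex_norm))
  if (length(bad_sex))
    stop("unknown sex label at row(s): ",
         paste(sprintf("%d ('%s')", bad_sex, sex[bad_sex]), collapse = ", "))
  bad_ph <- which(!phenotype %in% phenotypes)
  if (length(bad_ph))
    stop("unknown phenotype label at row(s): ",
         paste(sprintf("%d ('%s')", bad_ph, phenotype[bad_ph]), collapse = ", "))
  structure(data.frame(id = as.character(id), phenotype = phenotype,
                       sex = unname(sex_norm),
                       z_baseline = ifelse(sex_norm == "female", 1L, 2L)),
            class = c("sample_sheet", "data.frame"))
}

#' Read gene models and sample sheet together
#'
#' @param gene_path BED12 or GFF3 gene models.
#' @param sample_path CSV sample sheet.
#' @param ... Passed to [read_sample_sheet()].
#' @return List with elements `genes` and `samples`.
#' @export
read_annotations_and_samples <- function(gene_path, sample_path, ...) {
  list(genes = read_gene_models(gene_path),
       samples = read_sample_sheet(sample_path, ...))
}

#' Write a sample sheet CSV
#' @param samples A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples[, c("id", "phenotype", "sex")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
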