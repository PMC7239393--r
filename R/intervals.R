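#' Genomic interval (1-based, inclusive)
#'
#' Light container for a scaffold interval. All coordinates in the package
#' are 1-based and inclusive at both ends, matching how scaffold positions
#' are conventionally printed; BED input is converted on read.
#'
#' @param scaffold Scaffold/chromosome identifier.
#' @param start,end 1-based inclusive endpoints; `end >= start >= 1`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("ScoHet5_227", 5181467, 5259256)
#' interval_length(gi)   # 77790
#' kb_label(gi)          # "77 kb"
#' @export
genomic_interval <- function(scaffold, start, end) {
  stopifnot(is.character(scaffold), length(scaffold) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing positions")
  if (start < 1) stop("start must be >= 1 (coordinates are 1-based)")
  if (end < start) stop("end must be >= start")
  structure(list(scaffold = scaffold, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s> (%s)\n", x$scaffold,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              kb_label(x)))
  invisible(x)
}

#' Interval length in base pairs
#'
#' @param x A `genomic_interval`.
#' @return `end - start + 1`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' Kilobase label with floor rounding
#'
#' Reports interval size as `floor(length/1000)` kb, the convention used when
#' a segment of 77,790 bp is called a "77-kb segment".
#'
#' @param x A `genomic_interval` or a length in bp.
#' @return Character label, e.g. `"77 kb"`.
#' @export
kb_label <- function(x) {
  len <- if (inherits(x, "genomic_interval")) interval_length(x) else as.numeric(x)
  sprintf("%d kb", floor(len / 1000))
}

#' @rdname kb_label
#' @export
kb_floor <- function(x) {
  len <- if (inherits(x, "genomic_interval")) interval_length(x) else as.numeric(x)
  floor(len / 1000)
}

# is `pos` (vector) inside interval? scaffold-aware when scaffolds given
in_interval <- function(x, scaffold, pos) {
  scaffold == x$scaffold & pos >= x$start & pos <= x$end
}

# does interval `a` contain interval `b` entirely?
contains_interval <- function(a, b) {
  a$scaffold == b$scaffold && a$start <= b$start && a$end >= b$end
}

# strict nesting: b inside a with both boundaries strictly interior
strictly_nested <- function(a, b) {
  a$scaffold == b$scaffold && a$start < b$start && a$end > b$end
}

#' Parse a region string
#'
#' Accepts `"SCAFFOLD:START-END"` (commas in numbers allowed).
#'
#' @param region Region string.
#' @return A `genomic_interval`.
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", region)
  genomic_interval(m[2],
                   as.numeric(gsub(",", "", m[3])),
                   as.numeric(gsub(",", "", m[4])))
}
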