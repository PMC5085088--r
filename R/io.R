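# Readers and writers for the plain tabular metadata formats.
#
# All formats are TSV (any whitespace accepted on read), '#' starts a
# comment line, and a single header row is optional and auto-detected.

.read_tab <- function(path, ncol_min = 2L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) .stop_domain("empty input file: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < ncol_min))
    stop(sprintf("parse error in %s, line %d: expected >= %d fields, got %d",
                 path, which(nf < ncol_min)[1L], ncol_min, min(nf)),
         call. = FALSE)
  fields
}

.is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

# drop a header row when the value columns are non-numeric
.drop_header <- function(fields, num_cols) {
  first <- fields[[1L]]
  if (!all(.is_num(first[num_cols]))) fields[-1L] else fields
}

.col_num <- function(fields, j, path) {
  raw <- vapply(fields, `[`, character(1), j)
  out <- suppressWarnings(as.numeric(raw))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("parse error in %s: non-numeric value '%s' in column %d",
                 path, raw[bad], j), call. = FALSE)
  }
  out
}

.col_chr <- function(fields, j) vapply(fields, `[`, character(1), j)

#' Read a tabular metadata file into a typed input object
#'
#' Dispatches on `schema`:
#' \describe{
#'   \item{freq}{two columns `allele value`; values summing to 1 are
#'     frequencies, integer values are counts (normalized).  Returns the
#'     frequency vector (named by allele) with the raw values in
#'     attribute `"raw"`.}
#'   \item{sfs}{two columns `derived_count num_sites`; needs `n`.
#'     Returns an [sfs()]; missing classes default to 0.}
#'   \item{mismatch}{two columns `differences frequency_or_count` over
#'     classes 0..d; returns a [mismatch_dist()].}
#'   \item{hapmatrix}{one haplotype per line of 0/1 characters, with an
#'     optional leading whitespace-separated row of site positions;
#'     returns a [hap_matrix()].}
#'   \item{popfreq}{long format `pop locus allele value [n]`; returns a
#'     [pop_freqs()] (single locus) or named list of them.}
#'   \item{genotype}{`pop locus allele1 allele2 count` (the `locus`
#'     column may be omitted for single-locus tables); returns a
#'     [genotype_tab()].}
#'   \item{allelesize}{`pop locus size count` (`locus` optional);
#'     returns an [allele_sizes()].}
#' }
#'
#' @param path input file path.
#' @param schema one of `"freq", "sfs", "mismatch", "hapmatrix",
#'   "popfreq", "genotype", "allelesize"`.
#' @param n sample size (sequences), required for `schema = "sfs"`.
#' @param folded is the SFS folded (minor-allele classes)?
#' @return the typed object described above.
#' @export
parse_table <- function(path, schema = c("freq", "sfs", "mismatch",
                                         "hapmatrix", "popfreq",
                                         "genotype", "allelesize"),
                        n = NULL, folded = FALSE) {
  schema <- match.arg(schema)
  switch(schema,
         freq = .parse_freq(path),
         sfs = .parse_sfs(path, n = n, folded = folded),
         mismatch = .parse_mismatch(path),
         hapmatrix = .parse_hapmatrix(path),
         popfreq = .parse_popfreq(path),
         genotype = .parse_genotype(path),
         allelesize = .parse_allelesize(path))
}

.values_to_freqs <- function(vals, what = "frequencies") {
  s <- sum(vals)
  if (abs(s - 1) <= 1e-6) return(check_freqs(vals))
  if (all(vals >= 0) && all(vals == round(vals)) && s > 0)
    return(vals / s)  # counts
  .stop_domain(sprintf(
    "%s sum to %.6g: neither a frequency vector (sum 1 within 1e-6) nor integer counts",
    what, s))
}

.parse_freq <- function(path) {
  f <- .drop_header(.read_tab(path), num_cols = 2L)
  vals <- .col_num(f, 2L, path)
  if (any(vals < 0)) .stop_domain("negative value in frequency file ", path)
  out <- .values_to_freqs(vals)
  names(out) <- .col_chr(f, 1L)
  attr(out, "raw") <- vals
  out
}

.parse_sfs <- function(path, n, folded = FALSE) {
  if (is.null(n)) stop("schema 'sfs' requires the sample size 'n'", call. = FALSE)
  f <- .drop_header(.read_tab(path), num_cols = 1:2)
  cls <- .col_num(f, 1L, path)
  cnt <- .col_num(f, 2L, path)
  len <- if (folded) n %/% 2 else n - 1
  if (any(cls < 1 | cls > len | cls != round(cls)))
    .stop_domain(sprintf("SFS class out of range 1..%d in %s", len, path))
  if (anyDuplicated(cls)) .stop_domain("duplicated SFS class in ", path)
  counts <- numeric(len)
  counts[cls] <- cnt
  sfs(counts, n = n, folded = folded)
}

.parse_mismatch <- function(path) {
  f <- .drop_header(.read_tab(path), num_cols = 1:2)
  cls <- .col_num(f, 1L, path)
  val <- .col_num(f, 2L, path)
  if (any(cls < 0 | cls != round(cls)))
    .stop_domain("mismatch classes must be integers >= 0 in ", path)
  if (anyDuplicated(cls)) .stop_domain("duplicated mismatch class in ", path)
  x <- numeric(max(cls) + 1L)
  x[cls + 1L] <- val
  mismatch_dist(x)
}

.parse_hapmatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) .stop_domain("empty haplotype matrix file: ", path)
  positions <- NULL
  first <- trimws(lines[1L])
  if (grepl("[\t ]", first)) {  # header row of site positions
    positions <- as.numeric(strsplit(first, "[\t ]+")[[1L]])
    if (anyNA(positions))
      .stop_domain("malformed position header in ", path)
    lines <- lines[-1L]
  }
  rows <- strsplit(trimws(lines), "")
  if (length(unique(lengths(rows))) != 1L)
    .stop_domain("ragged haplotype rows in ", path)
  m <- do.call(rbind, lapply(rows, function(r) {
    if (!all(r %in% c("0", "1")))
      .stop_domain("haplotype rows must contain only 0/1 in ", path)
    as.integer(r)
  }))
  hap_matrix(m, positions = positions)
}

.parse_long <- function(path, cols_with_locus, cols_without) {
  f <- .read_tab(path, ncol_min = length(cols_without))
  has_locus <- all(lengths(f) >= length(cols_with_locus))
  cols <- if (has_locus) cols_with_locus else cols_without
  num_cols <- which(cols %in% c("value", "count", "size", "n"))
  f <- .drop_header(f, num_cols = num_cols[num_cols <= min(lengths(f))])
  out <- list()
  for (j in seq_along(cols)) {
    out[[cols[j]]] <- if (cols[j] %in% c("value", "count", "size", "n"))
      .col_num(f, j, path) else .col_chr(f, j)
  }
  if (!has_locus) out$locus <- rep("locus1", length(out[[1L]]))
  as.data.frame(out, stringsAsFactors = FALSE)
}

.parse_popfreq <- function(path) {
  f <- .read_tab(path, ncol_min = 3L)
  nf <- min(lengths(f))
  # columns: pop locus allele value [n] (4 or 5 cols) or pop allele value
  df <- if (nf >= 4L)
    .parse_long(path, c("pop", "locus", "allele", "value", "n")[seq_len(nf)],
                c("pop", "locus", "allele", "value"))
  else .parse_long(path, c("pop", "allele", "value"), c("pop", "allele", "value"))
  if (is.null(df$locus)) df$locus <- "locus1"
  build <- function(d) {
    pops <- sort(unique(d$pop))
    alleles <- sort(unique(d$allele))
    m <- matrix(0, length(pops), length(alleles),
                dimnames = list(pops, alleles))
    for (i in seq_len(nrow(d))) m[d$pop[i], d$allele[i]] <- d$value[i]
    freqs <- if (ncol(m) == 1L) {
      vapply(seq_len(nrow(m)), function(i)
        .values_to_freqs(m[i, ], what = "per-population values"), numeric(1))
      matrix(1, nrow(m), 1L, dimnames = dimnames(m))
    } else {
      t(apply(m, 1L, .values_to_freqs, what = "per-population values"))
    }
    nn <- NULL
    if (!is.null(d$n)) {
      nn <- vapply(pops, function(p) d$n[d$pop == p][1L], numeric(1))
    } else if (all(m == round(m)) && any(rowSums(m) > 1 + 1e-6)) {
      nn <- rowSums(m)  # counts double as sample sizes in allele copies
    }
    pop_freqs(freqs, n = nn)
  }
  by_locus <- lapply(split(df, df$locus), build)
  if (length(by_locus) == 1L) by_locus[[1L]] else by_locus
}

.parse_genotype <- function(path) {
  f <- .read_tab(path, ncol_min = 4L)
  nf <- min(lengths(f))
  df <- if (nf >= 5L)
    .parse_long(path, c("pop", "locus", "allele1", "allele2", "count"),
                c("pop", "allele1", "allele2", "count"))
  else .parse_long(path, c("pop", "allele1", "allele2", "count"),
                   c("pop", "allele1", "allele2", "count"))
  genotype_tab(df)
}

.parse_allelesize <- function(path) {
  f <- .read_tab(path, ncol_min = 3L)
  nf <- min(lengths(f))
  df <- if (nf >= 4L)
    .parse_long(path, c("pop", "locus", "size", "count"),
                c("pop", "size", "count"))
  else .parse_long(path, c("pop", "size", "count"),
                   c("pop", "size", "count"))
  pops <- sort(unique(df$pop))
  allele_sizes(lapply(pops, function(p) {
    d <- df[df$pop == p, ]
    rep(d$size, d$count)
  }))
}

# ---- writers (round-trip counterparts used by `simulate --out`) ---------

#' Write metadata objects to their tabular formats
#'
#' Counterparts of [parse_table()]: each writes a file that parses back
#' to an equivalent object.
#'
#' @param x object to write ([sfs()], [mismatch_dist()], [hap_matrix()]
#'   or a named frequency vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  i <- seq_along(x$counts)
  writeLines(c("# derived_count\tnum_sites",
               sprintf("%d\t%d", i, as.integer(x$counts))), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
write_mismatch <- function(x, path) {
  stopifnot(inherits(x, "mismatch_dist"))
  cls <- seq_along(x$probs) - 1L
  writeLines(c("# differences\tfrequency",
               sprintf("%d\t%.10g", cls, x$probs)), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
write_hap_matrix <- function(x, path) {
  stopifnot(inherits(x, "hap_matrix"))
  rows <- apply(x$matrix, 1L, paste, collapse = "")
  if (ncol(x$matrix) > 0L)
    rows <- c(paste(x$positions, collapse = "\t"), rows)
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
write_freqs <- function(x, path) {
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("a", seq_along(x))
  writeLines(c("# allele\tfrequency",
               sprintf("%s\t%.10g", nm, as.numeric(x))), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
write_pop_freqs <- function(x, path) {
  stopifnot(inherits(x, "pop_freqs"))
  pops <- rownames(x$freqs)
  if (is.null(pops)) pops <- paste0("pop", seq_len(x$r))
  alleles <- colnames(x$freqs)
  if (is.null(alleles)) alleles <- paste0("a", seq_len(ncol(x$freqs)))
  lines <- "# pop\tlocus\tallele\tfreq"
  for (i in seq_len(x$r))
    for (j in seq_len(ncol(x$freqs)))
      lines <- c(lines, sprintf("%s\tlocus1\t%s\t%.10g",
                                pops[i], alleles[j], x$freqs[i, j]))
  writeLines(lines, path)
  invisible(path)
}
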