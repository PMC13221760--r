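#' Construct a MarkerMatrix
#'
#' @param dosages numeric matrix of reference-allele counts (0/1/2, `NA` for
#'   missing), or values in `[0, 2]` when `fractional = TRUE`.
#' @param individualIds,locusIds optional identifiers; taken from dimnames
#'   when omitted.
#' @param fractional allow non-integer expected dosages.
#' @return a [MarkerMatrix-class].
#' @examples
#' m <- MarkerMatrix(matrix(c(0, 1, 2, 2, 1, 0), 2, 3,
#'   dimnames = list(c("i1", "i2"), c("s1", "s2", "s3"))))
#' dim(m)
#' @export
MarkerMatrix <- function(dosages, individualIds = rownames(dosages),
                         locusIds = colnames(dosages), fractional = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  rownames(dosages) <- as.character(individualIds)
  colnames(dosages) <- as.character(locusIds)
  new("MarkerMatrix", dosages = dosages, fractional = fractional)
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a genotype matrix from VCF or a delimited file
#'
#' VCF input uses the GT field only; each record must be biallelic (or is
#' split/rejected according to `multiallelic`). Dosages count the REF
#' allele, so GT `0/0` is 2, `0/1` is 1 and `1/1` is 0. Delimited input has
#' locus ids in the header row and individual ids in the first column; the
#' delimiter is auto-detected among comma and tab.
#'
#' @param path input file.
#' @param format `"vcf"` or `"matrix"`.
#' @param multiallelic policy for VCF records with >1 ALT allele:
#'   `"reject"` (error) or `"drop"` (skip with a warning).
#' @return a [MarkerMatrix-class]; VCF row/column order follows the file
#'   (individuals = samples).
#' @export
readGenotypes <- function(path, format = c("vcf", "matrix"),
                          multiallelic = c("reject", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") .read_vcf(path, multiallelic) else .read_matrix(path)
}

.read_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "reject")
      stop("non-biallelic VCF record(s) at position(s): ",
           paste(head(fix[multi, "POS"], 5), collapse = ", "),
           " (use multiallelic = 'drop' to skip them)")
    warning(sum(multi), " multiallelic record(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(fix), names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
  dose <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "0")  # dosage counts the REF allele
  }
  dm <- vapply(seq_len(ncol(gt)), function(j) vapply(gt[, j], dose, numeric(1)),
               numeric(nrow(gt)))
  dm <- matrix(dm, nrow = nrow(gt))
  out <- t(dm)  # individuals x loci
  rownames(out) <- colnames(gt)
  colnames(out) <- ids
  MarkerMatrix(out)
}

.read_matrix <- function(path) {
  delim <- .detect_delim(path)
  df <- read.csv(path, sep = delim, check.names = FALSE, row.names = 1,
                 colClasses = "character")
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  bad <- which((is.na(num) & !(is.na(m) | m %in% c("", "NA", "."))) |
                 (!is.na(num) & !(num %in% c(0, 1, 2))))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("invalid dosage '%s' at individual '%s', locus '%s' (must be 0, 1 or 2)",
                 m[bad[1]], rownames(m)[i], colnames(m)[j]))
  }
  MarkerMatrix(num)
}

#' Write a MarkerMatrix as a delimited file
#'
#' First row holds locus ids, first column individual ids; missing dosages
#' are written as `NA`. [readGenotypes()] with `format = "matrix"`
#' round-trips the object exactly (for integer dosage matrices).
#'
#' @param x a [MarkerMatrix-class].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeGenotypes <- function(x, path, sep = ",") {
  stopifnot(is(x, "MarkerMatrix"))
  df <- data.frame(id = individualIds(x), dosages(x), check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pedigree table
#'
#' CSV with columns `hybrid,parent1,parent2`; by convention `parent2` is the
#' tester.
#'
#' @param path CSV file.
#' @return data.frame with columns hybrid, parent1, parent2.
#' @export
readPedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid", "parent1", "parent2")
  if (!all(need %in% names(df)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$hybrid)) stop("duplicated hybrid ids in pedigree")
  df[need]
}

#' Read a long-format phenotype table
#'
#' CSV with columns `hybrid,year,location,replicate,trait,value`; one row
#' per plot observation.
#'
#' @param path CSV file.
#' @return data.frame with those columns; keys must be unique and values finite.
#' @export
readPhenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid", "year", "location", "replicate", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotypes must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df[, 1:5])) stop("duplicate (hybrid, year, location, replicate, trait) keys")
  if (any(!is.finite(df$value))) stop("non-finite phenotype values")
  df
}

#' Build hybrid genotypes from parental dosages
#'
#' Each hybrid's dosage at a locus is the expected dosage of the cross,
#' `(parent1 + parent2) / 2`. For fully inbred (homozygous) parents this is
#' the exact hybrid dosage and always an integer; heterozygous parents yield
#' fractional expected dosages, flagged via the `fractional` slot. A missing
#' parental call propagates to a missing hybrid call.
#'
#' @param parents [MarkerMatrix-class] of parental lines.
#' @param pedigree data.frame with columns hybrid, parent1, parent2.
#' @return [MarkerMatrix-class] of hybrids (rows in pedigree order).
#' @examples
#' p <- MarkerMatrix(matrix(c(0, 2, 2, 2, 1, 0), 2, 3,
#'   dimnames = list(c("A", "B"), c("s1", "s2", "s3"))))
#' ped <- data.frame(hybrid = "AxB", parent1 = "A", parent2 = "B")
#' dosages(makeHybridGenotypes(p, ped))
#' @export
makeHybridGenotypes <- function(parents, pedigree) {
  stopifnot(is(parents, "MarkerMatrix"))
  pm <- dosages(parents)
  miss <- setdiff(unique(c(pedigree$parent1, pedigree$parent2)), rownames(pm))
  if (length(miss))
    stop("pedigree parents absent from parental matrix: ",
         paste(miss, collapse = ", "))
  h <- (pm[pedigree$parent1, , drop = FALSE] +
          pm[pedigree$parent2, , drop = FALSE]) / 2
  rownames(h) <- pedigree$hybrid
  frac <- any(h[!is.na(h)] != round(h[!is.na(h)]))
  MarkerMatrix(h, fractional = frac)
}
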