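## Readers and writers: dosage matrices (CSV/TSV), VCF genotypes, phenotype
## tables, and ranked output tables with a provenance header.

#' Read a genotype dosage matrix
#'
#' CSV/TSV layout: header row of marker ids, first column the individual id,
#' remaining cells dosages in \{0, 1, 2\} with `.`, `NA` or an empty cell for
#' missing. VCF input (requires the `vcfR` package) keeps biallelic SNPs
#' only — multi-allelic records are skipped with a warning — and converts
#' the GT field to the ALT-allele dosage (`./.` becomes missing).
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"vcf"`.
#' @param ploidyRole passed to [MarkerPanel()].
#' @param onHeterozygote passed to [MarkerPanel()] (inbred panels only).
#' @return a [MarkerPanel-class].
#' @export
readGenotypes <- function(path, format = c("csv", "tsv", "vcf"),
                          ploidyRole = c("hybrid", "parental_inbred"),
                          onHeterozygote = c("error", "missing")) {
  format <- match.arg(format)
  ploidyRole <- match.arg(ploidyRole)
  if (format == "vcf")
    return(.readVcfGenotypes(path, ploidyRole, onHeterozygote))
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2L) stop("genotype file needs a header and at least one individual")
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- parts[[1L]]
  nc <- length(header)
  markers <- header[-1L]
  body <- parts[-1L]
  bad <- which(lengths(body) != nc)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, nc, length(body[[bad[1L]]])))
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- t(vapply(body, function(x) x[-1L], character(nc - 1L)))
  cells <- trimws(cells)
  cells[cells %in% c(".", "NA", "")] <- NA_character_
  ok <- is.na(cells) | cells %in% c("0", "1", "2")
  if (!all(ok)) {
    firstBad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage '%s' at line %d (individual %s, marker %s): cells must be 0, 1, 2 or missing",
                 cells[firstBad[1L], firstBad[2L]], firstBad[1L] + 1L,
                 ids[firstBad[1L]], markers[firstBad[2L]]))
  }
  d <- matrix(as.numeric(cells), nrow = length(ids),
              dimnames = list(ids, markers))
  MarkerPanel(d, ploidyRole = ploidyRole, onHeterozygote = onHeterozygote)
}

.readVcfGenotypes <- function(path, ploidyRole, onHeterozygote) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  if (any(!biallelic)) {
    warning(sprintf("%d multi-allelic site(s) skipped", sum(!biallelic)))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = "_")
  rownames(gt) <- make.unique(ids)
  allele1 <- substr(gt, 1L, 1L)
  allele2 <- substr(gt, 3L, 3L)
  dose <- matrix(suppressWarnings(as.numeric(allele1) + as.numeric(allele2)),
                 nrow = nrow(gt), dimnames = dimnames(gt))
  MarkerPanel(t(dose), ploidyRole = ploidyRole, onHeterozygote = onHeterozygote)
}

#' Read a phenotype table
#'
#' Two-column CSV of hybrid id and trait value. Hybrid ids may be written as
#' `"A x B"` or `"AxB"`; they are canonicalized to `"<A>x<B>"` with the
#' parents sorted, matching [hybridIds()]. One record per hybrid is
#' enforced: repeated measurements (e.g. multi-year trials) must be averaged
#' upstream before model fitting.
#'
#' @param path input CSV with a header row.
#' @param genotypeIds optional vector of valid hybrid ids; unknown phenotype
#'   ids raise an error, and the returned vector follows this order.
#' @return named numeric vector of phenotypes.
#' @export
readPhenotypes <- function(path, genotypeIds = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs id and value columns")
  ids <- canonicalHybridId(df[[1L]])
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(vals))
    stop(sprintf("non-numeric phenotype value at line %d", which(is.na(vals))[1L] + 1L))
  if (anyDuplicated(ids))
    stop("duplicate phenotype record(s) for ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         ": provide one record per hybrid (pre-average repeated measurements)")
  y <- setNames(vals, ids)
  if (!is.null(genotypeIds)) {
    unknown <- setdiff(ids, genotypeIds)
    if (length(unknown))
      stop("phenotype id(s) not found among the genotyped hybrids: ",
           paste(unknown, collapse = ", "))
    y <- y[intersect(genotypeIds, ids)]
  }
  y
}

#' Canonical hybrid identifier
#'
#' Normalizes `"B x A"`, `"BxA"` or `"B_x_A"` to `"AxB"` with the parent ids
#' sorted, the half-diallel convention in which a cross and its reciprocal
#' share one id.
#'
#' @param ids character vector of hybrid ids.
#' @return character vector of canonical ids.
#' @export
canonicalHybridId <- function(ids) {
  vapply(as.character(ids), function(id) {
    parts <- strsplit(id, "\\s+x\\s+|_x_")[[1L]]
    if (length(parts) != 2L) {
      ## compact form "AxB": only safe when there is exactly one 'x'
      if (lengths(regmatches(id, gregexpr("x", id, fixed = TRUE))) == 1L)
        parts <- strsplit(id, "x", fixed = TRUE)[[1L]]
      else return(id)
    }
    if (length(parts) != 2L) return(id)
    paste(sort(trimws(parts)), collapse = "x")
  }, character(1), USE.NAMES = FALSE)
}

## Tiny polynomial rolling hash for provenance headers (no external digest
## dependency; collision resistance is not a goal here).
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a ranked table with a provenance header
#'
#' Writes CSV preceded by a comment line recording the package version, the
#' seed and a hash of the run configuration, so output files are
#' self-describing.
#'
#' @param df data frame, e.g. from [rankHybrids()] or [rankParents()].
#' @param path output file.
#' @param seed seed used for the run (optional).
#' @param config configuration object to hash (optional).
#' @param digits presentation rounding for numeric columns (default 3,
#'   `NULL` for full precision).
#' @export
writeRankedTable <- function(df, path, seed = NULL, config = NULL, digits = 3) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  header <- sprintf("# diallelGS %s; seed=%s; config=%s",
                    as.character(packageVersion("diallelGS")),
                    if (is.null(seed)) "NA" else seed,
                    if (is.null(config)) "NA" else .configHash(config))
  body <- utils::capture.output(write.csv(df, row.names = FALSE, quote = FALSE))
  writeLines(c(header, body), path)
  invisible(path)
}
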