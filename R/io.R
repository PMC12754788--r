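# Readers and writers: TSV genotype/phenotype matrices, VCF genotypes
# (via vcfR), and provenance-stamped summary statistics.

#' Read a genotype dosage matrix
#'
#' TSV layout: samples in rows, one `sample_id` column (optional) and one
#' column per variant (header = variant ids), dosages in \[0, 2\]. VCF:
#' biallelic records with GT fields; the dosage is the ALT allele count.
#' Missing genotypes are imputed with the variant's mean dosage (count
#' reported via `message()`); multi-allelic VCF records are skipped with
#' a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") return(readGenotypesVCF(path))
  first <- readLines(path, n = 1L)
  positions <- NULL
  if (startsWith(first, "#positions=")) {
    positions <- as.integer(strsplit(sub("#positions=", "", first),
                                     ",", fixed = TRUE)[[1]])
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  sampleIds <- NULL
  if ("sample_id" %in% names(df)) {
    sampleIds <- as.character(df$sample_id)
    df$sample_id <- NULL
  }
  d <- as.matrix(df)
  if (!is.numeric(d)) stop("non-numeric dosages in ", path)
  nMissing <- sum(is.na(d))
  if (nMissing) {
    message(nMissing, " missing dosages mean-imputed")
    for (j in seq_len(ncol(d))) {
      na <- is.na(d[, j])
      if (any(na)) d[na, j] <- mean(d[!na, j])
    }
  }
  GenotypeMatrix(d, variantIds = colnames(d), positions = positions,
                 sampleIds = sampleIds)
}

readGenotypesVCF <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (!nrow(fix)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  countAlt <- function(x) {
    x[is.na(x)] <- "."
    alleles <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (!length(a) || any(is.na(a)) || any(a == "."))
        return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  d <- apply(gt, 2, countAlt)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1,
                                   dimnames = list(rownames(gt),
                                                   colnames(gt)))
  d <- t(d)  # samples x variants
  nMissing <- sum(is.na(d))
  if (nMissing) {
    message(nMissing, " missing genotype(s) mean-imputed")
    for (j in seq_len(ncol(d))) {
      na <- is.na(d[, j])
      d[na, j] <- mean(d[!na, j])
    }
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  GenotypeMatrix(d, variantIds = ids,
                 positions = as.integer(fix[, "POS"]),
                 sampleIds = rownames(d))
}

#' Write a genotype matrix as TSV
#'
#' Samples x variants with a leading `sample_id` column; base-pair
#' positions, when present, travel in a `#positions=` comment line so
#' the matrix round-trips through [readGenotypes()].
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output file.
#' @export
writeGenotypesTSV <- function(genotypes, path) {
  d <- dosages(genotypes)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", variantIds(genotypes))
  con <- file(path, "w")
  on.exit(close(con))
  pos <- variantPositions(genotypes)
  if (!anyNA(pos))
    writeLines(paste0("#positions=", paste(pos, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' One biallelic record per variant (REF A, ALT G placeholders), GT
#' derived from the rounded dosage (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#' Positions default to the variant index when absent.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output file.
#' @param chrom chromosome label for all records.
#' @export
writeGenotypesVCF <- function(genotypes, path, chrom = "1") {
  d <- dosages(genotypes)
  pos <- variantPositions(genotypes)
  if (anyNA(pos)) pos <- seq_len(ncol(d))
  gtStrings <- c("0/0", "0/1", "1/1")
  samples <- rownames(d)
  recs <- vapply(seq_len(ncol(d)), function(j) {
    gt <- gtStrings[pmin(2L, pmax(0L, as.integer(round(d[, j])))) + 1L]
    paste(c(chrom, pos[j], variantIds(genotypes)[j], "A", "G", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    recs), path)
  invisible(path)
}

#' Read a censored phenotype table
#'
#' TSV with columns `sample_id`, `value`, `lod` (a single trait-wide LOD
#' repeated on every row; per-row-varying LODs are rejected, since the
#' downstream transforms assume one detection limit per trait). Values
#' at or below the LOD are treated as censored and substituted with the
#' LOD. Rows with missing values are dropped with a reported count.
#'
#' @param path input TSV.
#' @return a [CensoredPhenotype-class]; sample ids are kept as names of
#'   `observedValues()`.
#' @export
readPhenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "value", "lod")
  if (!all(need %in% names(df)))
    stop("phenotype file must contain columns: ",
         paste(need, collapse = ", "))
  if (!is.numeric(df$value) || !is.numeric(df$lod))
    stop("value and lod must be numeric")
  drop <- !stats::complete.cases(df[, c("value", "lod")])
  if (any(drop)) {
    message(sum(drop), " row(s) with missing values dropped")
    df <- df[!drop, , drop = FALSE]
  }
  lods <- unique(df$lod)
  if (length(lods) > 1L)
    stop("per-row differing LOD values found (", length(lods),
         " distinct); a single LOD per trait is required")
  ph <- CensoredPhenotype(pmax(df$value, lods), lod = lods,
                          isCensored = df$value <= lods)
  ph@observed <- stats::setNames(ph@observed, df$sample_id)
  ph
}

#' Write a phenotype table as TSV
#'
#' Columns `sample_id`, `value`, `lod`, `is_censored`.
#'
#' @param ph a [CensoredPhenotype-class].
#' @param path output file.
#' @param sampleIds optional ids (defaults to names or s1..sn).
#' @export
writePhenotypeTSV <- function(ph, path, sampleIds = NULL) {
  v <- observedValues(ph)
  if (is.null(sampleIds))
    sampleIds <- names(v) %||% paste0("s", seq_along(v))
  df <- data.frame(sample_id = sampleIds, value = unname(v),
                   lod = lodValue(ph), is_censored = isCensored(ph))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' TSV with a `sample_id` column followed by numeric covariate columns.
#'
#' @param path input TSV.
#' @return numeric matrix with sample ids as row names.
#' @export
readCovariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  ids <- as.character(df$sample_id)
  df$sample_id <- NULL
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric covariates")
  rownames(m) <- ids
  m
}

#' Write GWAS summary statistics
#'
#' TSV preceded by `#key=value` provenance header lines (model, tie
#' policy, INT offset, clump parameters, seed, package version). Effect
#' estimates and standard errors are written with 6 significant digits
#' and p-values in scientific notation with 4 significant digits.
#'
#' @param table a [GwasTable-class].
#' @param path output file.
#' @param seed optional seed to record in the header.
#' @export
writeSumstats <- function(table, path, seed = NULL) {
  stopifnot(methods::is(table, "GwasTable"))
  tab <- table@table
  if (!nrow(tab)) stop("empty table")
  md <- table@metadata
  hdr <- c(
    paste0("#tool=tobitGWAS ",
           as.character(utils::packageVersion("tobitGWAS"))),
    paste0("#model=", md$model %||% "NA"),
    paste0("#ties_policy=", md$ties_policy %||% "NA"),
    paste0("#int_offset=", md$int_offset %||% "NA"),
    paste0("#censored_proportion=", md$censored_proportion %||% "NA"))
  if (!is.null(md$clump_params))
    hdr <- c(hdr, sprintf("#clump=p1=%g;p2=%g;r2=%g;kb=%g",
                          md$clump_params$p1, md$clump_params$p2,
                          md$clump_params$r2, md$clump_params$windowKb))
  if (!is.null(seed)) hdr <- c(hdr, paste0("#seed=", seed))
  fmt <- tab
  for (col in intersect(c("beta", "se", "refined_beta", "refined_se"),
                        names(fmt)))
    fmt[[col]] <- signif(fmt[[col]], 6)
  for (col in intersect(c("p_value", "refined_p"), names(fmt)))
    fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA,
                         formatC(fmt[[col]], format = "e", digits = 3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Read summary statistics written by [writeSumstats()]
#'
#' @param path input TSV.
#' @return a [GwasTable-class]; the parsed provenance header lands in
#'   `gwasMetadata()`.
#' @export
readSumstats <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) >= 2)
      meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  tab <- utils::read.delim(textConnection(lines[-hdr]),
                           stringsAsFactors = FALSE)
  if (!is.null(meta$int_offset))
    meta$int_offset <- as.numeric(meta$int_offset)
  methods::new("GwasTable", table = tab, metadata = meta)
}
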