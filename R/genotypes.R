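#' Construct a genotype matrix
#'
#' Dosage container for biallelic markers: a lines x markers integer matrix
#' with values 0/1/2 (copies of the alternate allele) and `NA` for missing
#' calls, plus a marker table sorted by (chrom, pos_bp).
#'
#' @param dosage numeric matrix, lines in rows, markers in columns.
#' @param markers data.frame with columns `chrom`, `pos_bp` and optionally
#'   `marker_id`, `ref`, `alt`.
#' @param samples character vector of line IDs (defaults to rownames).
#' @return A `genotype_matrix` object: list with elements `dosage`, `markers`,
#'   `samples`.
#' @export
genotype_matrix <- function(dosage, markers, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(markers))
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(samples)) samples <- paste0("line", seq_len(nrow(dosage)))
  markers$chrom <- as.character(markers$chrom)
  if (is.null(markers$marker_id)) {
    markers$marker_id <- paste0(markers$chrom, "_", markers$pos_bp)
  }
  if (is.null(markers$ref)) markers$ref <- "A"
  if (is.null(markers$alt)) markers$alt <- "T"
  key <- paste(markers$chrom, markers$pos_bp)
  if (anyDuplicated(key)) stop("duplicated (chrom, pos_bp) marker records")
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos_bp)
  markers <- markers[ord, c("marker_id", "chrom", "pos_bp", "ref", "alt")]
  rownames(markers) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(samples, markers$marker_id)
  structure(list(dosage = dosage, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%s)\n",
              length(x$samples), nrow(x$markers),
              paste(unique(x$markers$chrom), collapse = ", ")))
  invisible(x)
}

#' Subset a genotype matrix by marker and/or line index
#' @param geno a [genotype_matrix()].
#' @param markers integer/logical index into markers (optional).
#' @param lines integer/logical/character index into lines (optional).
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(geno, markers = NULL, lines = NULL) {
  d <- geno$dosage
  m <- geno$markers
  s <- geno$samples
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
  }
  if (!is.null(lines)) {
    if (is.character(lines)) lines <- match(lines, s)
    d <- d[lines, , drop = FALSE]
    s <- s[lines]
  }
  rownames(m) <- NULL
  structure(list(dosage = d, markers = m, samples = s),
            class = "genotype_matrix")
}

#' Minor allele frequency per marker
#' @param geno a [genotype_matrix()].
#' @return numeric vector of MAFs (NA for fully missing markers).
#' @export
marker_maf <- function(geno) {
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Read genotypes from VCF or TSV
#'
#' VCF input (v4.x, parsed with vcfR) keeps biallelic SNP/InDel records and
#' skips multiallelic records with a logged count; GT fields are mapped to
#' dosages (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA). TSV input is the
#' matrix written by [write_genotypes()]: marker metadata columns followed by
#' one column per line.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @return A [genotype_matrix()]. Number of skipped multiallelic VCF records
#'   is available as attribute `n_skipped`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF ", path)
  multi <- grepl(",", fix$ALT)
  n_skipped <- sum(multi)
  if (n_skipped > 0) {
    message("read_genotypes: skipped ", n_skipped, " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    out
  }
  dos <- apply(gt, 2, code)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
  markers <- data.frame(chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
                        marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                           paste0(fix$CHROM, "_", fix$POS), fix$ID),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  out <- genotype_matrix(t(dos), markers, samples = colnames(gt))
  attr(out, "n_skipped") <- n_skipped
  out
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(marker_id = "character",
                                          chrom = "character",
                                          ref = "character",
                                          alt = "character"))
  meta_cols <- c("marker_id", "chrom", "pos_bp", "ref", "alt")
  if (!all(c("chrom", "pos_bp") %in% names(tab))) {
    stop("malformed dosage TSV header (need chrom, pos_bp): ", path)
  }
  meta <- intersect(meta_cols, names(tab))
  samples <- setdiff(names(tab), meta)
  if (length(samples) == 0L) stop("no sample columns in ", path)
  dos <- t(as.matrix(tab[, samples, drop = FALSE]))
  genotype_matrix(dos, tab[, meta, drop = FALSE], samples = samples)
}

#' Write genotypes as a dosage TSV
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  out <- cbind(geno$markers,
               as.data.frame(t(geno$dosage), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Expects columns `line`, `trait`, `value` and optionally `env`. At most one
#' value per (line, trait, env) is allowed.
#'
#' @param path file path.
#' @return data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  phenotype_table(tab)
}

#' Validate and normalise a phenotype table
#' @param tab data.frame with `line`, `trait`, `value` and optional `env`.
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(tab) {
  stopifnot(all(c("line", "trait", "value") %in% names(tab)))
  if (is.null(tab$env)) tab$env <- "env1"
  key <- paste(tab$line, tab$trait, tab$env)
  if (anyDuplicated(key)) stop("more than one value per (line, trait, env)")
  tab <- tab[, c("line", "trait", "env", "value")]
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write a phenotype table to CSV
#' @param pheno a phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
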