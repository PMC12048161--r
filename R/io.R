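#' Write / read GWAS summary statistics TSV
#'
#' Tab-delimited with columns `SNP, CHR, BP, A1, A2, BETA, SE, Z, N, MAF,
#' INFO` (1-based positions, per-allele effects on the standardized
#' phenotype).
#'
#' @param ss a `summary_stats` data frame.
#' @param path file path.
#' @export
write_summary_tsv <- function(ss, path) {
  out <- data.frame(SNP = ss$id, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
                    A2 = ss$a2, BETA = ss$beta, SE = ss$se, Z = ss$z,
                    N = ss$n, MAF = ss$maf, INFO = ss$info)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @return `read_summary_tsv` returns a `summary_stats` data frame.
#' @export
read_summary_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "N",
            "MAF", "INFO")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$BETA) | !is.finite(d$SE) | d$SE <= 0)
  if (length(bad))
    stop("malformed rows (non-finite effect or non-positive SE) at lines: ",
         paste(bad + 1L, collapse = ", "))
  ss <- data.frame(id = d$SNP, chrom = d$CHR, pos = d$BP, a1 = d$A1,
                   a2 = d$A2, beta = d$BETA, se = d$SE, z = d$Z, n = d$N,
                   maf = d$MAF, info = d$INFO, stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

#' Write / read cis-eQTL summary statistics TSV
#'
#' Same layout as the GWAS TSV plus `GENE`, `TSS`, `TISSUE` columns.
#'
#' @param ss a `summary_stats` data frame.
#' @param path file path.
#' @param gene,tss,tissue gene annotation.
#' @export
write_eqtl_tsv <- function(ss, path, gene, tss, tissue) {
  out <- data.frame(SNP = ss$id, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
                    A2 = ss$a2, BETA = ss$beta, SE = ss$se, Z = ss$z,
                    N = ss$n, MAF = ss$maf, INFO = ss$info,
                    GENE = gene, TSS = tss, TISSUE = tissue)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_tsv
#' @return `read_eqtl_tsv` returns a `summary_stats` data frame with
#'   `gene`, `tss`, `tissue` columns.
#' @export
read_eqtl_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  ss <- data.frame(id = d$SNP, chrom = d$CHR, pos = d$BP, a1 = d$A1,
                   a2 = d$A2, beta = d$BETA, se = d$SE, z = d$Z, n = d$N,
                   maf = d$MAF, info = d$INFO, gene = d$GENE, tss = d$TSS,
                   tissue = d$TISSUE, stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

#' Write / read BED intervals (0-based half-open)
#'
#' @param bed data frame with `chrom`, `start`, `end` and optional `name`.
#' @param path file path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  if (any(d$end <= d$start))
    stop("malformed BED: end <= start at line(s) ",
         paste(which(d$end <= d$start), collapse = ", "))
  d
}

#' Convert between 1-based variant positions and BED intervals
#'
#' A single-base variant at 1-based position `p` occupies the 0-based
#' half-open interval `[p - 1, p)`.
#'
#' @param pos 1-based positions.
#' @return data frame `start`, `end` (0-based half-open).
#' @export
pos_to_bed <- function(pos) data.frame(start = pos - 1L, end = pos)

#' @rdname pos_to_bed
#' @param start,end 0-based half-open single-base interval.
#' @return `bed_to_pos` returns 1-based positions.
#' @export
bed_to_pos <- function(start, end) {
  if (any(end - start != 1L)) stop("not single-base intervals")
  start + 1L
}

#' Write / read FASTA sequences
#'
#' @param sequences named character vector.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a `truth_record` (or plain list).
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
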