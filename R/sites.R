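#' Read a table of single-base m6A sites
#'
#' Sites come from base-resolution CLIP experiments (mi-CLIP / m6A-CLIP) and
#' are consumed as given: one row per methylated adenosine with 1-based
#' coordinates and optional host-gene labels. Gene assignment for sites
#' overlapping several gene models is accepted as provided in the table.
#'
#' @param path TSV with header; required columns `site_id`, `chrom`,
#'   `position`, `strand`; optional `gene_entrez`, `gene_symbol`.
#' @return data.frame of sites in file order, one row per `GenomicSite`,
#'   with `position` integer and `gene_entrez` integer (NA when absent).
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path)) stopf("site table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(site_id = "character",
                                     chrom = "character"))
  need <- c("site_id", "chrom", "position", "strand")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("site table is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (!"gene_entrez" %in% colnames(df)) df$gene_entrez <- NA_integer_
  if (!"gene_symbol" %in% colnames(df)) df$gene_symbol <- NA_character_
  validateSites(df)
  df$position <- as.integer(df$position)
  df$gene_entrez <- suppressWarnings(as.integer(df$gene_entrez))
  df[c("site_id", "chrom", "position", "strand", "gene_entrez", "gene_symbol")]
}

validateSites <- function(df) {
  pos <- suppressWarnings(as.numeric(df$position))
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
  if (length(bad))
    stopf("malformed position in row(s): %s", paste(head(bad, 5), collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stopf("invalid strand in row(s): %s (must be '+' or '-')",
          paste(head(bad, 5), collapse = ", "))
  dup <- df$site_id[duplicated(df$site_id)]
  if (length(dup))
    stopf("duplicate site_id(s): %s", paste(unique(head(dup, 5)), collapse = ", "))
  invisible(df)
}

#' Write a site table
#' @param sites data.frame as returned by [readSiteTable()].
#' @param path output TSV path.
#' @export
writeSiteTable <- function(sites, path) {
  validateSites(sites)
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export sites as BED6
#'
#' Converts the 1-based single-base coordinates to BED's 0-based half-open
#' convention; the name field carries the site id, score 0.
#' @inheritParams writeSiteTable
#' @export
writeSiteBed <- function(sites, path) {
  validateSites(sites)
  bed <- data.frame(chrom = sites$chrom,
                    start = sites$position - 1L,
                    end = sites$position,
                    name = sites$site_id,
                    score = 0L,
                    strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test pentamers for the DRACH consensus
#'
#' The m6A consensus motif is D-R-A-C-H with D = A/G/T, R = A/G and
#' H = A/C/T, centred on the methylated adenosine; exactly 18 pentamers
#' qualify.
#'
#' @param pentamer character vector of 5-letter DNA strings (A/C/G/T).
#' @return logical vector.
#' @examples
#' checkDrach(c("GGACT", "GGGCT"))
#' @export
checkDrach <- function(pentamer) {
  if (any(nchar(pentamer) != 5L))
    stopf("pentamers must have length 5")
  if (any(grepl("[^ACGT]", pentamer)))
    stopf("pentamers must use the DNA alphabet A/C/G/T")
  grepl("^[AGT][AG]AC[ACT]$", pentamer)
}

#' Filter sites by CLIP-sample support
#'
#' Sites are retained when reported by at least `minSupport` of the
#' base-resolution CLIP samples (default 2 of 6).
#'
#' @param supportCounts named integer vector, site id -> number of
#'   supporting samples.
#' @param minSupport minimum support, default 2.
#' @return character vector of retained site ids, input order preserved.
#' @export
supportFilter <- function(supportCounts, minSupport = 2L) {
  if (any(supportCounts < 0))
    stopf("support counts must be non-negative")
  assertScalarNumber(minSupport, "minSupport", lower = 0)
  names(supportCounts)[supportCounts >= minSupport]
}

#' Quantification window around a site
#'
#' The read-counting bin is `width` bp long with the methylation site at its
#' centre (101 bp by default); the interval is truncated at coordinate 1.
#'
#' @param position integer vector of 1-based site positions.
#' @param width odd window width, default 101.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @export
siteWindow <- function(position, width = 101L) {
  assertScalarNumber(width, "width", lower = 1)
  if (width %% 2 == 0) stopf("'width' must be odd")
  half <- (width - 1L) / 2L
  data.frame(start = pmax(1L, as.integer(position - half)),
             end = as.integer(position + half))
}
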