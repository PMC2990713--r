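## Standard-format I/O. Interval tables are 0-based half-open (BED
## convention) in memory, so BED round-trips are coordinate-exact.

df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if ("strand" %in% names(df)) {
      s <- df$strand
      s[!s %in% c("+", "-")] <- "*"
      s
    } else "*")
  if (!is.null(df$id)) names(gr) <- df$id
  if (!is.null(df$name)) names(gr) <- df$name
  gr
}

#' Write an interval table as BED
#'
#' @param df data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{id}/\code{name}, \code{score},
#'   \code{strand}; extra columns are appended as BED6+ fields.
#' @param path output path.
#' @param extra_cols character vector of extra column names to append.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path, extra_cols = NULL) {
  gr <- df_to_granges(df)
  if (!is.null(df$score)) gr$score <- pmin(pmax(df$score, 0), 1000)
  rtracklayer::export(gr, path, format = "BED")
  if (!is.null(extra_cols) && length(extra_cols) > 0) {
    base <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    utils::write.table(cbind(base, df[, extra_cols, drop = FALSE]), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file as a 0-based half-open interval table
#' @param path BED path.
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{id},
#'   \code{score}, \code{strand} (where present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$id <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", ".", st)
  out
}

#' Write a two-column chromosome-sizes file
#' @param genome a \code{GenomeModel}.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(genome$chromosomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes file into a bare GenomeModel
#' @param path two-column (chrom, length) TSV.
#' @return a \code{GenomeModel} with empty feature sets.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  genome <- list(chromosomes = tab,
                 features = list(genes = empty_features(),
                                 ucsc_elements = empty_features(),
                                 mirnas = empty_features(),
                                 qtls = empty_features()))
  class(genome) <- "GenomeModel"
  genome
}

#' Write/read tab-separated tables with headers
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path GMT path.
#' @return named list of member-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @param descriptions optional descriptions (defaults to the names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an ArrayScan as a TSV scan table
#' @param scan an \code{ArrayScan}.
#' @param path output path.
#' @export
write_scan <- function(scan, path) {
  meta <- data.frame(array_id = attr(scan, "array_id"),
                     sample_id = attr(scan, "sample_id"),
                     orientation = attr(scan, "orientation"))
  write_tsv(cbind(meta, as.data.frame(scan)), path)
}

#' Read a scan table written by \code{\link{write_scan}}
#' @param path scan TSV path.
#' @return an \code{ArrayScan}.
#' @export
read_scan <- function(path) {
  tab <- read_tsv(path)
  scan <- tab[, setdiff(names(tab), c("array_id", "sample_id", "orientation"))]
  attr(scan, "array_id") <- tab$array_id[1]
  attr(scan, "sample_id") <- tab$sample_id[1]
  attr(scan, "orientation") <- tab$orientation[1]
  class(scan) <- c("ArrayScan", "data.frame")
  scan
}
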