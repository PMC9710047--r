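# Genomic track output: bedGraph by default, BigWig through rtracklayer
# when available.

#' Write a bedGraph track
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param name Optional track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  write.table(format(track[, c("chrom", "start", "end", "value")],
                     scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a BigWig track
#'
#' Requires the `rtracklayer` package.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param chroms Chromosome data.frame (for the sequence lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(track, chroms, path) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges", "GenomeInfoDb"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("BigWig output requires the ", pkg, " package; use bedGraph instead")
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end),
    score = track$value
  )
  GenomeInfoDb::seqlengths(gr) <- setNames(chroms$length, chroms$name)[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path (optional `track` header line tolerated).
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  df
}

# JSON provenance record written next to every CLI output.
write_provenance <- function(path, subcommand, config) {
  rec <- list(
    tool = "extrusim",
    version = as.character(utils::packageVersion("extrusim")),
    r_version = as.character(getRversion()),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(rec, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(rec)
}
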