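# File-format boundary: BED, wiggle, GFF3 (read-only), intensity/probe
# TSVs, chrom.sizes. All coordinates are converted exactly once at this
# boundary: BED and internal intervals are 0-based half-open; wiggle and
# GFF are 1-based closed on disk.

#' Read a BED3-BED6 file
#'
#' Tab-separated; `track`/`browser`/comment lines are skipped. Malformed
#' lines are rejected with the file name and line number.
#'
#' @param path File path.
#' @return An interval table (0-based half-open) with `name`, `score`,
#'   `strand` when the file carries those columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep))
    return(genomic_intervals(character(), integer(), integer()))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("%s:%d: BED line has fewer than 3 fields", path, lineno[which(nf < 3L)[1]])
  ncols <- max(pmin(nf, 6L))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0)
    stopf("%s:%d: non-numeric BED coordinates", path, lineno[bad[1]])
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0)
    stopf("%s:%d: invalid BED interval (end <= start)", path, lineno[bad[1]])
  name <- if (ncols >= 4L) get(4) else NULL
  score <- if (ncols >= 5L) suppressWarnings(as.numeric(get(5))) else NULL
  strand <- if (ncols >= 6L) get(6) else "."
  if (ncols >= 6L) {
    strand[is.na(strand)] <- "."  # shorter lines are unstranded
    if (any(!strand %in% c("+", "-", ".")))
      stopf("%s:%d: invalid strand field", path,
            lineno[which(!strand %in% c("+", "-", "."))[1]])
  }
  genomic_intervals(chrom, start, end, strand = strand, name = name,
                    score = score)
}

#' Write intervals as BED
#'
#' Writes as many of the BED3-BED6 columns as the table carries
#' (`name`, `score`, `strand`). Output is deterministic (no quoting, fixed
#' number formatting), so identical tables round-trip byte-identically.
#'
#' @param intervals Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  cols <- list(intervals$chrom, fmt_num(intervals$start),
               fmt_num(intervals$end))
  has_name <- !is.null(intervals$name)
  has_score <- !is.null(intervals$score)
  has_strand <- !is.null(intervals$strand) && any(intervals$strand != ".")
  if (has_name || has_score || has_strand)
    cols <- c(cols, list(if (has_name) intervals$name else rep(".", nrow(intervals))))
  if (has_score || has_strand)
    cols <- c(cols, list(if (has_score) fmt_num(intervals$score) else rep("0", nrow(intervals))))
  if (has_strand) cols <- c(cols, list(intervals$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a wiggle coverage track
#'
#' Supports `fixedStep` and `variableStep` (with `span`) declarations;
#' wiggle's 1-based closed coordinates are converted to the 0-based
#' half-open track convention. An empty file yields an empty track.
#'
#' @param path File path.
#' @return A [coverage_track()].
#' @export
read_wiggle <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  content <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(content) == 0L) return(coverage_track())
  if (!grepl("^(fixedStep|variableStep)", content[1]))
    stopf("%s: missing fixedStep/variableStep declaration", path)
  gr <- tryCatch(rtracklayer::import(path, format = "wig"),
                 error = function(e) stopf("%s: wiggle parse error: %s",
                                           path, conditionMessage(e)))
  if (length(gr) == 0L) return(coverage_track())
  coverage_track(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                 S4Vectors::mcols(gr)$score)
}

#' Write a coverage track as wiggle
#'
#' Emits one `variableStep span=1` block per chromosome with a line per
#' covered base, omitting zero-depth bases; absent bases read back as
#' depth 0, so round-trips are exact per base. (A single block per
#' chromosome parses far faster than per-run spans.)
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path) {
  steps <- track[track$depth > 0, , drop = FALSE]
  if (nrow(steps) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  widths <- as.integer(steps$end - steps$start)
  pos <- sequence(widths) - 1L + rep(as.integer(steps$start), widths)
  dep <- rep(steps$depth, widths)
  ch <- rep(steps$chrom, widths)
  out <- unlist(lapply(unique(ch), function(cc) {
    i <- ch == cc
    c(sprintf("variableStep chrom=%s span=1", cc),
      sprintf("%d %s", pos[i] + 1L,
              format(dep[i], scientific = FALSE, trim = TRUE)))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path File path (TSV: chromosome, length).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  if (any(!is.finite(df$size)) || any(df$size <= 0))
    stopf("%s: chromosome sizes must be positive numbers", path)
  stats::setNames(as.numeric(df$size), df$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named numeric vector to write.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(sprintf("%s\t%s", names(chrom_sizes),
                     format(chrom_sizes, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Read-only: extracts `gene` and `exon` features into the two annotation
#' layers the pipeline uses, converting to 0-based half-open coordinates.
#'
#' @param path File path.
#' @return List with interval tables `gene_bodies` and `known_exons`.
#' @export
read_gff3_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("%s: GFF3 parse error: %s", path,
                                           conditionMessage(e)))
  pick <- function(type) {
    sub <- gr[S4Vectors::mcols(gr)$type == type]
    if (length(sub) == 0L) return(empty_intervals())
    nm <- S4Vectors::mcols(sub)$ID
    if (is.null(nm)) nm <- S4Vectors::mcols(sub)$Parent
    genomic_intervals(as.character(GenomicRanges::seqnames(sub)),
                      GenomicRanges::start(sub) - 1L, GenomicRanges::end(sub),
                      strand = ifelse(as.character(GenomicRanges::strand(sub)) %in%
                                        c("+", "-"),
                                      as.character(GenomicRanges::strand(sub)), "."),
                      name = as.character(nm))
  }
  list(gene_bodies = pick("gene"), known_exons = pick("exon"))
}

#' Write gene models as GFF3
#'
#' @param gene_bodies,known_exons Interval tables with `name` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(gene_bodies, known_exons, path) {
  row <- function(df, type) {
    if (nrow(df) == 0L) return(character())
    sprintf("%s\tucetx\t%s\t%d\t%d\t.\t%s\t.\tID=%s", df$chrom, type,
            as.integer(df$start) + 1L, as.integer(df$end),
            ifelse(df$strand == ".", "+", df$strand),
            if (!is.null(df$name)) df$name else sprintf("%s_%d", type, seq_len(nrow(df))))
  }
  writeLines(c("##gff-version 3", row(gene_bodies, "gene"),
               row(known_exons, "exon")), path)
  invisible(path)
}

#' Read a probe intensity table
#'
#' TSV with metadata columns `probe_id`, `target_id`, `strand`, `role`
#' followed by one numeric column per array, named `STAGE_repN`. Duplicate
#' probe ids, ragged rows, missing metadata columns and non-numeric cells
#' are rejected.
#'
#' @param path File path.
#' @return List with `meta` (probe metadata) and `values` (probe x array
#'   matrix).
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stopf("%s:%d: ragged row (expected %d fields)", path,
          which(nf != nf[1])[1], nf[1])
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("probe_id", "target_id", "strand", "role")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss) > 0)
    stopf("%s: missing metadata column(s): %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stopf("%s: duplicate probe_id: %s", path,
          df$probe_id[duplicated(df$probe_id)][1])
  array_cols <- setdiff(names(df), meta_cols)
  if (length(array_cols) == 0L) stopf("%s: no array columns", path)
  parse_array_labels(array_cols)  # validates naming
  vals <- as.matrix(df[array_cols])
  if (!is.numeric(vals)) stopf("%s: non-numeric intensity cell(s)", path)
  rownames(vals) <- df$probe_id
  list(meta = df[meta_cols], values = vals)
}

#' Write a probe intensity table
#'
#' @param meta Probe metadata.
#' @param values Probe x array matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(meta, values, path) {
  stopifnot(identical(meta$probe_id, rownames(values)))
  df <- cbind(meta, as.data.frame(values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a plain deterministic TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
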