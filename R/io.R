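# Readers/writers for the text genomics formats the pipeline touches.
# Internal convention everywhere: 0-based half-open; GTF (1-based inclusive)
# is converted at the boundary. Scaffold names are matched by exact string
# equality -- no "chr" aliasing.

read_tab_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   !startsWith(lines, "browser")]
  lines
}

parse_coord <- function(x, line_no, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v)
  if (any(bad))
    stop("parse error in ", path, " at line ", line_no[bad][1L],
         ": non-integer coordinate '", x[bad][1L], "'")
  v
}

#' Read peak calls from narrowPeak or BED
#'
#' @param path file path.
#' @param format `"narrowPeak"` (10-column ENCODE) or `"bed"` (3-6 column).
#'   narrowPeak column 10 is the summit offset; `-1` means absent.
#' @return a [peaks()] table; for narrowPeak input the `signal_value`,
#'   `p_value` and `q_value` columns are retained so that [write_peaks()]
#'   round-trips the file.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  lines <- read_tab_lines(path)
  if (length(lines) == 0L)
    return(peaks(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < need))
    stop("parse error in ", path, " at line ", which(nf < need)[1L],
         ": expected >= ", need, " tab-separated fields")
  ln <- seq_along(lines)
  col <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  start <- parse_coord(col(2), ln, path)
  end <- parse_coord(col(3), ln, path)
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1L],
         ": invalid interval [", start[bad[1L]], ", ", end[bad[1L]], ")")
  name <- col(4); name[is.na(name)] <- "."
  score <- suppressWarnings(as.numeric(col(5))); score[is.na(score)] <- 0
  strand <- col(6); strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  p <- peaks(col(1), start, end, name = name, score = score, strand = strand)
  attr(p, "bed_ncol") <- max(nf)
  if (format == "narrowPeak") {
    summit <- parse_coord(col(10), ln, path)
    p$summit_offset <- ifelse(summit < 0L, NA_integer_, summit)
    bad <- which(!is.na(p$summit_offset) & p$summit_offset >= end - start)
    if (length(bad))
      stop("parse error in ", path, " at line ", bad[1L],
           ": summit offset outside peak")
    p$signal_value <- as.numeric(col(7))
    p$p_value <- as.numeric(col(8))
    p$q_value <- as.numeric(col(9))
  }
  p
}

#' Write peaks to narrowPeak or BED
#'
#' Inverse of [read_peaks()]: `write_peaks(read_peaks(f), g)` reproduces a
#' canonical input file byte for byte.
#'
#' @param x a [peaks()] table.
#' @param path output path.
#' @param format `"narrowPeak"` or `"bed"`.
#' @export
write_peaks <- function(x, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  num <- function(v) sprintf("%.15g", v)
  if (format == "narrowPeak") {
    sv <- if (!is.null(x$signal_value)) x$signal_value else x$score
    pv <- if (!is.null(x$p_value)) x$p_value else rep(-1, nrow(x))
    qv <- if (!is.null(x$q_value)) x$q_value else rep(-1, nrow(x))
    summit <- ifelse(is.na(x$summit_offset), -1L, x$summit_offset)
    lines <- paste(x$scaffold, x$start, x$end, x$name, num(x$score),
                   x$strand, num(sv), num(pv), num(qv), summit, sep = "\t")
  } else {
    ncol_out <- attr(x, "bed_ncol")
    if (is.null(ncol_out)) ncol_out <- 6L
    cols <- list(x$scaffold, x$start, x$end, x$name, num(x$score), x$strand)
    lines <- do.call(paste, c(cols[seq_len(max(3L, min(ncol_out, 6L)))],
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ATAC fragments from BED3
#'
#' One fragment per line (`scaffold  start  end`); insert length is
#' `end - start`. Parsing is atomic: any malformed line aborts with an error
#' naming the line, and no partial result is returned.
#'
#' @param path file path.
#' @return a [fragments()] table (empty file gives an empty table).
#' @export
read_fragments <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0L)
    return(fragments(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("parse error in ", path, " at line ", which(nf < 3L)[1L],
         ": expected >= 3 tab-separated fields")
  ln <- seq_along(lines)
  start <- parse_coord(vapply(fields, `[`, "", 2L), ln, path)
  end <- parse_coord(vapply(fields, `[`, "", 3L), ln, path)
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1L], ": invalid interval")
  fragments(vapply(fields, `[`, "", 1L), start, end)
}

#' Write fragments as BED3
#' @param x a [fragments()] table.
#' @param path output path.
#' @export
write_fragments <- function(x, path) {
  writeLines(paste(x$scaffold, x$start, x$end, sep = "\t"), path)
  invisible(path)
}

#' Construct a gene model table
#'
#' Genes are rows with `gene_id`, `scaffold`, `start`, `end`,
#' `strand` (`"+"`/`"-"` only), derived single-bp `tss`/`tts`, and an
#' `exons` list column of `data.frame(start, end)` sorted, non-overlapping,
#' inside the gene span. For a `+` gene `tss = start` and `tts = end - 1`;
#' for a `-` gene `tss = end - 1` and `tts = start` (both ends stored as the
#' position of the terminal base).
#'
#' @param gene_id,scaffold,start,end,strand vectors, one entry per gene.
#' @param exons list of `data.frame(start, end)` per gene; `NULL` means a
#'   single exon spanning the whole gene.
#' @return a `data.frame` of class `c("gene_models", "data.frame")`.
#' @export
gene_models <- function(gene_id, scaffold, start, end, strand, exons = NULL) {
  n <- length(gene_id)
  if (any(!strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  df <- data.frame(gene_id = as.character(gene_id),
                   scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  validate_intervals(df, "gene")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tts <- ifelse(df$strand == "+", df$end - 1L, df$start)
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i)
      data.frame(start = df$start[i], end = df$end[i]))
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (nrow(ex) == 0L) next
    if (any(ex$start < df$start[i] | ex$end > df$end[i]))
      stop("exon outside gene span for ", df$gene_id[i])
    if (any(ex$start >= ex$end)) stop("empty exon for ", df$gene_id[i])
    if (is.unsorted(ex$start) || any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("exons overlapping or unsorted for ", df$gene_id[i])
  }
  df$exons <- exons
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from GTF or TSV
#'
#' GTF input uses `gene` and `exon` features with a `gene_id` attribute;
#' 1-based inclusive GTF coordinates are converted to the internal 0-based
#' half-open convention. TSV input has six columns: gene_id, scaffold,
#' start, end, strand, comma-joined `start-end` exon spans (already
#' 0-based half-open). A gene with strand `"."` is an error.
#'
#' @param path file path.
#' @param format `"gtf"` or `"tsv"`.
#' @return a [gene_models()] table.
#' @export
read_genes <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  lines <- read_tab_lines(path)
  if (format == "tsv") {
    if (length(lines) == 0L)
      return(gene_models(character(), character(), integer(), integer(),
                         character(), list()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6L))
      stop("parse error in ", path, ": expected 6 tab-separated columns")
    ex <- lapply(fields, function(f) {
      spans <- strsplit(strsplit(f[6L], ",", fixed = TRUE)[[1L]], "-",
                        fixed = TRUE)
      data.frame(start = as.integer(vapply(spans, `[`, "", 1L)),
                 end = as.integer(vapply(spans, `[`, "", 2L)))
    })
    return(gene_models(vapply(fields, `[`, "", 1L),
                       vapply(fields, `[`, "", 2L),
                       as.integer(vapply(fields, `[`, "", 3L)),
                       as.integer(vapply(fields, `[`, "", 4L)),
                       vapply(fields, `[`, "", 5L), ex))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && any(lengths(fields) < 8L))
    stop("parse error in ", path, ": expected >= 8 GTF fields")
  feat <- vapply(fields, `[`, "", 3L)
  gid <- vapply(fields, function(f) {
    m <- regmatches(f[9L], regexec('gene_id[ =]+"?([^";]+)"?', f[9L]))[[1L]]
    if (length(m) < 2L) stop("GTF record without gene_id in ", path) else m[2L]
  }, "")
  sc <- vapply(fields, `[`, "", 1L)
  # GTF 1-based inclusive -> 0-based half-open
  start0 <- as.integer(vapply(fields, `[`, "", 4L)) - 1L
  end0 <- as.integer(vapply(fields, `[`, "", 5L))
  strand <- vapply(fields, `[`, "", 7L)
  gi <- which(feat == "gene")
  if (any(strand[gi] == "."))
    stop("gene with strand '.' in ", path)
  exons <- lapply(gi, function(i) {
    ei <- which(feat == "exon" & gid == gid[i])
    if (length(ei) == 0L)
      return(data.frame(start = start0[i], end = end0[i]))
    o <- order(start0[ei])
    data.frame(start = start0[ei][o], end = end0[ei][o])
  })
  gene_models(gid[gi], sc[gi], start0[gi], end0[gi], strand[gi], exons)
}

#' Write gene models
#'
#' `format = "gtf"` emits one `gene` and per-exon `exon` records with
#' 1-based inclusive coordinates; `format = "tsv"` emits the 6-column format
#' read by [read_genes()].
#'
#' @param x a [gene_models()] table.
#' @param path output path.
#' @param format `"gtf"` or `"tsv"`.
#' @export
write_genes <- function(x, path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    exstr <- vapply(x$exons, function(e)
      paste(paste0(e$start, "-", e$end), collapse = ","), "")
    writeLines(paste(x$gene_id, x$scaffold, x$start, x$end, x$strand, exstr,
                     sep = "\t"), path)
    return(invisible(path))
  }
  lines <- character()
  for (i in seq_len(nrow(x))) {
    attrs <- sprintf('gene_id "%s";', x$gene_id[i])
    lines <- c(lines,
               paste(x$scaffold[i], "accessdyn", "gene", x$start[i] + 1L,
                     x$end[i], ".", x$strand[i], ".", attrs, sep = "\t"),
               paste(x$scaffold[i], "accessdyn", "exon",
                     x$exons[[i]]$start + 1L, x$exons[[i]]$end, ".",
                     x$strand[i], ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs are run-length encoded: adjacent runs with equal value are merged and
#' zero-coverage runs are omitted. [read_bedgraph()] inverts the encoding.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character()
  for (sc in names(track)) {
    r <- track[[sc]]
    keep <- r$value != 0
    if (!any(keep)) next
    r <- r[keep, , drop = FALSE]
    lines <- c(lines, paste(sc, r$start, r$end,
                            sprintf("%.15g", r$value), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#' @param path file path.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0L) return(coverage_track(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("parse error in ", path, ": expected 4 bedGraph columns")
  df <- data.frame(scaffold = vapply(fields, `[`, "", 1L),
                   start = as.integer(vapply(fields, `[`, "", 2L)),
                   end = as.integer(vapply(fields, `[`, "", 3L)),
                   value = as.numeric(vapply(fields, `[`, "", 4L)),
                   stringsAsFactors = FALSE)
  coverage_track(split(df[c("start", "end", "value")], df$scaffold))
}

#' Read a count table (genes x samples)
#'
#' Tab-separated with a header line; first column gene_id, one column per
#' sample.
#'
#' @param path file path.
#' @return numeric matrix with gene_id rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a count table
#' @param m numeric matrix with gene_id rownames.
#' @param path output path.
#' @param id_col name of the leading identifier column.
#' @export
write_counts <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
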