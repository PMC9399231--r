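## Readers/writers for the plain-text formats the pipeline touches:
## BED3/BED6, ENCODE narrowPeak, BEDPE, TSV count matrices, gene tables
## (TSV or GTF-lite), SNP tables, JASPAR-like PWM text, contact triplets,
## FASTA (via Biostrings). All tab-separated; '#' comment lines ignored.

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(x) strsplit(x, "\t", fixed = TRUE)

#' Read a count matrix from TSV
#'
#' The first column holds feature identifiers, the header row holds sample
#' names. Sample conditions are taken from `conditions` when given, else
#' inferred from the sample-name prefix before the last underscore
#' (e.g. `LSS_1` -> `LSS`).
#'
#' @param path TSV file.
#' @param conditions Optional named character vector, sample -> condition.
#' @return A [count_matrix] object.
#' @export
read_counts <- function(path, conditions = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count TSV needs a feature column plus samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (is.null(conditions)) {
    conditions <- sub("_[^_]*$", "", colnames(m))
    names(conditions) <- colnames(m)
  }
  count_matrix(m, conditions)
}

#' Construct a count matrix with sample conditions
#'
#' A light S3 container for replicate counts: a non-negative
#' features x samples matrix plus a sample -> condition map.
#'
#' @param counts Numeric matrix with rownames (unique feature ids) and
#'   colnames (sample ids); entries must be non-negative.
#' @param condition Named character vector mapping every sample id to its
#'   condition label (e.g. "LSS" or "ST").
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  condition <- condition[colnames(counts)]
  if (anyNA(condition))
    stop("every sample needs a condition label")
  structure(list(counts = counts,
                 condition = stats::setNames(as.character(condition),
                                             colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$condition)),
                            as.integer(table(x$condition))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix to TSV
#' @param m A [count_matrix].
#' @param path Output path.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peaks from BED or narrowPeak
#'
#' BED3/BED6: `summit_offset` defaults to the interval midpoint and
#' `signal` to BED column 5 (score) when present, else 0. narrowPeak
#' (10 columns): `signal` is column 7 (signalValue) and `summit_offset`
#' column 10 (-1 meaning midpoint).
#'
#' @param path Input file.
#' @param format One of "auto", "bed", "narrowPeak"; "auto" decides by
#'   extension and column count.
#' @return Peak data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `summit_offset`.
#' @export
read_regions <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  tl <- read_tsv_lines(path)
  if (!length(tl$lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      signal = numeric(), summit_offset = integer(),
                      stringsAsFactors = FALSE))
  fields <- split_fields(tl$lines)
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (grepl("narrowPeak$", path) || all(ncols == 10L))
      "narrowPeak" else "bed"
  }
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(ncols < need)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s (%d field(s), need >= %d)",
                 format, tl$lineno[bad[1L]], path, ncols[bad[1L]], need))
  f <- function(i, default = NA) {
    vapply(fields, function(x) if (length(x) >= i) x[i] else
      as.character(default), character(1))
  }
  chrom <- f(1); start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop(sprintf("invalid coordinates at line %d of %s",
                 tl$lineno[bad[1L]], path))
  name <- f(4, default = "")
  name[!nzchar(name) | name == "NA"] <- paste0("region_",
    which(!nzchar(name) | name == "NA"))
  score <- suppressWarnings(as.numeric(f(5, default = "0")))
  score[is.na(score)] <- 0
  strand <- f(6, default = ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  if (format == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(f(7)))
    summit <- suppressWarnings(as.integer(f(10)))
    if (anyNA(signal) || anyNA(summit))
      stop("malformed narrowPeak numeric fields in ", path)
    summit[summit < 0L] <- ((end - start) %/% 2L)[summit < 0L]
  } else {
    signal <- score
    summit <- (end - start) %/% 2L
  }
  if (any(summit >= end - start))
    stop("narrowPeak summit offset outside peak in ", path)
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = strand, signal = signal,
             summit_offset = summit, stringsAsFactors = FALSE)
}

#' Write peaks as BED6 or narrowPeak
#'
#' Output is sorted by (chrom, start, end) for stability.
#'
#' @param peaks Peak data frame (see [read_regions]).
#' @param path Output path.
#' @param format "bed" or "narrowPeak".
#' @export
write_regions <- function(peaks, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  o <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[o, , drop = FALSE]
  name <- if ("name" %in% names(p)) p$name else paste0("region_", seq_len(nrow(p)))
  score <- if ("score" %in% names(p)) p$score else 0
  strand <- if ("strand" %in% names(p)) p$strand else "."
  if (format == "bed") {
    df <- data.frame(p$chrom, p$start, p$end, name, score, strand)
  } else {
    signal <- if ("signal" %in% names(p)) p$signal else 0
    summit <- if ("summit_offset" %in% names(p)) p$summit_offset else
      (p$end - p$start) %/% 2L
    df <- data.frame(p$chrom, p$start, p$end, name, score, strand,
                     signal, -1, -1, summit)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired anchors from BEDPE
#'
#' @param path BEDPE file (>= 6 columns); column 7 is kept as `name` and
#'   column 8 as a numeric `score` when present.
#' @return Data frame `chrom1,start1,end1,chrom2,start2,end2,name,score`.
#' @export
read_loops <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines))
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  fields <- split_fields(tl$lines)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d in %s", tl$lineno[bad[1L]], path))
  g <- function(i, default = NA_character_)
    vapply(fields, function(x) if (length(x) >= i) x[i] else default,
           character(1))
  df <- data.frame(chrom1 = g(1),
                   start1 = as.integer(g(2)), end1 = as.integer(g(3)),
                   chrom2 = g(4),
                   start2 = as.integer(g(5)), end2 = as.integer(g(6)),
                   name = g(7, "."),
                   score = suppressWarnings(as.numeric(g(8, "0"))),
                   stringsAsFactors = FALSE)
  df$score[is.na(df$score)] <- 0
  if (any(df$start1 >= df$end1 | df$start2 >= df$end2, na.rm = TRUE) ||
      anyNA(df[, c("start1", "end1", "start2", "end2")]))
    stop("invalid BEDPE coordinates in ", path)
  df
}

#' Write paired anchors as BEDPE
#' @param loops Data frame as returned by [read_loops].
#' @param path Output path.
#' @export
write_loops <- function(loops, path) {
  name <- if ("name" %in% names(loops)) loops$name else "."
  score <- if ("score" %in% names(loops)) loops$score else 0
  df <- data.frame(loops$chrom1, loops$start1, loops$end1,
                   loops$chrom2, loops$start2, loops$end2, name, score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Accepts either a 6-column TSV with header
#' `gene_id, symbol, chrom, start, end, strand` (0-based half-open), or
#' GTF-lite `gene` feature lines whose 1-based inclusive coordinates are
#' converted to 0-based half-open (`start - 1`, `end`). GTF gene ids are
#' parsed from the `gene_id "..."` attribute.
#'
#' @param path Input file; GTF assumed for `.gtf` extensions or 9-field
#'   lines with a `gene` feature column.
#' @return Gene data frame `gene_id, symbol, chrom, start, end, strand`.
#' @export
read_genes <- function(path) {
  tl <- read_tsv_lines(path)
  is_gtf <- grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)
  if (!is_gtf && length(tl$lines)) {
    fx <- split_fields(tl$lines[1L])[[1L]]
    is_gtf <- length(fx) == 9L && fx[3L] %in% c("gene", "transcript", "exon")
  }
  if (is_gtf) {
    fields <- split_fields(tl$lines)
    keep <- vapply(fields, function(x) length(x) == 9L && x[3L] == "gene",
                   logical(1))
    fields <- fields[keep]
    if (!length(fields)) stop("no gene features in GTF ", path)
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
      if (length(m)) sub(paste0(key, ' "([^"]*)"'), "\\1", m) else NA_character_
    }
    genes <- data.frame(
      gene_id = vapply(fields, function(x) attr_get(x[9L], "gene_id"),
                       character(1)),
      symbol = vapply(fields, function(x) {
        s <- attr_get(x[9L], "gene_name")
        if (is.na(s)) attr_get(x[9L], "gene_id") else s
      }, character(1)),
      chrom = vapply(fields, `[`, character(1), 1L),
      start = vapply(fields, function(x) as.integer(x[4L]) - 1L, integer(1)),
      end = vapply(fields, function(x) as.integer(x[5L]), integer(1)),
      strand = vapply(fields, `[`, character(1), 7L),
      stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
    if (!all(need %in% names(genes)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    genes <- genes[, need]
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in ", path)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' in ", path)
  validate_intervals(genes)
  genes
}

#' Write a gene table as 6-column TSV
#' @param genes Gene data frame.
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(
    genes[, c("gene_id", "symbol", "chrom", "start", "end", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table (TSV: rsid, chrom, pos; 0-based position)
#' @param path Input TSV with header.
#' @return Data frame `rsid, chrom, pos`.
#' @export
read_snps <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("rsid", "chrom", "pos") %in% names(df)))
    stop("SNP TSV must have columns rsid, chrom, pos")
  if (any(df$pos < 0)) stop("SNP positions must be >= 0")
  df[, c("rsid", "chrom", "pos")]
}

#' @rdname read_snps
#' @param snps SNP data frame.
#' @export
write_snps <- function(snps, path) {
  utils::write.table(snps[, c("rsid", "chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position probability matrix
#'
#' JASPAR-like text: an optional `>name` header line followed by four
#' rows (A, C, G, T) of tab- or space-separated values, either
#' probabilities or counts; columns are normalised to sum to 1.
#'
#' @param path PWM file.
#' @return An object of class `pwm`: list with `name` and a 4 x L `probs`
#'   matrix with rownames A,C,G,T.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- tools::file_path_sans_ext(basename(path))
  if (startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("PWM file needs 4 base rows: ", path)
  rows <- lapply(lines[1:4], function(l) {
    parts <- strsplit(trimws(l), "[\t ]+")[[1L]]
    if (toupper(parts[1L]) %in% c("A", "C", "G", "T"))
      parts <- parts[-1L]
    as.numeric(parts)
  })
  L <- unique(lengths(rows))
  if (length(L) != 1L) stop("PWM rows have unequal lengths: ", path)
  m <- do.call(rbind, rows)
  rownames(m) <- c("A", "C", "G", "T")
  new_pwm(name, m)
}

#' Construct a PWM object
#' @param name Motif name.
#' @param probs 4 x L numeric matrix (rows A,C,G,T) of probabilities or
#'   counts; columns are normalised to sum to 1.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(name, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("PWM needs 4 rows (A,C,G,T)")
  if (ncol(probs) < 4L) stop("PWM length must be >= 4")
  if (any(probs < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(probs)
  if (any(cs <= 0)) stop("PWM has an all-zero column")
  probs <- sweep(probs, 2L, cs, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, probs = probs), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (length %d), consensus %s\n", x$name,
              ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' @rdname read_pwm
#' @param pwm A `pwm` object.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pwm$name), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(paste(c(b, format(pwm$probs[b, ], digits = 6)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read contact records (TSV: bin1, bin2, count)
#'
#' Bin indices are integer bin numbers at a fixed resolution; an optional
#' `chrom` column is carried through when present.
#'
#' @param path Input TSV with header.
#' @return Data frame with columns `bin1, bin2, count` (+ `chrom`).
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("bin1", "bin2", "count") %in% names(df)))
    stop("contact TSV must have columns bin1, bin2, count")
  if (any(df$count < 0)) stop("contact counts must be non-negative")
  df
}

#' @rdname read_contacts
#' @param contacts Contact data frame.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings returning a named character vector,
#' which is the representation the motif-scanning functions take.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Warn about chromosome naming mismatches between two tables
#'
#' Chromosome names are compared as exact strings (no "chr" stripping);
#' this helper flags the likely configuration error instead of silently
#' renaming, and reports how many records share no chromosome.
#'
#' @param a,b Character vectors of chromosome names.
#' @param what Label used in the warning.
#' @return Invisibly, the chromosomes common to both.
#' @export
check_chrom_compat <- function(a, b, what = "inputs") {
  ca <- unique(a); cb <- unique(b)
  common <- intersect(ca, cb)
  if (length(ca) && length(cb) && !length(common)) {
    warning(sprintf(
      "no shared chromosome names between %s (e.g. '%s' vs '%s'); %d and %d records would be dropped",
      what, ca[1L], cb[1L], length(a), length(b)))
  }
  invisible(common)
}
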