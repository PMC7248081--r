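# Input handling: reference genome (FASTA), interval sets (BED3), bisulfite
# methylation calls (TSV) and the derived per-CpG methylation map.
#
# Coordinate convention: all positions are 1-based and intervals are
# closed [start, end], the Bioconductor convention. BED input (0-based
# half-open) is converted on read; interval identifiers keep the original
# BED coordinates so they remain stable across tools.

#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzip-compressed) FASTA file into a
#' \code{DNAStringSet}. Sequences are upper-cased; contig names are the
#' first whitespace-delimited token of each header and must be unique.
#' IUPAC ambiguity codes other than N are rejected by default, or mapped
#' to N with \code{ambiguity = "mask"}.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @param ambiguity \code{"error"} to reject ambiguity codes other than N,
#'   \code{"mask"} to convert them to N.
#' @return a \code{Biostrings::DNAStringSet} over the alphabet A,C,G,T,N.
#' @export
load_genome <- function(path, ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) cs_input_error(sprintf("genome FASTA not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) cs_format_error(sprintf("empty FASTA: %s", path))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    cs_format_error(sprintf("duplicate contig name(s) in %s: %s", path,
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  names(seqs) <- nm
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  freq <- Biostrings::alphabetFrequency(seqs)
  bad <- colnames(freq)[colSums(freq) > 0 & !colnames(freq) %in% c("A", "C", "G", "T", "N")]
  if (length(bad)) {
    if (ambiguity == "error") {
      # locate the first offending base for the error message
      for (i in seq_along(seqs)) {
        s <- as.character(seqs[[i]])
        hit <- regexpr(sprintf("[%s]", paste(bad, collapse = "")), s)
        if (hit > 0)
          cs_format_error(sprintf(
            "illegal character '%s' in contig %s at position %d (use ambiguity = \"mask\" to convert to N)",
            substr(s, hit, hit), nm[i], as.integer(hit)))
      }
    } else {
      chars <- as.character(seqs)
      chars <- chartr(paste(bad, collapse = ""), strrep("N", length(bad)), chars)
      seqs <- Biostrings::DNAStringSet(chars)
      names(seqs) <- nm
    }
  }
  seqs
}

#' Load genomic intervals from BED
#'
#' Reads a BED3(+) file and validates each interval against the genome.
#' Intervals are returned as a \code{GRanges} (1-based, closed); names are
#' stable identifiers \code{"contig:start-end"} in the original 0-based
#' BED coordinates. Mask-type interval sets should be loaded with
#' \code{merge = TRUE}, which unions overlapping or adjacent intervals;
#' island sets keep input order and stay distinct.
#'
#' @param path path to a BED file (plain or gzipped).
#' @param genome a \code{DNAStringSet} used to validate contig names and
#'   bounds; \code{NULL} skips bounds validation.
#' @param merge union overlapping intervals (mask semantics).
#' @return a \code{GenomicRanges::GRanges}.
#' @export
load_intervals <- function(path, genome = NULL, merge = FALSE) {
  if (!file.exists(path)) cs_input_error(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) cs_format_error(sprintf("empty BED: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (ln in seq_along(fields)) {
    f <- fields[[ln]]
    if (length(f) < 3L)
      cs_format_error(sprintf("%s line %d: fewer than 3 BED fields", path, ln))
    s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      cs_format_error(sprintf("%s line %d: non-integer coordinates", path, ln))
    if (s < 0L)
      cs_format_error(sprintf("%s line %d: negative start %d", path, ln, s))
    if (s >= e)
      cs_format_error(sprintf("%s line %d: empty or inverted interval [%d, %d)", path, ln, s, e))
    if (!is.null(genome)) {
      ctg <- f[1L]
      if (!ctg %in% names(genome))
        cs_format_error(sprintf("%s line %d: contig '%s' absent from genome", path, ln, ctg))
      if (e > Biostrings::width(genome)[match(ctg, names(genome))])
        cs_format_error(sprintf("%s line %d: end %d beyond contig '%s' length", path, ln, e, ctg))
    }
  }
  ctg <- vapply(fields, `[`, "", 1L)
  bs <- as.integer(vapply(fields, `[`, "", 2L))
  be <- as.integer(vapply(fields, `[`, "", 3L))
  gr <- GenomicRanges::GRanges(ctg, IRanges::IRanges(start = bs + 1L, end = be))
  names(gr) <- sprintf("%s:%d-%d", ctg, bs, be)
  if (merge) {
    gr <- GenomicRanges::reduce(gr)
    names(gr) <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  }
  gr
}

#' Load bisulfite methylation calls
#'
#' Reads per-CpG bisulfite call records from a tab-separated file. The
#' default dialect has four columns: contig, 1-based position of the C of
#' the CpG on the forward strand, read coverage, and methylated-read
#' count. Other dialects are adapted with \code{columns}, a named integer
#' vector mapping the required fields to column indices.
#'
#' @param path TSV path (plain or gzipped); lines starting with '#' are
#'   skipped.
#' @param columns named integer vector with entries \code{contig},
#'   \code{position}, \code{coverage}, \code{methylated}.
#' @param genome optional \code{DNAStringSet}; when supplied, each call is
#'   checked to sit on a CpG (C at position, G at position + 1).
#' @param validate \code{"error"}, \code{"warn"} or \code{"none"}: what to
#'   do when a call does not sit on a CpG of the genome.
#' @return data.frame with columns contig, position, coverage,
#'   methylated_count.
#' @export
load_methylation_calls <- function(path,
                                   columns = c(contig = 1L, position = 2L,
                                               coverage = 3L, methylated = 4L),
                                   genome = NULL,
                                   validate = c("error", "warn", "none")) {
  validate <- match.arg(validate)
  req <- c("contig", "position", "coverage", "methylated")
  if (!all(req %in% names(columns)))
    cs_input_error("'columns' must name contig, position, coverage, methylated")
  if (!file.exists(path)) cs_input_error(sprintf("methylation TSV not found: %s", path))
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) cs_format_error(sprintf("empty methylation TSV: %s", path))
  calls <- data.frame(
    contig = df[[columns[["contig"]]]],
    position = suppressWarnings(as.integer(df[[columns[["position"]]]])),
    coverage = suppressWarnings(as.integer(df[[columns[["coverage"]]]])),
    methylated_count = suppressWarnings(as.integer(df[[columns[["methylated"]]]])),
    stringsAsFactors = FALSE)
  bad <- which(is.na(calls$position) | is.na(calls$coverage) | is.na(calls$methylated_count))
  if (length(bad))
    cs_format_error(sprintf("%s line %d: non-integer field", path, bad[1L]))
  bad <- which(calls$position < 1L | calls$coverage < 0L |
                 calls$methylated_count < 0L | calls$methylated_count > calls$coverage)
  if (length(bad))
    cs_format_error(sprintf(
      "%s line %d: invalid call (position %d, coverage %d, methylated %d)",
      path, bad[1L], calls$position[bad[1L]], calls$coverage[bad[1L]],
      calls$methylated_count[bad[1L]]))
  if (!is.null(genome) && validate != "none")
    check_calls_on_cpg(calls, genome, action = validate)
  calls
}

# Verify that every call sits on a forward-strand CpG of the genome.
check_calls_on_cpg <- function(calls, genome, action = c("error", "warn")) {
  action <- match.arg(action)
  for (ctg in unique(calls$contig)) {
    if (!ctg %in% names(genome))
      cs_format_error(sprintf("methylation call on contig '%s' absent from genome", ctg))
    pos <- calls$position[calls$contig == ctg]
    len <- Biostrings::width(genome)[match(ctg, names(genome))]
    out <- pos >= len  # need position + 1 for the G
    s <- as.character(genome[[ctg]])
    okC <- !out & substring(s, pos, pos) == "C"
    okG <- !out & substring(s, pos + 1L, pos + 1L) == "G"
    bad <- which(!(okC & okG))
    if (length(bad)) {
      msg <- sprintf("%d methylation call(s) on %s do not sit on a CpG (first at position %d)",
                     length(bad), ctg, pos[bad[1L]])
      if (action == "error") cs_format_error(msg) else warning(msg, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a methylation map from bisulfite calls
#'
#' Thresholds raw calls into per-CpG statuses. A CpG is only classified
#' when its coverage is strictly greater than \code{min_coverage}; it is
#' then METHYLATED when the methylated fraction exceeds
#' \code{concordance}, UNMETHYLATED when the unmethylated fraction exceeds
#' \code{concordance}, and UNKNOWN otherwise (intermediate ratios are
#' excluded from analysis). Defaults implement the more-than-10-reads,
#' more-than-90-percent rule.
#'
#' @param calls data.frame as returned by
#'   \code{\link{load_methylation_calls}}.
#' @param min_coverage coverage must be strictly greater than this.
#' @param concordance required majority fraction, in (0.5, 1].
#' @return a \code{methylation_map} object mapping (contig, position of
#'   the CpG's C) to METHYLATED / UNMETHYLATED / UNKNOWN; positions absent
#'   from the map are UNKNOWN.
#' @export
build_methylation_map <- function(calls, min_coverage = 10L, concordance = 0.9) {
  stopifnot(min_coverage >= 0, concordance > 0.5, concordance <= 1)
  key <- paste(calls$contig, calls$position)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    cov1 <- calls$coverage[first][match(key, key[first])]
    met1 <- calls$methylated_count[first][match(key, key[first])]
    if (any(calls$coverage != cov1 | calls$methylated_count != met1))
      cs_input_error("duplicate methylation call with conflicting counts")
    calls <- calls[first, , drop = FALSE]
  }
  frac <- calls$methylated_count / calls$coverage
  status <- rep.int(3L, nrow(calls))  # UNKNOWN
  deep <- calls$coverage > min_coverage
  status[deep & frac > concordance] <- 1L            # METHYLATED
  status[deep & (1 - frac) > concordance] <- 2L      # UNMETHYLATED
  new_methylation_map(calls$contig, calls$position, status,
                      params = list(min_coverage = min_coverage,
                                    concordance = concordance))
}

new_methylation_map <- function(contig, position, status, params = list()) {
  by_contig <- split(data.frame(position = position, status = status),
                     factor(contig, levels = unique(contig)))
  by_contig <- lapply(by_contig, function(d) {
    o <- order(d$position)
    list(position = d$position[o], status = d$status[o])
  })
  structure(list(by_contig = by_contig, params = params),
            class = "methylation_map")
}

#' @export
print.methylation_map <- function(x, ...) {
  n <- vapply(x$by_contig, function(d) length(d$position), 0L)
  st <- unlist(lapply(x$by_contig, `[[`, "status"), use.names = FALSE)
  cat(sprintf("methylation_map: %d CpG position(s) on %d contig(s)\n",
              sum(n), length(n)))
  tab <- tabulate(st, 3L)
  cat(sprintf("  METHYLATED %d, UNMETHYLATED %d, UNKNOWN %d\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Look up methylation statuses
#'
#' Vectorized status lookup; positions not present in the map are
#' UNKNOWN.
#'
#' @param map a \code{methylation_map}.
#' @param contig single contig name.
#' @param positions integer vector of 1-based C positions.
#' @return character vector of statuses.
#' @export
methylation_status <- function(map, contig, positions) {
  codes <- methylation_status_codes(map, contig, positions)
  METH_STATUSES[codes]
}

# integer codes: 1 METHYLATED, 2 UNMETHYLATED, 3 UNKNOWN
methylation_status_codes <- function(map, contig, positions) {
  d <- map$by_contig[[contig]]
  out <- rep.int(3L, length(positions))
  if (!is.null(d)) {
    idx <- match(positions, d$position)
    hit <- !is.na(idx)
    out[hit] <- d$status[idx[hit]]
  }
  out
}

#' Write / read a methylation map as TSV
#'
#' The on-disk dialect is three tab-separated columns: contig, 1-based
#' position of the CpG's C, status (METHYLATED / UNMETHYLATED / UNKNOWN),
#' preceded by '#'-prefixed header lines recording the thresholds used.
#' \code{read_methylation_map} round-trips this format exactly.
#'
#' @param map a \code{methylation_map}.
#' @param path output / input TSV path.
#' @return \code{write_methylation_map} returns \code{path} invisibly;
#'   \code{read_methylation_map} returns a \code{methylation_map}.
#' @export
write_methylation_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- map$params
  if (length(p))
    writeLines(sprintf("# %s=%s", names(p), unlist(p)), con)
  for (ctg in names(map$by_contig)) {
    d <- map$by_contig[[ctg]]
    writeLines(sprintf("%s\t%d\t%s", ctg, d$position, METH_STATUSES[d$status]), con)
  }
  invisible(path)
}

#' @rdname write_methylation_map
#' @export
read_methylation_map <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  params <- list()
  if (any(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    kv <- strsplit(kv, "=", fixed = TRUE)
    params <- lapply(kv, function(x) {
      v <- suppressWarnings(as.numeric(x[2L])); if (is.na(v)) x[2L] else v
    })
    names(params) <- vapply(kv, `[`, "", 1L)
  }
  f <- strsplit(lines[!hdr], "\t", fixed = TRUE)
  if (!length(f)) cs_format_error(sprintf("empty methylation map: %s", path))
  status <- match(vapply(f, `[`, "", 3L), METH_STATUSES)
  if (anyNA(status)) cs_format_error(sprintf("unrecognized status in %s", path))
  new_methylation_map(vapply(f, `[`, "", 1L),
                      as.integer(vapply(f, `[`, "", 2L)),
                      status, params = params)
}
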