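# Read-start extraction: turn an alignment stream into filtered 5'-end
# break events. The default policy reproduces `samtools view -f 35 -F 4`
# restricted to autosomes: paired, properly paired, mate-reverse reads on
# the forward strand, mapped, with the break coordinate taken as the
# leftmost aligned base.

#' Alignment filter policy
#'
#' Encodes which alignments contribute break events. Flag semantics
#' follow SAM: a record is kept when (flag AND required) == required and
#' (flag AND excluded) == 0. Defaults reproduce the forward-strand
#' autosome protocol (required 35 = paired + proper pair + mate reverse,
#' excluded 4 = unmapped; contigs 1-22 in both plain and "chr" naming).
#'
#' @param required_flag SAM flag bits that must all be set.
#' @param excluded_flag SAM flag bits that must all be clear.
#' @param contigs allowed contig names; events elsewhere are dropped.
#' @param min_mapq minimum mapping quality (default 0, i.e. no filter).
#' @param drop_duplicates drop reads with the PCR/optical duplicate flag.
#' @param max_leading_clip maximum allowed soft/hard clip at the 5' end of
#'   the alignment; clipped 5' ends hide the true fragment break, so the
#'   default 0 drops them.
#' @param strand \code{"forward"} (default protocol), \code{"reverse"}
#'   (5' end is the rightmost aligned base, dinucleotide read as the
#'   reverse complement), or \code{"both"}.
#' @return a \code{filter_policy} object.
#' @export
filter_policy <- function(required_flag = 35L, excluded_flag = 4L,
                          contigs = c(as.character(1:22), paste0("chr", 1:22)),
                          min_mapq = 0L, drop_duplicates = FALSE,
                          max_leading_clip = 0L,
                          strand = c("forward", "reverse", "both")) {
  strand <- match.arg(strand)
  required_flag <- as.integer(required_flag)
  excluded_flag <- as.integer(excluded_flag)
  if (drop_duplicates) excluded_flag <- bitwOr(excluded_flag, 1024L)
  if (bitwAnd(required_flag, excluded_flag) != 0L)
    cs_input_error("required and excluded flag bitmasks overlap")
  structure(list(required_flag = required_flag, excluded_flag = excluded_flag,
                 contigs = contigs, min_mapq = as.integer(min_mapq),
                 drop_duplicates = drop_duplicates,
                 max_leading_clip = as.integer(max_leading_clip),
                 strand = strand),
            class = "filter_policy")
}

#' Extract filtered read-start events
#'
#' Converts alignments into \code{ReadStartEvent} records: one row per
#' kept read with the 1-based coordinate of its aligned 5'-end base.
#' Input may be a SAM or BAM file, an event TSV (columns contig, 0-based
#' position, optional strand; an alignment-free source, no flag filtering
#' applied), or a data.frame of events (columns contig, position
#' [1-based], optional strand). Input order is preserved.
#'
#' For the forward strand the 5' end is the leftmost aligned base; in
#' reverse mode it is the rightmost. Events whose 5'-end position falls
#' inside a mask interval are dropped.
#'
#' @param source path to .sam/.bam/.tsv, or an event data.frame.
#' @param policy a \code{\link{filter_policy}}.
#' @param mask optional \code{GRanges} of masked regions (merged).
#' @param genome optional \code{DNAStringSet}; when given, event contigs
#'   must exist in it and positions are bounds-checked.
#' @param sample_id sample identifier attached to every event.
#' @return data.frame with columns contig, position, strand, sample_id.
#' @export
extract_read_starts <- function(source, policy = filter_policy(), mask = NULL,
                                genome = NULL, sample_id = "sample") {
  ev <- if (is.data.frame(source)) {
    data.frame(contig = as.character(source$contig),
               position = as.integer(source$position),
               strand = if ("strand" %in% names(source)) as.character(source$strand) else "+",
               stringsAsFactors = FALSE)
  } else if (grepl("\\.(sam|bam)$", source, ignore.case = TRUE)) {
    read_alignment_events(source, policy)
  } else {
    read_events_tsv(source)
  }

  keep <- ev$contig %in% policy$contigs
  keep <- keep & switch(policy$strand,
                        forward = ev$strand == "+",
                        reverse = ev$strand == "-",
                        both = TRUE)
  ev <- ev[keep, , drop = FALSE]

  if (!is.null(genome)) {
    miss <- setdiff(unique(ev$contig), names(genome))
    if (length(miss))
      cs_input_error(sprintf("event contig(s) absent from genome: %s",
                             paste(miss, collapse = ", ")))
    len <- Biostrings::width(genome)[match(ev$contig, names(genome))]
    ev <- ev[ev$position >= 1L & ev$position <= len, , drop = FALSE]
  }

  if (!is.null(mask) && nrow(ev)) {
    pts <- GenomicRanges::GRanges(ev$contig,
                                  IRanges::IRanges(ev$position, width = 1L))
    hit <- GenomicRanges::countOverlaps(pts, mask) > 0L
    ev <- ev[!hit, , drop = FALSE]
  }

  ev$sample_id <- sample_id
  rownames(ev) <- NULL
  ev
}

# SAM/BAM -> events applying flag / mapq / clip filters. SAM input is
# converted with Rsamtools; positions come back 1-based.
read_alignment_events <- function(path, policy) {
  if (!file.exists(path)) cs_input_error(sprintf("alignment file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "mapq", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- rec$flag
  keep <- bitwAnd(flag, policy$required_flag) == policy$required_flag &
    bitwAnd(flag, policy$excluded_flag) == 0L &
    !is.na(rec$pos)
  mq <- rec$mapq
  mq[is.na(mq)] <- 255L  # SAM: 255 means unavailable; do not filter on it
  keep <- keep & mq >= policy$min_mapq
  rev <- bitwAnd(flag, 16L) == 16L
  cig <- rec$cigar
  lead_clip <- clip_length(cig, leading = !rev)  # clip at the 5' end
  keep <- keep & !is.na(lead_clip) & lead_clip <= policy$max_leading_clip
  pos5 <- ifelse(rev,
                 rec$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(cig) - 1L,
                 rec$pos)
  data.frame(contig = as.character(rec$rname)[keep],
             position = as.integer(pos5)[keep],
             strand = ifelse(rev, "-", "+")[keep],
             stringsAsFactors = FALSE)
}

# length of the soft/hard clip at the leading (or trailing) alignment edge
clip_length <- function(cigar, leading = TRUE) {
  leading <- rep_len(leading, length(cigar))
  lead_n <- trail_n <- integer(length(cigar))
  has <- !is.na(cigar) & grepl("^[0-9]+[SH]", cigar)
  lead_n[has] <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cigar[has]))
  has <- !is.na(cigar) & grepl("[0-9]+[SH]$", cigar)
  trail_n[has] <- as.integer(sub("^.*?([0-9]+)[SH]$", "\\1", cigar[has], perl = TRUE))
  out <- ifelse(leading, lead_n, trail_n)
  out[is.na(cigar) | cigar == "*"] <- NA_integer_
  out
}

#' Read / write the plain event TSV dialect
#'
#' Two or three tab-separated columns: contig, 0-based 5'-end position,
#' optional strand (+/-, default +). This alignment-free dialect lets
#' break coordinates be exchanged without sequence-level data.
#'
#' @param path TSV path (plain or gzipped).
#' @param events event data.frame (internal 1-based positions).
#' @return \code{read_events_tsv}: event data.frame with 1-based
#'   positions; \code{write_events_tsv}: \code{path}, invisibly.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) cs_input_error(sprintf("event TSV not found: %s", path))
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) cs_format_error(sprintf("%s: expected >= 2 columns", path))
  pos <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(pos)) cs_format_error(sprintf("%s line %d: non-integer position",
                                          path, which(is.na(pos))[1L]))
  if (any(pos < 0L)) cs_format_error(sprintf("%s line %d: negative position",
                                             path, which(pos < 0L)[1L]))
  data.frame(contig = df[[1L]], position = pos + 1L,
             strand = if (ncol(df) >= 3L) df[[3L]] else "+",
             stringsAsFactors = FALSE)
}

#' @rdname read_events_tsv
#' @export
write_events_tsv <- function(events, path) {
  df <- data.frame(events$contig, events$position - 1L,
                   if ("strand" %in% names(events)) events$strand else "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count break events
#'
#' The sample-level total N: the number of filtered read-start events.
#'
#' @param events event data.frame.
#' @return integer count.
#' @export
count_events <- function(events) nrow(events)
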