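# Cleavage-rate computation. For each dinucleotide class XY the cleavage
# rate is
#
#     r(XY) = n(XY) / (N * p(XY))
#
# where n(XY) counts reads whose 5'-end base is the Y of an XY pair in
# the reference, N is the number of usable reads, and p(XY) is the
# fraction of XY among the overlapping dinucleotides of the 200-bp
# genomic windows around the read starts. The local window normalizes
# away composition and mappability bias; r = 1 means breaks occur at XY
# no more and no less often than expected from local sequence content.
#
# With a methylation map the CG class is split into CmG / CuG / CxG
# (methylated / unmethylated / undetermined cytosine), 18 labels in all.
# Undetermined CpGs (CxG) are tallied for audit but excluded from the
# background and from N, mirroring their exclusion from analysis.

# revcomp lookup over base codes A=1,C=2,G=3,T=4
RC_BASE <- c(4L, 3L, 2L, 1L)

# map a plain-16 class code to its 18-label code (CG handled separately)
MAP16TO18 <- c(1L, 2L, 3L, 4L, 5L, 6L, NA, 10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L)

revcomp_map <- function(annotated) {
  labels <- if (annotated) CLASSES18 else DINUC16
  vapply(labels, function(l) {
    if (l %in% c("CmG", "CuG", "CxG")) return(match(l, labels))
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(l, "")[[1L]]), collapse = ""))
    if (annotated && rc == "CG") rc <- l  # cannot occur: CG revcomps to CG
    match(rc, labels)
  }, 0L, USE.NAMES = FALSE)
}

# base codes for one contig: A=1, C=2, G=3, T=4, anything else 0
contig_base_codes <- function(genome, contig) {
  s <- as.character(genome[[contig]])
  lut <- integer(256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[as.integer(charToRaw(s))]
}

# Dinucleotide class code at every start position j (pair = bases j, j+1),
# length L - 1. 0 = uninformative (N or masked base). Plain mode: codes
# into DINUC16; annotated mode: codes into CLASSES18 with CG split by the
# methylation status of the C.
class_code_vector <- function(genome, contig, methylmap = NULL, mask = NULL) {
  b <- contig_base_codes(genome, contig)
  L <- length(b)
  if (L < 2L) return(integer(0L))
  b1 <- b[-L]; b2 <- b[-1L]
  cc <- (b1 - 1L) * 4L + b2
  cc[b1 == 0L | b2 == 0L] <- 0L
  if (!is.null(mask)) {
    m <- mask[as.character(GenomicRanges::seqnames(mask)) == contig]
    if (length(m)) {
      masked <- logical(L)
      st <- pmax(GenomicRanges::start(m), 1L); en <- pmin(GenomicRanges::end(m), L)
      for (k in seq_along(st)) masked[st[k]:en[k]] <- TRUE
      cc[masked[-L] | masked[-1L]] <- 0L
    }
  }
  if (!is.null(methylmap)) {
    is_cg <- cc == 7L
    new <- integer(length(cc))
    nz <- cc > 0L & !is_cg
    new[nz] <- MAP16TO18[cc[nz]]
    if (any(is_cg)) {
      pos <- which(is_cg)
      new[pos] <- 6L + methylation_status_codes(methylmap, contig, pos)
    }
    cc <- new
  }
  cc
}

#' Classify break sites by reference dinucleotide
#'
#' For each event the class is read from the reference pair ending at the
#' 5'-end base: bases (i - 1, i) for a forward event at position i.
#' Reverse-strand events are classified by the reverse complement of the
#' pair (i, i + 1). With a methylation map, CG is split into CmG / CuG /
#' CxG by the status of its C. \code{"DISCARD"} is returned when there is
#' no preceding base, when either base is N, or when either base is
#' masked.
#'
#' @param genome \code{DNAStringSet}.
#' @param events event data.frame (contig, position, strand).
#' @param methylmap optional \code{methylation_map}; enables the 18-class
#'   alphabet.
#' @param mask optional merged \code{GRanges} mask.
#' @return character vector: a class label or \code{"DISCARD"} per event.
#' @export
classify_break_sites <- function(genome, events, methylmap = NULL, mask = NULL) {
  annotated <- !is.null(methylmap)
  labels <- dinucleotide_classes(annotated)
  rcmap <- revcomp_map(annotated)
  out <- character(nrow(events))
  strand <- if ("strand" %in% names(events)) events$strand else rep("+", nrow(events))
  for (ctg in unique(events$contig)) {
    if (!ctg %in% names(genome))
      cs_input_error(sprintf("event contig '%s' absent from genome", ctg))
    sel <- events$contig == ctg
    cc <- class_code_vector(genome, ctg, methylmap, mask)
    i <- events$position[sel]
    fwd <- strand[sel] == "+"
    j <- ifelse(fwd, i - 1L, i)
    code <- integer(length(j))
    ok <- j >= 1L & j <= length(cc)
    code[ok] <- cc[j[ok]]
    code[!fwd & code > 0L] <- rcmap[code[!fwd & code > 0L]]
    out[sel] <- ifelse(code == 0L, "DISCARD", labels[pmax(code, 1L)])
  }
  out
}

# Shared engine: per-class break counts and pooled window tallies.
# Returns list(n, counts, informative, excluded, n_windows, truncated,
# discarded, N) with n and counts indexed by class code.
rate_engine <- function(genome, events, methylmap = NULL, mask = NULL,
                        half_width = 100L,
                        p_mode = c("pooled", "per_window_mean")) {
  p_mode <- match.arg(p_mode)
  if (half_width < 1L) cs_input_error("half_width must be >= 1")
  annotated <- !is.null(methylmap)
  K <- if (annotated) 18L else 16L
  cx <- if (annotated) 9L else -1L  # CxG code: audited but uninformative
  rcmap <- revcomp_map(annotated)
  h <- as.integer(half_width)
  if (2L * h > max(Biostrings::width(genome)))
    cs_input_error("background window wider than every contig")
  strand <- if ("strand" %in% names(events)) events$strand else rep("+", nrow(events))

  n <- numeric(K); counts <- numeric(K); frac_sums <- numeric(K)
  truncated <- 0L; discarded <- 0L; windows_total <- 0L; excluded_bg <- 0

  for (ctg in unique(events$contig)) {
    if (!ctg %in% names(genome))
      cs_input_error(sprintf("event contig '%s' absent from genome", ctg))
    cc <- class_code_vector(genome, ctg, methylmap, mask)
    L <- length(cc) + 1L
    sel <- which(events$contig == ctg)
    i <- events$position[sel]
    fwd <- strand[sel] == "+"
    full <- i - h >= 1L & i + h - 1L <= L
    truncated <- truncated + sum(!full)
    i <- i[full]; fwd <- fwd[full]
    if (!length(i)) next
    windows_total <- windows_total + length(i)

    # --- numerator: class of the break dinucleotide
    j <- ifelse(fwd, i - 1L, i)
    code <- integer(length(j))
    ok <- j >= 1L & j <= length(cc)
    code[ok] <- cc[j[ok]]
    code[!fwd & code > 0L] <- rcmap[code[!fwd & code > 0L]]
    discarded <- discarded + sum(code == 0L)
    n <- n + tabulate(code[code > 0L], K)

    # --- background: window coverage of every dinucleotide start.
    # cov[j] = number of (full) windows whose dinucleotide-start range
    # [i - h, i + h - 2] contains j; computed from the cumulative count
    # of event positions, O(L + E).
    for (pass in c(TRUE, FALSE)) {
      ii <- i[fwd == pass]
      if (!length(ii)) next
      Tpos <- tabulate(ii, L)
      S <- c(0, cumsum(Tpos))
      jj <- seq_len(length(cc))
      lo <- pmin(pmax(jj - h + 2L, 1L), L + 1L)
      hi <- pmin(jj + h, L)
      cov <- S[hi + 1L] - S[lo]
      wcounts <- numeric(K)
      for (k in seq_len(K)) wcounts[k] <- sum(cov[cc == k])
      if (!pass) wcounts <- wcounts[rcmap]  # reverse: revcomp classes
      counts <- counts + wcounts
      excluded_bg <- excluded_bg + sum(cov[cc == 0L])

      if (p_mode == "per_window_mean") {
        inform <- as.numeric(cc > 0L & cc != cx)
        Cinf <- c(0, cumsum(inform))
        lo_e <- ii - h; hi_e <- ii + h - 2L
        inf_e <- Cinf[hi_e + 1L] - Cinf[lo_e]
        for (k in seq_len(K)) {
          kk <- if (pass) k else rcmap[k]
          Ck <- c(0, cumsum(cc == kk))
          ct_e <- Ck[hi_e + 1L] - Ck[lo_e]
          frac_sums[k] <- frac_sums[k] + sum(ct_e[inf_e > 0] / inf_e[inf_e > 0])
        }
      }
    }
  }

  if (cx > 0L) excluded_bg <- excluded_bg + counts[cx]
  informative <- sum(counts) - (if (cx > 0L) counts[cx] else 0)
  if (p_mode == "pooled") {
    p <- if (informative > 0) counts / informative else rep(NA_real_, K)
  } else {
    p <- if (windows_total > 0) frac_sums / windows_total else rep(NA_real_, K)
  }
  if (cx > 0L) p[cx] <- 0
  usable <- sum(n) - (if (cx > 0L) n[cx] else 0)
  list(n = n, counts = counts, p = p, informative = informative,
       excluded_bg = excluded_bg, n_windows = windows_total,
       truncated = truncated, discarded = discarded, N = usable,
       K = K, annotated = annotated, p_mode = p_mode)
}

#' Per-class background fractions
#'
#' Computes p(XY): the fraction of XY among the overlapping dinucleotides
#' of the 2 x \code{half_width} bp genomic windows centered on the read
#' starts, pooled over all windows. Dinucleotides containing N, a masked
#' base, or (in annotated mode) an undetermined-status CpG are excluded
#' from the informative total. Events whose window is truncated by a
#' contig edge are skipped.
#'
#' @inheritParams classify_break_sites
#' @param half_width half window width in bases (default 100, i.e. the
#'   200-bp window).
#' @param p_mode \code{"pooled"} (sum of counts over all windows divided
#'   by the informative total; default) or \code{"per_window_mean"} (mean
#'   of per-window fractions; identical for full unmasked windows).
#' @return named numeric vector of p(XY) over the class alphabet, with
#'   attributes \code{counts}, \code{informative} and \code{n_windows}.
#' @export
accumulate_background <- function(genome, events, methylmap = NULL, mask = NULL,
                                  half_width = 100L,
                                  p_mode = c("pooled", "per_window_mean")) {
  eng <- rate_engine(genome, events, methylmap, mask, half_width, p_mode)
  p <- setNames(eng$p, dinucleotide_classes(eng$annotated))
  attr(p, "counts") <- setNames(eng$counts, names(p))
  attr(p, "informative") <- eng$informative
  attr(p, "n_windows") <- eng$n_windows
  p
}

#' Compute the cleavage-rate table
#'
#' The central statistic: for every dinucleotide class, the break count
#' n(XY), local background fraction p(XY), and cleavage rate
#' r(XY) = n(XY) / (N * p(XY)). With a methylation map the table has 18
#' classes (CG split into CmG / CuG / CxG); CxG breaks are reported for
#' audit but carry no rate (their background is excluded) and do not
#' enter N. Events with edge-truncated windows are excluded from both
#' numerator and background; events at N bases, masked bases or a contig
#' start are discarded and tallied.
#'
#' @inheritParams accumulate_background
#' @return a \code{cleavage_rate_table}: list with \code{table}
#'   (data.frame class, n, p, r), \code{N} (usable events), and audit
#'   fields \code{truncated}, \code{discarded}, \code{n_windows},
#'   \code{half_width}, \code{mode}.
#' @export
compute_cleavage_rates <- function(genome, events, methylmap = NULL, mask = NULL,
                                   half_width = 100L,
                                   p_mode = c("pooled", "per_window_mean")) {
  if (nrow(events) == 0L) cs_input_error("no events supplied")
  eng <- rate_engine(genome, events, methylmap, mask, half_width, p_mode)
  if (eng$N == 0L)
    cs_input_error("all events were discarded or truncated; no usable break events remain")
  labels <- dinucleotide_classes(eng$annotated)
  r <- ifelse(eng$p > 0, eng$n / (eng$N * eng$p), NA_real_)
  r[eng$n == 0 & eng$p > 0] <- 0
  structure(list(
    table = data.frame(class = labels, n = as.integer(eng$n), p = eng$p, r = r,
                       stringsAsFactors = FALSE),
    N = eng$N, n_classified = sum(eng$n), truncated = eng$truncated,
    discarded = eng$discarded, n_windows = eng$n_windows,
    excluded_background = eng$excluded_bg,
    half_width = as.integer(half_width),
    mode = if (eng$annotated) "annotated" else "plain",
    p_mode = eng$p_mode), class = "cleavage_rate_table")
}

#' @export
print.cleavage_rate_table <- function(x, ...) {
  cat(sprintf("cleavage_rate_table (%s mode): N = %d usable events, half-width %d bp\n",
              x$mode, x$N, x$half_width))
  cat(sprintf("  windows %d | truncated %d | discarded %d\n",
              x$n_windows, x$truncated, x$discarded))
  print(transform(x$table, p = signif(p, 4), r = signif(r, 4)), row.names = FALSE)
  invisible(x)
}

#' Island-restricted CpG cleavage rates
#'
#' Scores each CpG island by the cleavage-rate statistic restricted to
#' the island: n counts break events whose dinucleotide is CG (any
#' methylation status) and starts inside the island, p is the fraction of
#' CG among the informative dinucleotides of the island sequence itself,
#' and the rate is n / (N * p) with the sample-wide N so scores are
#' depth-comparable across samples. Islands with too few informative CG
#' positions or too little read support get a missing rate with a status
#' code.
#'
#' @inheritParams accumulate_background
#' @param islands \code{GRanges} of CpG islands (named; see
#'   \code{\link{load_intervals}}).
#' @param N sample-wide usable event count; defaults to
#'   \code{count_events(events)}.
#' @param min_cg minimum informative CG dinucleotide positions for a
#'   score (default 5).
#' @param min_support minimum events falling in the island (default 0).
#' @return data.frame: island_id, contig, start, end (0-based half-open,
#'   as in BED), n, p_island, rate, status.
#' @export
island_cleavage_rates <- function(genome, events, islands, N = count_events(events),
                                  mask = NULL, min_cg = 5L, min_support = 0L) {
  if (N <= 0L) cs_input_error("island scoring requires N > 0")
  ids <- names(islands)
  if (is.null(ids))
    ids <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(islands)),
                   GenomicRanges::start(islands) - 1L, GenomicRanges::end(islands))
  out <- data.frame(island_id = ids,
                    contig = as.character(GenomicRanges::seqnames(islands)),
                    start = GenomicRanges::start(islands) - 1L,
                    end = GenomicRanges::end(islands),
                    n = 0L, p_island = NA_real_, rate = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  strand <- if ("strand" %in% names(events)) events$strand else rep("+", nrow(events))
  for (ctg in unique(out$contig)) {
    if (!ctg %in% names(genome))
      cs_input_error(sprintf("island contig '%s' absent from genome", ctg))
    cc <- class_code_vector(genome, ctg, methylmap = NULL, mask = mask)
    sel_e <- events$contig == ctg
    i <- events$position[sel_e]
    jj <- ifelse(strand[sel_e] == "+", i - 1L, i)  # CG revcomps to CG
    jj <- jj[jj >= 1L & jj <= length(cc)]
    cg_breaks <- sort(jj[cc[jj] == 7L])
    pos_all <- sort(i)
    for (w in which(out$contig == ctg)) {
      s <- out$start[w] + 1L; e <- out$end[w]
      jr <- if (e - 1L >= s) seq.int(s, e - 1L) else integer(0L)  # dinucs fully inside
      jr <- jr[jr <= length(cc)]
      inform <- sum(cc[jr] > 0L)
      ncg <- sum(cc[jr] == 7L)
      nb <- sum(findInterval(c(s - 1L, e - 1L), cg_breaks) * c(-1L, 1L))
      support <- sum(findInterval(c(s - 1L, e), pos_all) * c(-1L, 1L))
      out$n[w] <- nb
      if (ncg == 0L) { out$status[w] <- "no_cg"; next }
      out$p_island[w] <- ncg / inform
      if (ncg < min_cg) { out$status[w] <- "low_cg"; next }
      if (support < min_support) { out$status[w] <- "low_support"; next }
      out$rate[w] <- nb / (N * out$p_island[w])
    }
  }
  out$rate[out$status != "ok"] <- NA_real_
  out
}

#' Write / read a cleavage-rate table as TSV
#'
#' Four columns (class, n, p, r) preceded by '#'-prefixed header lines
#' recording N, half-width, mode and exclusion tallies.
#'
#' @param x a \code{cleavage_rate_table}.
#' @param path TSV path.
#' @return \code{write_rate_table}: \code{path}, invisibly;
#'   \code{read_rate_table}: a \code{cleavage_rate_table}.
#' @export
write_rate_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(N = x$N, half_width = x$half_width, truncated = x$truncated,
            discarded = x$discarded, n_windows = x$n_windows)
  writeLines(c(sprintf("# %s=%s", names(meta), meta),
               sprintf("# mode=%s", x$mode), sprintf("# p_mode=%s", x$p_mode)), con)
  writeLines("class\tn\tp\tr", con)
  writeLines(sprintf("%s\t%d\t%.10g\t%s", x$table$class, x$table$n, x$table$p,
                     ifelse(is.na(x$table$r), "NA", sprintf("%.10g", x$table$r))), con)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  structure(list(table = df, N = as.integer(meta[["N"]]),
                 n_classified = sum(df$n),
                 truncated = as.integer(meta[["truncated"]]),
                 discarded = as.integer(meta[["discarded"]]),
                 n_windows = as.integer(meta[["n_windows"]]),
                 excluded_background = NA_real_,
                 half_width = as.integer(meta[["half_width"]]),
                 mode = meta[["mode"]], p_mode = meta[["p_mode"]]),
            class = "cleavage_rate_table")
}

#' Write island scores as TSV
#'
#' @param scores data.frame from \code{\link{island_cleavage_rates}}.
#' @param path TSV path.
#' @param N sample-wide event count recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_island_scores <- function(scores, path, N = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%s", N), con)
  writeLines(paste(colnames(scores), collapse = "\t"), con)
  body <- apply(scores, 1L, function(row) paste(row, collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read island scores written by \code{\link{write_island_scores}}
#' @param path TSV path.
#' @return list with \code{scores} (data.frame) and \code{N}.
#' @export
read_island_scores <- function(path) {
  lines <- readLines(path)
  N <- suppressWarnings(as.numeric(sub("^# N=", "", lines[grepl("^# N=", lines)][1L])))
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  list(scores = df, N = N)
}
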