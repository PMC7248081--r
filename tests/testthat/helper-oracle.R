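# Independent brute-force oracle for the cleavage-rate statistic: an
# explicit per-event recount over every window position, working on raw
# character vectors and a plain status table. It shares no code with the
# streaming implementation.

# status_df: data.frame(contig, position, status) or NULL for plain mode
naive_rates <- function(genome, events, status_df = NULL, mask = NULL,
                        half_width = 100L) {
  annotated <- !is.null(status_df)
  labels <- if (annotated)
    c("AA", "AC", "AG", "AT", "CA", "CC", "CmG", "CuG", "CxG", "CT",
      "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  else
    c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
      "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  h <- as.integer(half_width)
  n <- setNames(numeric(length(labels)), labels)
  tally <- setNames(numeric(length(labels)), labels)
  informative_total <- 0
  truncated <- 0L; discarded <- 0L

  chars_by_contig <- lapply(names(genome), function(ctg)
    strsplit(as.character(genome[[ctg]]), "")[[1L]])
  names(chars_by_contig) <- names(genome)
  masked_by_contig <- lapply(names(genome), function(ctg) {
    v <- logical(length(chars_by_contig[[ctg]]))
    if (!is.null(mask)) {
      m <- mask[as.character(GenomicRanges::seqnames(mask)) == ctg]
      for (k in seq_along(m))
        v[GenomicRanges::start(m)[k]:GenomicRanges::end(m)[k]] <- TRUE
    }
    v
  })
  names(masked_by_contig) <- names(genome)
  status_key <- if (annotated)
    setNames(status_df$status, paste(status_df$contig, status_df$position))

  label_at <- function(ctg, j) {
    # class labels of dinucleotides starting at positions j (vectorized)
    ch <- chars_by_contig[[ctg]]; mk <- masked_by_contig[[ctg]]
    a <- ch[j]; b <- ch[j + 1L]
    lab <- paste0(a, b)
    bad <- !(a %in% c("A", "C", "G", "T")) | !(b %in% c("A", "C", "G", "T")) |
      mk[j] | mk[j + 1L]
    if (annotated) {
      cg <- lab == "CG" & !bad
      if (any(cg)) {
        st <- status_key[paste(ctg, j[cg])]
        st[is.na(st)] <- "UNKNOWN"
        lab[cg] <- c(METHYLATED = "CmG", UNMETHYLATED = "CuG",
                     UNKNOWN = "CxG")[st]
      }
    }
    lab[bad] <- NA_character_
    lab
  }

  for (e in seq_len(nrow(events))) {
    ctg <- events$contig[e]; i <- events$position[e]
    L <- length(chars_by_contig[[ctg]])
    if (i - h < 1L || i + h - 1L > L) { truncated <- truncated + 1L; next }
    brk <- if (i >= 2L) label_at(ctg, i - 1L) else NA_character_
    if (is.na(brk)) discarded <- discarded + 1L else n[brk] <- n[brk] + 1
    win <- label_at(ctg, (i - h):(i + h - 2L))
    for (lab in win[!is.na(win)]) tally[lab] <- tally[lab] + 1
  }
  informative_total <- sum(tally) - if (annotated) tally[["CxG"]] else 0
  p <- tally / informative_total
  if (annotated) p[["CxG"]] <- 0
  N <- sum(n) - if (annotated) n[["CxG"]] else 0
  r <- ifelse(p > 0, n / (N * p), NA_real_)
  list(n = n, p = p, r = r, N = N, truncated = truncated, discarded = discarded)
}

# brute-force island score: n CG breaks in the island / (N * CG fraction)
naive_island_rate <- function(genome, events, contig, start1, end1, N) {
  ch <- strsplit(as.character(genome[[contig]]), "")[[1L]]
  js <- start1:(end1 - 1L)
  pairs <- paste0(ch[js], ch[js + 1L])
  informative <- sum(ch[js] %in% c("A", "C", "G", "T") &
                       ch[js + 1L] %in% c("A", "C", "G", "T"))
  ncg <- sum(pairs == "CG")
  nb <- 0L
  for (e in seq_len(nrow(events))) {
    if (events$contig[e] != contig) next
    j <- events$position[e] - 1L
    if (j >= start1 && j <= end1 - 1L && j >= 1L &&
        paste0(ch[j], ch[j + 1L]) == "CG") nb <- nb + 1L
  }
  list(n = nb, p = ncg / informative, rate = nb / (N * ncg / informative))
}
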