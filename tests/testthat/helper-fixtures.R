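# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# random i.i.d. genome as a DNAStringSet with one contig
random_genome <- function(len, seed, contig = "c1",
                          comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  set.seed(seed)
  make_genome(setNames(paste(sample(names(comp), len, replace = TRUE, prob = comp),
                             collapse = ""), contig))
}

# events data.frame from 1-based positions
events_at <- function(positions, contig = "c1", strand = "+") {
  n <- length(positions)
  data.frame(contig = rep_len(contig, n), position = as.integer(positions),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

write_fasta <- function(genome, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(genome, path)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# minimal valid SAM file; records = list of c(qname, flag, rname, pos,
# mapq, cigar)
write_sam <- function(records, contigs, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  body <- vapply(records, function(r)
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t*\t0\t0\tACGT\t*",
            r[1L], r[2L], r[3L], r[4L], r[5L], r[6L]), "")
  writeLines(c(hdr, body), path)
  path
}

# methylation-map TSV -> plain lookup table for the oracle (independent
# of the package's map object)
read_map_tsv_plain <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(contig = vapply(f, `[`, "", 1L),
             position = as.integer(vapply(f, `[`, "", 2L)),
             status = vapply(f, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
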