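# Synthetic data with known ground truth. The generative model is the
# inverse of the cleavage-rate estimator: every dinucleotide start
# position carries a break weight determined by its class, and read
# starts are drawn independently with probability proportional to that
# weight. Under this model estimated rate ratios converge to weight
# ratios, which makes the simulator the oracle for recovery tests.

#' Fragmentation model: per-class break weights
#'
#' Defaults give every class weight 1 with methylated CpG (CmG) elevated
#' to 1.5, emulating the observed preferential cleavage of methylated
#' CpG: mechanochemical breakage occurs about 1.5x more often there than
#' at other dinucleotides.
#'
#' @param weights named positive numeric vector over the class alphabet;
#'   \code{NULL} for the defaults.
#' @param n_reads number of break events to draw.
#' @param seed integer seed.
#' @param annotated use the 18-label methylation-aware alphabet.
#' @return a \code{fragmentation_model}.
#' @export
fragmentation_model <- function(weights = NULL, n_reads = 1e5, seed = 1L,
                                annotated = TRUE) {
  labels <- dinucleotide_classes(annotated)
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(labels)), labels)
    if (annotated) weights["CmG"] <- 1.5
  }
  if (!all(labels %in% names(weights)))
    cs_input_error("weights must cover the full class alphabet")
  weights <- weights[labels]
  if (any(!is.finite(weights) | weights <= 0))
    cs_input_error("all break weights must be positive")
  structure(list(weights = weights, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), annotated = annotated),
            class = "fragmentation_model")
}

#' Cohort specification for the simulator
#'
#' Describes a synthetic study: genome size and composition, CpG-island
#' geometry and CG enrichment, methylation-map noise, group sizes, read
#' depth, and the tumor effect (a break-weight multiplier applied to CG
#' dinucleotides inside a designated set of islands). Groups differ only
#' through that multiplier.
#'
#' @param genome_length bases (default 100 kb).
#' @param n_islands number of CpG islands (default 20).
#' @param island_length island length in bp (default 500).
#' @param island_cg_boost multiplicative boost of P(G | previous C)
#'   inside islands; 1 means no enrichment (default 4).
#' @param base_comp background base probabilities (A, C, G, T).
#' @param meth_noise named fractions: \code{island_methylated} (island
#'   CpGs wrongly methylated), \code{background_unmethylated},
#'   \code{unknown} (status undetermined); defaults 5% each.
#' @param samples_per_group samples per group (default 20 + 20).
#' @param reads_per_sample break events per sample (default 2e5).
#' @param base_weights per-class break weights of the shared
#'   fragmentation model; \code{NULL} for the
#'   \code{\link{fragmentation_model}} defaults.
#' @param n_affected_islands islands carrying the tumor effect
#'   (default 3).
#' @param tumor_cg_multiplier break-weight multiplier for CG positions
#'   inside affected islands in the tumor group (default 2).
#' @param contig contig name of the simulated genome.
#' @param seed integer master seed.
#' @return a \code{cohort_spec}.
#' @export
cohort_spec <- function(genome_length = 1e5, n_islands = 20L, island_length = 500L,
                        island_cg_boost = 4, base_comp = c(A = 0.25, C = 0.25,
                                                           G = 0.25, T = 0.25),
                        meth_noise = c(island_methylated = 0.05,
                                       background_unmethylated = 0.05,
                                       unknown = 0.05),
                        samples_per_group = c(tumor = 20L, normal = 20L),
                        reads_per_sample = 2e5,
                        base_weights = NULL,
                        n_affected_islands = 3L,
                        tumor_cg_multiplier = 2,
                        contig = "sim1", seed = 1L) {
  stopifnot(genome_length > 0, n_islands >= 0, island_length > 0,
            island_cg_boost > 0, all(base_comp > 0),
            all(meth_noise >= 0), all(meth_noise < 1),
            tumor_cg_multiplier > 0, n_affected_islands <= n_islands)
  structure(list(genome_length = as.integer(genome_length),
                 n_islands = as.integer(n_islands),
                 island_length = as.integer(island_length),
                 island_cg_boost = island_cg_boost,
                 base_comp = base_comp / sum(base_comp),
                 meth_noise = meth_noise,
                 samples_per_group = samples_per_group,
                 reads_per_sample = as.integer(reads_per_sample),
                 base_weights = base_weights,
                 n_affected_islands = as.integer(n_affected_islands),
                 tumor_cg_multiplier = tumor_cg_multiplier,
                 contig = contig, seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw a sequence chunk; when boost != 1 the chain is first-order Markov
# with P(G | previous C) multiplied by `boost` and renormalized
draw_sequence <- function(n, comp, boost = 1, prev = "") {
  bases <- names(comp)
  if (boost == 1) return(sample(bases, n, replace = TRUE, prob = comp))
  after_c <- comp; after_c["G"] <- after_c["G"] * boost
  after_c <- after_c / sum(after_c)
  out <- character(n)
  for (i in seq_len(n)) {
    p <- if (prev == "C") after_c else comp
    prev <- out[i] <- sample(bases, 1L, prob = p)
  }
  out
}

#' Simulate a genome with CpG islands and a methylation map
#'
#' Draws an i.i.d. background sequence, plants non-overlapping CG-boosted
#' islands (one per equal-width block, at a random offset, keeping a
#' 200-bp margin from the contig ends), and labels CpGs: island CpGs
#' UNMETHYLATED, background CpGs METHYLATED, with the configured noise
#' and unknown fractions. Bisulfite-style calls consistent with the map
#' under the default thresholds are emitted alongside.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param dir optional directory; when given, genome.fa, islands.bed,
#'   calls.tsv, methylation_map.tsv and manifest.json are written there.
#' @return list: \code{genome} (DNAStringSet), \code{islands} (named
#'   GRanges), \code{methylmap}, \code{calls} (data.frame), \code{spec}.
#' @export
simulate_genome <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  G <- spec$genome_length
  chars <- draw_sequence(G, spec$base_comp)
  margin <- 200L
  starts <- integer(0L)
  if (spec$n_islands > 0L) {
    block <- (G - 2L * margin) %/% spec$n_islands
    if (block < spec$island_length + 1L)
      cs_input_error("islands cannot be placed without overlap at this genome size")
    offs <- sample.int(block - spec$island_length + 1L, spec$n_islands, replace = TRUE)
    starts <- margin + (seq_len(spec$n_islands) - 1L) * block + offs
    for (k in seq_len(spec$n_islands)) {
      idx <- starts[k]:(starts[k] + spec$island_length - 1L)
      prev <- if (starts[k] > 1L) chars[starts[k] - 1L] else ""
      chars[idx] <- draw_sequence(spec$island_length, spec$base_comp,
                                  boost = spec$island_cg_boost, prev = prev)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- spec$contig

  islands <- GenomicRanges::GRanges(
    rep(spec$contig, length(starts)),
    IRanges::IRanges(start = starts, width = rep(spec$island_length, length(starts))))
  names(islands) <- sprintf("%s:%d-%d", spec$contig, starts - 1L,
                            starts + spec$island_length - 1L)

  # CpG positions and their statuses
  is_c <- chars == "C"
  cpg <- which(is_c[-G] & chars[-1L] == "G")
  in_island <- rep(FALSE, length(cpg))
  for (k in seq_along(starts))
    in_island <- in_island | (cpg >= starts[k] & cpg <= starts[k] + spec$island_length - 2L)
  status <- ifelse(in_island, 2L, 1L)  # island UNMETHYLATED, background METHYLATED
  nz <- spec$meth_noise
  u <- runif(length(cpg))
  flip <- (in_island & u < nz[["island_methylated"]]) |
    (!in_island & u < nz[["background_unmethylated"]])
  status[flip] <- 3L - status[flip]
  status[runif(length(cpg)) < nz[["unknown"]]] <- 3L

  calls <- data.frame(contig = spec$contig, position = cpg,
                      coverage = ifelse(status == 3L, 8L, 30L),
                      methylated_count = c(30L, 0L, 4L)[status],
                      stringsAsFactors = FALSE)
  methylmap <- new_methylation_map(calls$contig, calls$position, status,
                                   params = list(min_coverage = 10, concordance = 0.9,
                                                 source = "simulated"))

  out <- list(genome = genome, islands = islands, methylmap = methylmap,
              calls = calls, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    write.table(data.frame(spec$contig, starts - 1L,
                           starts + spec$island_length - 1L),
                file.path(dir, "islands.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(calls, file.path(dir, "calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write_methylation_map(methylmap, file.path(dir, "methylation_map.tsv"))
    jsonlite::write_json(list(spec = unclass(spec),
                              n_cpg = length(cpg),
                              island_ids = names(islands)),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate break events under a fragmentation model
#'
#' Draws exactly \code{n_reads} read-start events; the probability of a
#' break whose dinucleotide starts at position j is proportional to the
#' weight of the class at (j, j + 1). Uninformative positions (N) never
#' break. The emitted event position is j + 1: the 5'-end base of a
#' forward read, so the estimator reads the same pair back.
#'
#' @param genome \code{DNAStringSet} (single- or multi-contig; positions
#'   are drawn from all contigs jointly).
#' @param methylmap \code{methylation_map}, required when the model uses
#'   the 18-label alphabet.
#' @param model a \code{\link{fragmentation_model}}.
#' @param position_multiplier optional numeric vector (one entry per
#'   dinucleotide start of the single contig) of extra per-position
#'   weight factors; used to localize group effects in islands.
#' @return event data.frame (contig, position, strand).
#' @export
simulate_breaks <- function(genome, methylmap = NULL, model = fragmentation_model(),
                            position_multiplier = NULL) {
  if (model$annotated && is.null(methylmap))
    cs_input_error("annotated fragmentation model needs a methylation map")
  per_contig <- lapply(names(genome), function(ctg) {
    cc <- class_code_vector(genome, ctg,
                            methylmap = if (model$annotated) methylmap else NULL)
    w <- numeric(length(cc))
    w[cc > 0L] <- model$weights[cc[cc > 0L]]
    list(contig = ctg, w = w)
  })
  w_all <- unlist(lapply(per_contig, `[[`, "w"))
  if (!is.null(position_multiplier)) {
    if (length(genome) != 1L)
      cs_input_error("position_multiplier requires a single-contig genome")
    if (length(position_multiplier) != length(w_all))
      cs_input_error("position_multiplier length must match dinucleotide positions")
    w_all <- w_all * position_multiplier
  }
  if (all(w_all == 0)) cs_input_error("no informative break positions in genome")
  offsets <- cumsum(c(0L, vapply(per_contig, function(x) length(x$w), 0L)))
  set.seed(model$seed)
  j <- sample.int(length(w_all), model$n_reads, replace = TRUE, prob = w_all)
  ctg_idx <- findInterval(j - 1L, offsets)  # contig whose block contains j
  local_j <- j - offsets[ctg_idx]
  data.frame(contig = names(genome)[ctg_idx], position = local_j + 1L,
             strand = "+", stringsAsFactors = FALSE)
}

#' Simulate a labeled tumor/normal cohort
#'
#' Builds one genome, methylation map and island set, designates
#' \code{n_affected_islands} islands (chosen with the master seed), and
#' draws per-sample break events: normal samples under the base
#' fragmentation model, tumor samples with every CG dinucleotide inside
#' an affected island up-weighted by \code{tumor_cg_multiplier}. Full
#' ground truth is returned for recovery tests.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list: \code{genome}, \code{islands}, \code{methylmap},
#'   \code{events} (named list of event data.frames), \code{labels}
#'   (named TUMOR/NORMAL vector), \code{ground_truth} (affected island
#'   ids and multiplier), \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  if (any(spec$samples_per_group < 1L))
    cs_input_error("each group needs at least one sample")
  sim <- simulate_genome(spec)
  set.seed(spec$seed + 1L)
  affected <- sort(sample.int(spec$n_islands, spec$n_affected_islands))
  cc_plain <- class_code_vector(sim$genome, spec$contig)
  mult <- rep(1, length(cc_plain))
  st <- GenomicRanges::start(sim$islands)[affected]
  en <- GenomicRanges::end(sim$islands)[affected]
  for (k in seq_along(st)) {
    jr <- st[k]:(en[k] - 1L)
    mult[jr][cc_plain[jr] == 7L] <- spec$tumor_cg_multiplier
  }
  groups <- rep(c("TUMOR", "NORMAL"), times = c(spec$samples_per_group[["tumor"]],
                                                spec$samples_per_group[["normal"]]))
  ids <- sprintf("%s%02d", tolower(groups),
                 c(seq_len(spec$samples_per_group[["tumor"]]),
                   seq_len(spec$samples_per_group[["normal"]])))
  events <- vector("list", length(ids))
  names(events) <- ids
  for (s in seq_along(ids)) {
    model <- fragmentation_model(spec$base_weights, n_reads = spec$reads_per_sample,
                                 seed = spec$seed + 1000L + s, annotated = TRUE)
    events[[s]] <- simulate_breaks(sim$genome, sim$methylmap, model,
                                   position_multiplier = if (groups[s] == "TUMOR") mult else NULL)
  }
  list(genome = sim$genome, islands = sim$islands, methylmap = sim$methylmap,
       events = events, labels = setNames(groups, ids),
       ground_truth = list(affected_islands = names(sim$islands)[affected],
                           multiplier = spec$tumor_cg_multiplier),
       spec = spec)
}

#' Island score tables for a simulated cohort
#'
#' Convenience wrapper: computes \code{\link{island_cleavage_rates}} for
#' every sample of a \code{\link{simulate_cohort}} result.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param min_cg,min_support thresholds passed through.
#' @return named list of island score data.frames.
#' @export
cohort_island_scores <- function(cohort, min_cg = 5L, min_support = 0L) {
  lapply(cohort$events, function(ev)
    island_cleavage_rates(cohort$genome, ev, cohort$islands,
                          N = count_events(ev),
                          min_cg = min_cg, min_support = min_support))
}
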