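# Tumor/normal classification from island-score vectors. Each sample is
# a vector of island-restricted CpG cleavage rates; a linear-kernel SVM
# (e1071) separates the groups after per-island z-scoring, and accuracy
# is estimated by balanced jack-knife: repeated training with a random
# equal-sized holdout per class withheld and scored.

LABEL_LEVELS <- c("NORMAL", "TUMOR", "UNLABELED")

#' Assemble the sample-by-island rate matrix
#'
#' Takes per-sample island score tables (from
#' \code{\link{island_cleavage_rates}}) over the outer union of island
#' ids. Islands whose rate is missing in more than \code{max_missing}
#' of the samples are dropped (and logged); remaining missing cells are
#' imputed by the column median. The un-imputed matrix is retained for
#' analyses that must respect missingness (e.g.
#' \code{\link{rank_islands}}).
#'
#' @param score_tables named list (one element per sample) of island
#'   score data.frames with columns island_id and rate.
#' @param labels character vector, named by sample or in list order, with
#'   values TUMOR / NORMAL / UNLABELED.
#' @param max_missing maximum tolerated fraction of samples missing an
#'   island's rate (default 0.2).
#' @return an \code{island_rate_matrix}: list with \code{values} (imputed
#'   numeric matrix, samples x islands), \code{raw} (with NAs),
#'   \code{labels}, \code{dropped} (island ids removed).
#' @export
build_matrix <- function(score_tables, labels, max_missing = 0.2) {
  if (is.null(names(score_tables)))
    names(score_tables) <- paste0("sample", seq_along(score_tables))
  samples <- names(score_tables)
  if (is.null(names(labels))) names(labels) <- samples[seq_along(labels)]
  labels <- toupper(as.character(labels[samples]))
  labels[is.na(labels)] <- "UNLABELED"
  if (!all(labels %in% LABEL_LEVELS))
    cs_input_error("labels must be TUMOR, NORMAL or UNLABELED")
  islands <- unique(unlist(lapply(score_tables, function(d) d$island_id)))
  raw <- matrix(NA_real_, nrow = length(samples), ncol = length(islands),
                dimnames = list(samples, islands))
  for (s in samples) {
    d <- score_tables[[s]]
    raw[s, match(d$island_id, islands)] <- d$rate
  }
  miss_frac <- colMeans(is.na(raw))
  dropped <- islands[miss_frac > max_missing]
  keep <- setdiff(islands, dropped)
  if (length(samples) < 2L || length(keep) < 1L)
    cs_input_error("matrix needs at least 2 samples and 1 surviving island")
  raw <- raw[, keep, drop = FALSE]
  values <- raw
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- median(values[, j], na.rm = TRUE)
  }
  structure(list(values = values, raw = raw,
                 labels = setNames(labels, samples), dropped = dropped),
            class = "island_rate_matrix")
}

#' @export
print.island_rate_matrix <- function(x, ...) {
  cat(sprintf("island_rate_matrix: %d sample(s) x %d island(s); %d dropped for missingness\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

# numeric feature matrix from an island_rate_matrix or plain matrix
as_feature_matrix <- function(x) {
  if (is(x, "island_rate_matrix")) x$values
  else if (is.matrix(x)) x
  else cs_input_error("expected an island_rate_matrix or a numeric matrix")
}

#' Train the linear SVM tumor/normal classifier
#'
#' Features are standardized per island (z-score from the training rows;
#' constant islands get scale 1) before fitting a linear-kernel SVM.
#' Classes are balanced by seeded down-sampling of the larger class, so
#' training always sees the same number of tumor and normal samples. The
#' returned model is self-contained: it carries the feature order,
#' standardization constants, training medians for imputation, and the
#' explicit hyperplane (w, b), so prediction needs nothing else.
#'
#' @param mat an \code{island_rate_matrix} with both TUMOR and NORMAL
#'   labels present.
#' @param cost SVM regularization constant C (default 1).
#' @param seed integer seed for the balancing down-sample.
#' @return a \code{cleavage_classifier}.
#' @export
train_classifier <- function(mat, cost = 1, seed = 1L) {
  x <- as_feature_matrix(mat)
  lab <- mat$labels
  use <- lab %in% c("TUMOR", "NORMAL")
  x <- x[use, , drop = FALSE]; lab <- lab[use]
  tab <- table(factor(lab, levels = c("NORMAL", "TUMOR")))
  if (any(tab == 0L)) cs_input_error("training requires both TUMOR and NORMAL samples")
  set.seed(seed)
  n_keep <- min(tab)
  keep <- unlist(lapply(c("NORMAL", "TUMOR"), function(cl) {
    idx <- which(lab == cl)
    if (length(idx) > n_keep) sort(sample(idx, n_keep)) else idx
  }))
  x <- x[keep, , drop = FALSE]; lab <- lab[keep]

  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  y <- factor(lab, levels = c("NORMAL", "TUMOR"))
  fit <- e1071::svm(x = z, y = y, kernel = "linear", cost = cost, scale = FALSE)

  # explicit hyperplane; orient so positive decision values mean TUMOR
  w <- as.numeric(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  dv_manual <- as.numeric(z %*% w + b)
  dv_svm <- as.numeric(attr(predict(fit, z, decision.values = TRUE), "decision.values"))
  if (cor(dv_manual, dv_svm) < 0) { w <- -w; b <- -b; dv_manual <- -dv_manual }
  pred <- predict(fit, z)
  pos_is_tumor <- mean((dv_manual > 0) == (pred == "TUMOR"))
  if (pos_is_tumor < 0.5) { w <- -w; b <- -b }

  structure(list(features = colnames(x), center = center, scale = scale,
                 medians = apply(x, 2L, median), w = w, b = b,
                 cost = cost, seed = seed,
                 train_samples = rownames(x), train_labels = lab),
            class = "cleavage_classifier")
}

#' @export
print.cleavage_classifier <- function(x, ...) {
  cat(sprintf("cleavage_classifier: linear SVM over %d island feature(s), C = %g\n",
              length(x$features), x$cost))
  cat(sprintf("  trained on %d sample(s) (balanced)\n", length(x$train_samples)))
  invisible(x)
}

#' Predict tumor/normal status
#'
#' Applies the trained hyperplane to new island-score rows. Features are
#' matched by island id; islands absent from the input are imputed with
#' the training median. The decision value is w.z + b in standardized
#' space: positive predicts TUMOR, negative NORMAL, and an exact tie
#' predicts NORMAL (documented, arbitrary, stable).
#'
#' @param object a \code{cleavage_classifier}.
#' @param newdata an \code{island_rate_matrix} or numeric matrix with
#'   island-id column names.
#' @param ... unused.
#' @return data.frame: sample_id, label, decision.
#' @export
predict.cleavage_classifier <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  common <- intersect(object$features, colnames(x))
  if (length(common) == 0L)
    cs_input_error("no overlap between model features and input islands")
  full <- matrix(rep(object$medians, each = nrow(x)), nrow = nrow(x),
                 dimnames = list(rownames(x), object$features))
  full[, common] <- x[, common, drop = FALSE]
  nas <- is.na(full)
  if (any(nas))
    full[nas] <- rep(object$medians, each = nrow(x))[nas]
  z <- sweep(sweep(full, 2L, object$center), 2L, object$scale, "/")
  dv <- as.numeric(z %*% object$w + object$b)
  label <- ifelse(dv > 0, "TUMOR", "NORMAL")  # tie (dv == 0) -> NORMAL
  data.frame(sample_id = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
             label = label, decision = dv, stringsAsFactors = FALSE)
}

#' Balanced jack-knife evaluation
#'
#' Repeatedly withholds a random balanced holdout (the same number of
#' tumor and normal samples), trains on the remainder, and predicts the
#' holdout. Percentages aggregate over all rounds: TP% = 100 TP/(TP+FN)
#' over held-out tumor samples and TN% = 100 TN/(TN+FP) over held-out
#' normal samples, so TP% + FN% = 100 and TN% + FP% = 100.
#'
#' @param mat labeled \code{island_rate_matrix}.
#' @param rounds number of jack-knife rounds (default 100).
#' @param holdout_per_class samples withheld per class per round; default
#'   \code{max(1, floor(0.2 * smaller class size))}.
#' @param seed integer seed; the report is bit-reproducible given
#'   (matrix, parameters, seed).
#' @param cost SVM regularization constant.
#' @return an \code{evaluation_report}: list with \code{aggregate}
#'   (tp_pct, tn_pct, fp_pct, fn_pct), \code{rounds} (per-prediction
#'   detail), \code{seed}, \code{holdout_per_class}.
#' @export
jackknife_evaluate <- function(mat, rounds = 100L, holdout_per_class = NULL,
                               seed = 1L, cost = 1) {
  lab <- mat$labels
  tumor <- names(lab)[lab == "TUMOR"]; normal <- names(lab)[lab == "NORMAL"]
  n_min <- min(length(tumor), length(normal))
  if (is.null(holdout_per_class)) holdout_per_class <- max(1L, floor(0.2 * n_min))
  holdout_per_class <- as.integer(holdout_per_class)
  if (rounds < 1L) cs_input_error("rounds must be >= 1")
  if (holdout_per_class < 1L || holdout_per_class >= n_min)
    cs_input_error("holdout_per_class must be >= 1 and smaller than the smaller class")
  set.seed(seed)
  round_seeds <- sample.int(.Machine$integer.max - 1L, rounds)
  detail <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    set.seed(round_seeds[t])
    hold <- c(sample(tumor, holdout_per_class), sample(normal, holdout_per_class))
    train_mat <- structure(list(
      values = mat$values[setdiff(rownames(mat$values), hold), , drop = FALSE],
      raw = mat$raw[setdiff(rownames(mat$raw), hold), , drop = FALSE],
      labels = lab[setdiff(names(lab), hold)], dropped = mat$dropped),
      class = "island_rate_matrix")
    model <- train_classifier(train_mat, cost = cost, seed = round_seeds[t])
    pred <- predict(model, mat$values[hold, , drop = FALSE])
    detail[[t]] <- data.frame(round = t, sample_id = hold,
                              truth = as.character(lab[hold]),
                              predicted = pred$label,
                              decision = pred$decision,
                              stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  tp <- sum(detail$truth == "TUMOR" & detail$predicted == "TUMOR")
  fn <- sum(detail$truth == "TUMOR" & detail$predicted == "NORMAL")
  tn <- sum(detail$truth == "NORMAL" & detail$predicted == "NORMAL")
  fp <- sum(detail$truth == "NORMAL" & detail$predicted == "TUMOR")
  aggregate <- c(tp_pct = 100 * tp / (tp + fn), tn_pct = 100 * tn / (tn + fp),
                 fp_pct = 100 * fp / (tn + fp), fn_pct = 100 * fn / (tp + fn))
  structure(list(aggregate = aggregate, rounds = detail, seed = seed,
                 holdout_per_class = holdout_per_class, n_rounds = rounds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("evaluation_report: %d round(s), %d per class held out, seed %d\n",
              x$n_rounds, x$holdout_per_class, x$seed))
  cat(sprintf("  TP %.1f%%  TN %.1f%%  FP %.1f%%  FN %.1f%%\n",
              a["tp_pct"], a["tn_pct"], a["fp_pct"], a["fn_pct"]))
  invisible(x)
}

#' Rank islands by tumor/normal difference
#'
#' Orders islands by the absolute difference of their class-mean cleavage
#' rates (missing values excluded from the means), descending; ties break
#' lexicographically by island id. Signed differences expose the
#' direction: a negative difference (tumor below normal) is the
#' hypomethylation signature expected when tumor islands lose methylated
#' CpG.
#'
#' @param mat labeled \code{island_rate_matrix}.
#' @param k number of top islands to return; \code{NULL} returns all. A
#'   \code{k} beyond the island count returns all with a warning.
#' @return data.frame: island_id, normal_mean, tumor_mean, difference
#'   (tumor - normal), ordered by |difference| descending.
#' @export
rank_islands <- function(mat, k = NULL) {
  lab <- mat$labels
  if (!any(lab == "TUMOR") || !any(lab == "NORMAL"))
    cs_input_error("ranking requires both TUMOR and NORMAL samples")
  raw <- mat$raw
  tmean <- colMeans(raw[lab == "TUMOR", , drop = FALSE], na.rm = TRUE)
  nmean <- colMeans(raw[lab == "NORMAL", , drop = FALSE], na.rm = TRUE)
  diff <- tmean - nmean
  ord <- order(-abs(diff), colnames(raw))
  out <- data.frame(island_id = colnames(raw)[ord],
                    normal_mean = nmean[ord], tumor_mean = tmean[ord],
                    difference = diff[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(k)) {
    if (k > nrow(out)) warning(sprintf("k = %d exceeds island count %d; returning all",
                                       k, nrow(out)), call. = FALSE)
    out <- head(out, k)
  }
  out
}

# ---- persistence -------------------------------------------------------

#' Save / load the classifier as JSON
#'
#' The model artifact is a flat JSON document: feature order,
#' standardization constants, training medians, hyperplane weights and
#' bias, cost and seed. \code{read_classifier} reconstructs a model whose
#' predictions are identical.
#'
#' @param model a \code{cleavage_classifier}.
#' @param path JSON path.
#' @return \code{write_classifier}: \code{path}, invisibly;
#'   \code{read_classifier}: a \code{cleavage_classifier}.
#' @export
write_classifier <- function(model, path) {
  obj <- list(type = "cleavage_classifier", version = 1L,
              features = model$features,
              center = as.numeric(model$center), scale = as.numeric(model$scale),
              medians = as.numeric(model$medians),
              w = model$w, b = model$b, cost = model$cost, seed = model$seed,
              train_samples = model$train_samples,
              train_labels = as.character(model$train_labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "cleavage_classifier"))
    cs_format_error(sprintf("%s is not a classifier artifact", path))
  structure(list(features = obj$features,
                 center = setNames(obj$center, obj$features),
                 scale = setNames(obj$scale, obj$features),
                 medians = setNames(obj$medians, obj$features),
                 w = obj$w, b = obj$b, cost = obj$cost, seed = obj$seed,
                 train_samples = obj$train_samples,
                 train_labels = obj$train_labels),
            class = "cleavage_classifier")
}

#' Write / read the island rate matrix as TSV
#'
#' TSV with sample ids in the first column and island ids as header;
#' missing values written as NA. Labels travel in a two-column companion
#' file (sample_id, label).
#'
#' @param mat an \code{island_rate_matrix}.
#' @param path matrix TSV path.
#' @param labels_path companion label TSV path.
#' @return \code{write_matrix_tsv}: \code{path} invisibly;
#'   \code{read_matrix_tsv}: an \code{island_rate_matrix} (no islands are
#'   re-dropped; the stored matrix is taken as final, with any NA cells
#'   median-imputed).
#' @export
write_matrix_tsv <- function(mat, path, labels_path) {
  df <- data.frame(sample_id = rownames(mat$raw), mat$raw, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(mat$labels), label = mat$labels),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, labels_path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  rownames(raw) <- df[[1L]]
  lab <- read.table(labels_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  labels <- setNames(toupper(lab$label), lab$sample_id)[rownames(raw)]
  values <- raw
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- median(values[, j], na.rm = TRUE)
  }
  structure(list(values = values, raw = raw, labels = labels,
                 dropped = character(0L)),
            class = "island_rate_matrix")
}
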