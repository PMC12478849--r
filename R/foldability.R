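# Foldability analysis. A conformation is "foldable" when the RMSD of its
# guanine core to the unique core reference of its class falls strictly
# below a per-class threshold, defined as the 99th percentile of the RMSD
# fluctuation distribution of reference (properly folded) structures.
# Aggregations over the conformational grid then map which topologies and
# loop-length configurations fold.

#' Percentile RMSD threshold from a folded-state trace
#'
#' Empirical percentile with linear interpolation between order statistics
#' (\code{stats::quantile} type 7). The method is frozen here so thresholds
#' are reproducible.
#'
#' @param folded_samples numeric vector of RMSD values from reference
#'   folded-state fluctuations (nm).
#' @param percentile percentile in (0, 100], default 99.
#' @return threshold (nm).
#' @export
rmsd_threshold <- function(folded_samples, percentile = 99) {
  if (length(folded_samples) == 0L || !is.numeric(folded_samples)) {
    stop("folded_samples must be a nonempty numeric vector")
  }
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  stats::quantile(folded_samples, percentile / 100, type = 7, names = FALSE)
}

#' Per-class RMSD threshold set
#'
#' @param thresholds named numeric vector of thresholds (nm) keyed by class
#'   label (see [conformation_class()]).
#' @param percentile percentile the thresholds correspond to.
#' @return object of class \code{g4_thresholds}.
#' @export
g4_thresholds <- function(thresholds, percentile = 99) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)),
            all(thresholds > 0))
  structure(list(thresholds = thresholds, percentile = percentile),
            class = "g4_thresholds")
}

#' Default RMSD thresholds
#'
#' 99th-percentile thresholds of 0.104, 0.079 and 0.083 nm for the
#' three-tetrad right-handed, two-tetrad right-handed and two-tetrad
#' left-handed classes, as derived from reference MD fluctuation
#' distributions of experimentally solved G4 cores.
#'
#' @return a \code{g4_thresholds} object.
#' @export
default_thresholds <- function() {
  g4_thresholds(c("3T-RH" = 0.104, "2T-RH" = 0.079, "2T-LH" = 0.083),
                percentile = 99)
}

#' Label records as foldable by RMSD thresholding
#'
#' A record is foldable when its RMSD is strictly below the threshold of
#' its class.
#'
#' @param records data.frame with the conformational-grid columns plus
#'   \code{rmsd_nm}.
#' @param thresholds a \code{g4_thresholds} object (default
#'   [default_thresholds()]).
#' @return \code{records} with a logical \code{foldable} column.
#' @export
label_foldable <- function(records, thresholds = default_thresholds()) {
  stopifnot(inherits(thresholds, "g4_thresholds"),
            "rmsd_nm" %in% names(records))
  cls <- conformation_class(records)
  missing <- setdiff(unique(cls), names(thresholds$thresholds))
  if (length(missing) > 0L) {
    stop("no threshold for class(es): ", paste(missing, collapse = ", "))
  }
  records$foldable <- records$rmsd_nm < thresholds$thresholds[cls]
  records
}

#' Foldability map: topology x total loop length
#'
#' Fraction of foldable records in each (topology, total loop length) cell,
#' averaged over polarity patterns and loop-length permutations. Rows are
#' ordered by decreasing mean foldability of the topology; cells with no
#' records are \code{NA}.
#'
#' @param records labelled records (see [label_foldable()]).
#' @return numeric matrix, rownames topologies, colnames total lengths.
#' @export
foldability_map <- function(records) {
  stopifnot("foldable" %in% names(records))
  total <- records$len_I + records$len_II + records$len_III
  cell <- tapply(records$foldable, list(records$topology, total),
                 mean)
  topo_mean <- tapply(records$foldable, records$topology, mean)
  cell <- cell[order(-topo_mean[rownames(cell)]), , drop = FALSE]
  cell[, order(as.numeric(colnames(cell))), drop = FALSE]
}

#' Average foldability by loop feature and position
#'
#' @param records labelled records.
#' @param feature \code{"type"} (loop token) or \code{"length"}.
#' @return data.frame: \code{position}, \code{value}, \code{foldability},
#'   \code{n}.
#' @export
foldability_by_feature <- function(records, feature = c("type", "length")) {
  feature <- match.arg(feature)
  stopifnot("foldable" %in% names(records))
  positions <- c("I", "II", "III")
  rows <- lapply(1:3, function(k) {
    value <- if (feature == "type") {
      vapply(records$topology, function(t) as_loop_tokens(t)[k], character(1),
             USE.NAMES = FALSE)
    } else {
      as.character(records[[c("len_I", "len_II", "len_III")[k]]])
    }
    agg <- tapply(records$foldable, value, mean)
    data.frame(position = positions[k], value = names(agg),
               foldability = as.numeric(agg),
               n = as.integer(table(value)[names(agg)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average foldability of two-loop type combinations
#'
#' For every pair of distinct loop positions and every ordered pair of loop
#' types at those positions, the mean foldability over all records whose
#' topology carries that combination, with the list of such topologies.
#' When only one topology carries a combination, the average is simply that
#' topology's foldability.
#'
#' @param records labelled records.
#' @return data.frame: \code{position_a}, \code{type_a}, \code{position_b},
#'   \code{type_b}, \code{foldability}, \code{n}, \code{topologies}.
#' @export
two_loop_combination_table <- function(records) {
  stopifnot("foldable" %in% names(records))
  positions <- c("I", "II", "III")
  tok <- t(vapply(records$topology, as_loop_tokens, character(3)))
  pairs <- utils::combn(3, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    for (ta in LOOP_TOKENS) for (tb in LOOP_TOKENS) {
      sel <- tok[, pa] == ta & tok[, pb] == tb
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        position_a = positions[pa], type_a = ta,
        position_b = positions[pb], type_b = tb,
        foldability = mean(records$foldable[sel]),
        n = sum(sel),
        topologies = paste(sort(unique(records$topology[sel])),
                           collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature matrix for foldability modelling
#'
#' Encodes each record as loop type at positions I-III (one-hot over the
#' five loop tokens), loop length at I-III (numeric), and the tetrad
#' polarity pattern (one-hot). Columns are grouped by originating feature
#' so grouped attribution can treat each categorical block as one player.
#'
#' @param records conformational records.
#' @return list with \code{x} (numeric matrix) and \code{groups} (named
#'   list mapping feature name to column indices).
#' @export
g4_feature_matrix <- function(records) {
  tok <- t(vapply(records$topology, as_loop_tokens, character(3)))
  blocks <- list()
  groups <- list()
  onehot <- function(values, levels, prefix) {
    m <- sapply(levels, function(l) as.numeric(values == l))
    m <- matrix(m, nrow = length(values),
                dimnames = list(NULL, paste0(prefix, levels)))
    m
  }
  for (k in 1:3) {
    nm <- paste0("type_", c("I", "II", "III")[k])
    blocks[[nm]] <- onehot(tok[, k], LOOP_TOKENS, paste0(nm, "."))
  }
  for (k in 1:3) {
    nm <- paste0("len_", c("I", "II", "III")[k])
    m <- matrix(as.numeric(records[[nm]]), ncol = 1,
                dimnames = list(NULL, nm))
    blocks[[nm]] <- m
  }
  pol_levels <- sort(unique(records$polarity))
  blocks[["polarity"]] <- onehot(records$polarity, pol_levels, "polarity.")
  x <- do.call(cbind, blocks)
  start <- 1L
  for (nm in names(blocks)) {
    groups[[nm]] <- seq(start, length.out = ncol(blocks[[nm]]))
    start <- start + ncol(blocks[[nm]])
  }
  list(x = x, groups = groups)
}

xgb_train_quiet <- function(x, y, nrounds, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 4, eta = 0.3,
                  nthread = 1, seed = seed %% 2147483647),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

xgb_predict <- function(fit, xnew) {
  stats::predict(fit, xgboost::xgb.DMatrix(xnew, nthread = 1))
}

#' Fit a gradient-boosted foldability classifier with cross-validation
#'
#' Trains a gradient-boosted tree classifier on the loop-type, loop-length
#' and polarity features and reports mean precision (positive class:
#' foldable) over stratified k-fold cross-validation, then refits on the
#' full data.
#'
#' @param records labelled records.
#' @param folds number of CV folds (default 10), stratified by label.
#' @param seed RNG seed controlling fold assignment and training.
#' @param nrounds boosting rounds (default 50).
#' @return list of class \code{g4_classifier}: \code{model}, \code{precision}
#'   (mean over folds), \code{fold_precision}, \code{prevalence},
#'   \code{features}.
#' @export
fit_foldability_classifier <- function(records, folds = 10,
                                       seed = 20250911, nrounds = 50) {
  stopifnot("foldable" %in% names(records))
  y <- records$foldable
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fm <- g4_feature_matrix(records)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {   # stratified assignment
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_precision <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- xgb_train_quiet(fm$x[tr, , drop = FALSE], y[tr], nrounds,
                           seed + f)
    pred <- xgb_predict(fit, fm$x[!tr, , drop = FALSE]) > 0.5
    if (!any(pred)) return(NA_real_)
    sum(pred & y[!tr]) / sum(pred)
  }, numeric(1))
  model <- xgb_train_quiet(fm$x, y, nrounds, seed)
  structure(
    list(model = model, precision = mean(fold_precision, na.rm = TRUE),
         fold_precision = fold_precision, prevalence = mean(y),
         features = fm$groups),
    class = "g4_classifier"
  )
}
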